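#' Sample one draw per row from a Dirichlet distribution
#' @noRd
.rdirichlet <- function(n, conc) {
  g <- matrix(stats::rgamma(n * length(conc), shape = rep(conc, each = n)),
              nrow = n)
  g / rowSums(g)
}

#' Categorical draw per row of a row-stochastic matrix
#' @noRd
.rcat_rows <- function(P) {
  cs <- t(apply(P, 1L, cumsum))
  u <- stats::runif(nrow(P)) * cs[, ncol(P)]
  1L + rowSums(u > cs)
}

#' Sample ground-truth model parameters
#'
#' Draws the global parameters of the generative model: per-type topic
#' distributions `phi[[t]]` (columns `~ Dirichlet(beta[[t]])`), per-lab
#' result distributions `eta[[l]]` (rows `~ Dirichlet(zeta[[l]])`),
#' topic-dependent lab observation probabilities
#' `psi[l, k] ~ Beta(a[l], b[l])`, and per-patient topic mixtures
#' `theta[j, ] ~ Dirichlet(alpha)`.
#'
#' @param hyper a [mixehr_hyper()].
#' @param D number of patients.
#' @param seed integer RNG seed; the draw is deterministic given it.
#' @return object of class `mixehr_truth` with fields `theta` (`D x K`),
#'   `phi` (list of `W[t] x K`), `eta` (list of `K x V[l]`), `psi`
#'   (`L x K`), and the dimension vectors `W`, `V`.
#' @export
sample_truth <- function(hyper, D, seed) {
  .check_hyper(hyper)
  stopifnot(D >= 0L)
  set.seed(as.integer(seed))
  K <- length(hyper$alpha)
  W <- vapply(hyper$beta, length, 1L)
  V <- vapply(hyper$zeta, length, 1L)
  L <- length(V)
  phi <- lapply(seq_along(W), function(t) t(.rdirichlet(K, hyper$beta[[t]])))
  eta <- lapply(seq_len(L), function(l) .rdirichlet(K, hyper$zeta[[l]]))
  psi <- if (L > 0L)
    matrix(stats::rbeta(L * K, shape1 = rep(hyper$a, K),
                        shape2 = rep(hyper$b, K)), nrow = L)
  else matrix(0, 0L, K)
  theta <- if (D > 0L) .rdirichlet(D, hyper$alpha) else matrix(0, 0L, K)
  structure(list(theta = theta, phi = phi, eta = eta, psi = psi,
                 W = W, V = V),
            class = "mixehr_truth")
}

#' Sample a synthetic corpus from ground-truth parameters
#'
#' For each patient `j` and type `t`, `M[j, t]` tokens are drawn: a topic
#' `z ~ Multinomial(theta[j, ])`, then a feature `x ~ Multinomial(phi[[t]][, z])`;
#' identical tokens are collapsed into count records.  For every
#' patient-lab pair `(l, j)` a latent topic `h ~ Multinomial(theta[j, ])`
#' is drawn, then the observation indicator `r ~ Bernoulli(psi[l, h])`; if
#' `r = 1`, result states are drawn from `Multinomial(eta[[l]][h, ])` and
#' recorded with their frequencies.  Missingness is therefore
#' non-missing-at-random: it depends on the latent topic `h`, never on the
#' result value itself.
#'
#' @param truth a `mixehr_truth` from [sample_truth()].
#' @param tokens_per_patient token budget `M[j, t]`: a `D x T` matrix, a
#'   length-`T` vector (recycled over patients) or a scalar.
#' @param seed integer RNG seed.
#' @param lab_draws number of result draws for an observed pair: `"one"`
#'   (default, a single draw) or a positive rate `lambda` for
#'   `Poisson(lambda) + 1` repeated measurements.
#' @return a [mixehr_corpus()] with attribute `"h"` (the `L x D` matrix of
#'   latent lab topics actually drawn).
#' @export
sample_corpus <- function(truth, tokens_per_patient, seed, lab_draws = "one") {
  set.seed(as.integer(seed))
  D <- nrow(truth$theta)
  K <- ncol(truth$theta)
  T_ <- length(truth$W)
  L <- length(truth$V)
  M <- tokens_per_patient
  if (is.null(dim(M))) M <- matrix(M, nrow = max(D, 1L), ncol = T_, byrow = TRUE)
  if (any(M < 0)) stop("negative token budget")
  crec <- vector("list", D * T_)
  for (j in seq_len(D)) {
    for (t in seq_len(T_)) {
      m <- M[j, t]
      if (m == 0) next
      zcnt <- stats::rmultinom(1L, m, truth$theta[j, ])[, 1L]
      wcnt <- integer(truth$W[t])
      for (k in which(zcnt > 0L))
        wcnt <- wcnt + stats::rmultinom(1L, zcnt[k], truth$phi[[t]][, k])[, 1L]
      w <- which(wcnt > 0L)
      crec[[(j - 1L) * T_ + t]] <- data.frame(patient = j, type = t,
                                              feature = w, count = wcnt[w])
    }
  }
  counts <- do.call(rbind, crec)
  if (is.null(counts))
    counts <- data.frame(patient = integer(0), type = integer(0),
                         feature = integer(0), count = integer(0))
  h <- matrix(0L, nrow = L, ncol = D)
  lrec <- list()
  if (L > 0L && D > 0L) {
    for (l in seq_len(L)) {
      h[l, ] <- .rcat_rows(truth$theta)
      p_obs <- truth$psi[l, h[l, ]]
      r <- stats::rbinom(D, 1L, p_obs)
      for (j in which(r == 1L)) {
        ndraw <- if (identical(lab_draws, "one")) 1L
                 else 1L + stats::rpois(1L, as.numeric(lab_draws))
        y <- stats::rmultinom(1L, ndraw, truth$eta[[l]][h[l, j], ])[, 1L]
        v <- which(y > 0L)
        lrec[[length(lrec) + 1L]] <- data.frame(patient = j, lab = l,
                                                state = v, freq = y[v])
      }
    }
  }
  labs <- if (length(lrec)) do.call(rbind, lrec)
          else data.frame(patient = integer(0), lab = integer(0),
                          state = integer(0), freq = integer(0))
  corpus <- mixehr_corpus(counts, labs, D, truth$W, truth$V)
  attr(corpus, "h") <- h
  corpus
}

#' Fixed tiny corpus and truth used across the test suite
#'
#' A hard-coded instance with `D = 6` patients, `K = 2` topics, `T = 2`
#' data types with vocabularies `W = (5, 4)`, `L = 2` labs with
#' `V = (2, 2)` result states, and 35 tokens in total.  Identical on every
#' call; nothing is sampled.
#'
#' @return list with elements `corpus` (a [mixehr_corpus()]) and `truth`
#'   (a `mixehr_truth` the fixture is loosely patterned on).
#' @export
make_fixture <- function() {
  counts <- data.frame(
    patient = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L, 3L, 3L,
                4L, 4L, 4L, 5L, 5L, 5L, 5L, 6L, 6L, 6L, 6L),
    type    = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 1L, 1L, 2L, 2L,
                1L, 1L, 2L, 1L, 1L, 2L, 2L, 1L, 1L, 1L, 2L),
    feature = c(1L, 2L, 1L, 2L, 1L, 3L, 2L, 2L, 4L, 3L, 1L,
                4L, 5L, 4L, 5L, 4L, 3L, 4L, 1L, 2L, 3L, 2L),
    count   = c(3L, 2L, 2L, 1L, 1L, 2L, 2L, 1L, 2L, 1L, 1L,
                2L, 1L, 2L, 3L, 1L, 2L, 1L, 1L, 1L, 1L, 2L))
  labs <- data.frame(
    patient = c(1L, 2L, 2L, 4L, 6L, 1L, 3L, 5L),
    lab     = c(1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L),
    state   = c(1L, 1L, 2L, 2L, 1L, 1L, 2L, 2L),
    freq    = c(2L, 1L, 1L, 1L, 1L, 1L, 2L, 1L))
  corpus <- mixehr_corpus(counts, labs, n_patients = 6L,
                          n_features = c(5L, 4L), n_states = c(2L, 2L))
  theta <- matrix(c(0.9, 0.8, 0.5, 0.2, 0.1, 0.6,
                    0.1, 0.2, 0.5, 0.8, 0.9, 0.4), ncol = 2L)
  phi <- list(matrix(c(0.40, 0.30, 0.15, 0.10, 0.05,
                       0.05, 0.10, 0.15, 0.30, 0.40), ncol = 2L),
              matrix(c(0.50, 0.30, 0.15, 0.05,
                       0.05, 0.15, 0.30, 0.50), ncol = 2L))
  eta <- list(matrix(c(0.8, 0.3, 0.2, 0.7), nrow = 2L),
              matrix(c(0.6, 0.1, 0.4, 0.9), nrow = 2L))
  psi <- matrix(c(0.9, 0.4, 0.3, 0.8), nrow = 2L)
  truth <- structure(list(theta = theta, phi = phi, eta = eta, psi = psi,
                          W = c(5L, 4L), V = c(2L, 2L)),
                     class = "mixehr_truth")
  list(corpus = corpus, truth = truth)
}

#' Synthetic benchmark instances
#'
#' Reproducible synthetic study conditions used by the test suite and the
#' acceptance script.
#'
#' \describe{
#'   \item{`"recovery"`}{Parameter-recovery conditions: `D` patients
#'     (default 500), `K = 3` topics, two data types with vocabularies
#'     `(60, 40)`, 10 binary labs, 80 tokens per patient (40 per type).
#'     Topics are drawn sparse (`beta = 0.05`) so they are well separated;
#'     patient mixtures use `alpha = 0.5`, lab result concentrations
#'     `zeta = 0.5`, and uniform `Beta(1, 1)` observation probabilities.}
#'   \item{`"nmar"`}{Topic-dependent missingness conditions for the
#'     imputation benchmark: `K = 3` topics, vocabularies `(60, 40)`,
#'     60 tokens per patient, 10 binary labs.  Each lab's preferred result
#'     state alternates with the topic (`eta = 0.9` on the preferred
#'     state) and its observation probability is high (0.7) under one
#'     designated topic and low (0.3) under the others, so whether a lab
#'     is taken carries information about the disease topic.  Patient
#'     mixtures use `alpha = 0.3` (fairly concentrated patients).}
#' }
#'
#' @param type `"recovery"` or `"nmar"`.
#' @param D number of patients.
#' @param seed integer RNG seed.
#' @return list with `corpus`, `truth`, and the generator `hyper` (for
#'   `"recovery"`).
#' @export
simulate_benchmark <- function(type = c("recovery", "nmar"), D = 500L,
                               seed = 1L) {
  type <- match.arg(type)
  K <- 3L
  W <- c(60L, 40L)
  V <- rep(2L, 10L)
  if (type == "recovery") {
    gen <- mixehr_hyper(alpha = rep(0.5, K), beta = 0.05, zeta = 0.5,
                        a = 1, b = 1, W = W, V = V)
    truth <- sample_truth(gen, D = D, seed = seed)
    corpus <- sample_corpus(truth, tokens_per_patient = c(40L, 40L),
                            seed = seed + 1L)
    return(list(corpus = corpus, truth = truth, hyper = gen))
  }
  gen <- mixehr_hyper(alpha = rep(0.3, K), beta = 0.05, zeta = 0.5,
                      a = 1, b = 1, W = W, V = V)
  truth <- sample_truth(gen, D = D, seed = seed)
  L <- length(V)
  for (l in seq_len(L)) {
    pref <- 1L + (l + seq_len(K)) %% 2L            # preferred state per topic
    truth$eta[[l]] <- matrix(0.1, K, 2L)
    truth$eta[[l]][cbind(seq_len(K), pref)] <- 0.9
    on_topic <- 1L + (l %% K)                      # topic that orders the lab
    truth$psi[l, ] <- ifelse(seq_len(K) == on_topic, 0.7, 0.3)
  }
  corpus <- sample_corpus(truth, tokens_per_patient = c(30L, 30L),
                          seed = seed + 1L)
  list(corpus = corpus, truth = truth, hyper = gen)
}
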