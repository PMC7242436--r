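#' Model hyperparameters
#'
#' Bundles every hyperparameter of the generative model: the patient-level
#' Dirichlet concentration `alpha` (length `K`), the per-type feature
#' Dirichlet concentrations `beta` (list of length `T`, element `t` of
#' length `W[t]`), the per-lab result-state Dirichlet concentrations `zeta`
#' (list of length `L`, element `l` of length `V[l]`), and the per-lab Beta
#' shapes `a`, `b` governing the topic-dependent observation probability of
#' each lab.  Each family in turn carries a Gamma hyper-prior
#' `(shape, rate)` used by the empirical-Bayes fixed-point updates.
#'
#' @param alpha numeric vector of `K` positive reals.
#' @param beta list of `T` numeric vectors (positive), or a single scalar to
#'   be recycled symmetrically given `W`.
#' @param zeta list of `L` numeric vectors (positive), or a scalar given `V`.
#' @param a,b numeric vectors of `L` positive reals (scalars recycled).
#' @param gamma_prior named list of `(shape, rate)` pairs for families
#'   `alpha`, `beta`, `zeta`, `a`, `b`. Default: shape 1, rate 1 for all.
#' @param W,V integer vectors of vocabulary sizes / lab state counts, used
#'   only to expand scalar `beta` / `zeta`.
#'
#' @return object of class `mixehr_hyper`.
#' @export
mixehr_hyper <- function(alpha, beta, zeta = list(), a = numeric(0),
                         b = numeric(0), gamma_prior = NULL,
                         W = NULL, V = NULL) {
  if (!is.list(beta)) {
    stopifnot(!is.null(W))
    beta <- lapply(W, function(w) rep_len(as.numeric(beta), w))
  }
  if (!is.list(zeta)) {
    stopifnot(!is.null(V))
    zeta <- lapply(V, function(v) rep_len(as.numeric(zeta), v))
  }
  L <- length(zeta)
  if (length(a) == 1L) a <- rep(a, L)
  if (length(b) == 1L) b <- rep(b, L)
  if (is.null(gamma_prior)) gamma_prior <- list()
  for (fam in c("alpha", "beta", "zeta", "a", "b"))
    if (is.null(gamma_prior[[fam]]))
      gamma_prior[[fam]] <- c(shape = 1, rate = 1)
  h <- structure(list(alpha = as.numeric(alpha), beta = beta, zeta = zeta,
                      a = as.numeric(a), b = as.numeric(b),
                      gamma_prior = gamma_prior),
                 class = "mixehr_hyper")
  .check_hyper(h)
  h
}

.check_hyper <- function(h) {
  pos <- function(x) length(x) == 0L || (all(is.finite(x)) && all(x > 0))
  if (!pos(h$alpha) || !all(vapply(h$beta, pos, TRUE)) ||
      !all(vapply(h$zeta, pos, TRUE)) || !pos(h$a) || !pos(h$b))
    stop("all hyperparameters must be strictly positive and finite")
  invisible(h)
}

#' Default hyperparameters for a corpus
#'
#' Symmetric, weakly informative defaults: `alpha = 1/K` per topic,
#' `beta = 0.1` per feature, `zeta = 1` per result state, `a = b = 1`
#' (uniform prior on each lab's observation probability).
#'
#' @param K number of topics.
#' @param corpus a [mixehr_corpus()] supplying the dimensions.
#' @return a [mixehr_hyper()].
#' @export
default_hyper <- function(K, corpus) {
  mixehr_hyper(alpha = rep(1 / K, K), beta = 0.1, zeta = 1,
               a = 1, b = 1, W = corpus$W, V = corpus$V)
}

#' @export
print.mixehr_hyper <- function(x, ...) {
  cat("<mixehr_hyper> K=", length(x$alpha), ", T=", length(x$beta),
      ", L=", length(x$zeta), "\n", sep = "")
  cat("  alpha: ", paste(signif(utils::head(x$alpha, 5), 3), collapse = " "),
      if (length(x$alpha) > 5) " ...", "\n", sep = "")
  invisible(x)
}
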