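#' One full CVB0 E-step sweep
#'
#' Applies the single-record updates ([update_gamma()], [update_lambda()],
#' [update_pi()]) to every record of the corpus in deterministic sweep
#' order — patients in index order; within a patient, token records, then
#' observed lab records, then unobserved lab pairs — with incremental
#' maintenance of the cached statistics (own contribution subtracted and
#' clipped at zero before each update, new contribution added back).
#' Runs in compiled code; [refresh_statistics()] should follow each sweep
#' to cancel floating-point drift.
#'
#' @param state a [mixehr_state].
#' @param hyper a [mixehr_hyper()].
#' @param patients integer vector of patient indices to sweep (default all).
#' @return the updated state (assignments and incrementally updated caches).
#' @export
e_step <- function(state, hyper, patients = seq_len(state$D)) {
  K <- state$K; D <- state$D
  T_ <- length(state$W); L <- length(state$V)
  gamma <- state$gamma + 0
  lambda <- state$lambda + 0
  pi_flat <- state$pi + 0
  s <- state$stats
  n_jk <- s$n_jk + 0
  n_wk <- lapply(s$n_wk, `+`, 0)
  nk <- matrix(0, max(T_, 1L), K)
  for (t in seq_len(T_)) nk[t, ] <- colSums(n_wk[[t]])
  m_jk <- s$m_jk + 0
  m_lkv <- lapply(s$m_lkv, `+`, 0)
  p <- s$p + 0
  q <- s$q + 0
  ptr <- function(df, n) c(0L, cumsum(tabulate(df$patient, nbins = n)))
  cvb0_sweep_cpp(K, as.integer(patients - 1L),
                 ptr(state$tok, D), as.integer(state$tok$type - 1L),
                 as.integer(state$tok$feature - 1L),
                 as.numeric(state$tok$count), gamma,
                 ptr(state$obs, D), as.integer(state$obs$lab - 1L),
                 as.integer(state$obs$state - 1L),
                 as.numeric(state$obs$freq), lambda,
                 ptr(state$miss, D), as.integer(state$miss$lab - 1L),
                 as.integer(state$pi_off), pi_flat,
                 as.integer(state$V),
                 n_jk, n_wk, nk, m_jk, m_lkv, p, q,
                 hyper$alpha, hyper$beta,
                 vapply(hyper$beta, sum, 1.0),
                 hyper$zeta, vapply(hyper$zeta, sum, 1.0),
                 hyper$a, hyper$b)
  state$gamma <- gamma
  state$lambda <- lambda
  state$pi <- pi_flat
  state$stats <- list(n_jk = n_jk, n_wk = n_wk, m_jk = m_jk,
                      m_lkv = m_lkv, p = p, q = q)
  state
}

#' Empirical-Bayes fixed-point update of all hyperparameters
#'
#' One pass of the digamma-ratio fixed point that maximizes the collapsed
#' marginal likelihood in each Dirichlet/Beta hyperparameter, with the
#' Gamma hyper-prior `(shape, rate)` of each family entering as
#' `shape - 1` in the numerator and `rate` in the denominator.  For a
#' feature concentration `beta_wt` the update is
#' `beta* = (shape - 1 + beta * sum_k [psi(beta + n_wk) - psi(beta)]) /
#'          (rate + sum_k [psi(sum_w beta + n_.k) - psi(sum_w beta)])`
#' and the updates for `alpha`, `zeta`, `a`, `b` take the analogous form on
#' their own sufficient statistics.  With all counts zero the update
#' returns the prior mode `(shape - 1) / rate`.  All families are updated
#' simultaneously from the current values; results are floored at `1e-6`.
#'
#' @param state a [mixehr_state] with fresh statistics.
#' @param hyper current [mixehr_hyper()].
#' @return a new [mixehr_hyper()] with strictly positive entries.
#' @export
update_hyperparameters <- function(state, hyper) {
  s <- state$stats
  K <- state$K
  floor_ <- 1e-6
  fp <- function(conc, counts_mat, group_counts, prior) {
    # conc: vector over components; counts_mat: components x groups;
    # group_counts: totals per group (= colSums(counts_mat)).
    csum <- sum(conc)
    num <- prior[["shape"]] - 1 +
      conc * rowSums(digamma(counts_mat + conc) - digamma(conc))
    den <- prior[["rate"]] +
      sum(digamma(csum + group_counts) - digamma(csum))
    out <- num / den
    if (any(!is.finite(out)))
      stop("non-finite hyperparameter fixed point (family counts: ",
           paste(signif(range(counts_mat), 3), collapse = ".."), ")")
    pmax(out, floor_)
  }
  gp <- hyper$gamma_prior
  njk <- s$n_jk + s$m_jk
  alpha <- fp(hyper$alpha, t(njk), rowSums(njk), gp$alpha)
  beta <- lapply(seq_along(hyper$beta), function(t)
    fp(hyper$beta[[t]], s$n_wk[[t]], colSums(s$n_wk[[t]]), gp$beta))
  zeta <- lapply(seq_along(hyper$zeta), function(l)
    fp(hyper$zeta[[l]], t(s$m_lkv[[l]]), rowSums(s$m_lkv[[l]]), gp$zeta))
  L <- length(hyper$zeta)
  a <- hyper$a; b <- hyper$b
  if (L > 0L) {
    for (l in seq_len(L)) {
      al <- hyper$a[l]; bl <- hyper$b[l]
      den_ab <- sum(digamma(al + bl + s$p[l, ] + s$q[l, ]) - digamma(al + bl))
      a[l] <- max((gp$a[["shape"]] - 1 +
                     al * sum(digamma(al + s$p[l, ]) - digamma(al))) /
                    (gp$a[["rate"]] + den_ab), floor_)
      b[l] <- max((gp$b[["shape"]] - 1 +
                     bl * sum(digamma(bl + s$q[l, ]) - digamma(bl))) /
                    (gp$b[["rate"]] + den_ab), floor_)
    }
    if (any(!is.finite(a)) || any(!is.finite(b)))
      stop("non-finite Beta-shape fixed point")
  }
  mixehr_hyper(alpha = alpha, beta = beta, zeta = zeta, a = a, b = b,
               gamma_prior = gp)
}

#' Training configuration for batch collapsed variational inference
#'
#' @param max_iter maximum number of full sweeps (default 500).
#' @param min_iter minimum number of sweeps before the convergence test is
#'   applied (default 10): early sweeps break the near-uniform initial
#'   symmetry slowly and the monitored likelihood can be transiently flat.
#' @param tol convergence tolerance: stop when the relative change of the
#'   monitored log-likelihood over a sweep falls below it (default 1e-4).
#' @param hyperupdate_every run [update_hyperparameters()] every this many
#'   sweeps (default 5); 0 disables hyperparameter learning.
#' @param include_lab_mass include lab-topic mass in the patient mixture
#'   estimates (default TRUE).
#' @param lab_loglik `"product"` (default) or `"sum"`; how the lab term of
#'   the predictive likelihood combines the observation probability and the
#'   result distribution (see [predictive_log_likelihood()]).
#' @param verbose print the monitored likelihood each sweep.
#' @return a list of class `jcvb_control`.
#' @export
jcvb_control <- function(max_iter = 500L, min_iter = 10L, tol = 1e-4,
                         hyperupdate_every = 5L,
                         include_lab_mass = TRUE, lab_loglik = "product",
                         verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter),
                 min_iter = as.integer(min_iter), tol = tol,
                 hyperupdate_every = as.integer(hyperupdate_every),
                 include_lab_mass = isTRUE(include_lab_mass),
                 lab_loglik = match.arg(lab_loglik, c("product", "sum")),
                 verbose = isTRUE(verbose)),
            class = "jcvb_control")
}

#' Fit the topic model by batch collapsed variational inference
#'
#' Alternates full E-step sweeps ([e_step()]) with statistic refreshes and
#' periodic empirical-Bayes hyperparameter updates, monitoring the
#' training-set predictive log-likelihood under the current posterior-mean
#' estimates until its relative change falls below `control$tol` or
#' `control$max_iter` sweeps have run.
#'
#' @param corpus a [mixehr_corpus()].
#' @param K number of topics (>= 1).
#' @param control a [jcvb_control()].
#' @param hyper starting hyperparameters; default [default_hyper()].
#' @param seed integer seed for the state initialization.
#' @return object of class `mixehr_fit`: list with `estimates`
#'   (a `mixehr_estimates`), `state`, `hyper`, and `trace` (data.frame
#'   with `iter`, `loglik`).
#' @export
fit_jcvb <- function(corpus, K, control = jcvb_control(), hyper = NULL,
                     seed = 1L) {
  if (K < 1L) stop("K must be >= 1")
  if (is.null(hyper)) hyper <- default_hyper(K, corpus)
  state <- initialize_state(corpus, K, seed)
  trace <- data.frame(iter = integer(0), loglik = numeric(0))
  ll_prev <- NA_real_
  est <- estimate_parameters(state, hyper, control$include_lab_mass)
  for (it in seq_len(control$max_iter)) {
    state <- e_step(state, hyper)
    state <- refresh_statistics(state, corpus)
    if (control$hyperupdate_every > 0L &&
        it %% control$hyperupdate_every == 0L)
      hyper <- update_hyperparameters(state, hyper)
    est <- estimate_parameters(state, hyper, control$include_lab_mass)
    ll <- .corpus_loglik(est, corpus, est$theta, control$lab_loglik)
    if (!is.finite(ll))
      stop("divergence: non-finite monitored likelihood at sweep ", it)
    trace <- rbind(trace, data.frame(iter = it, loglik = ll))
    if (control$verbose)
      message(sprintf("sweep %d  loglik %.4f", it, ll))
    if (it >= control$min_iter && !is.na(ll_prev) &&
        abs(ll - ll_prev) < control$tol * abs(ll_prev))
      break
    ll_prev <- ll
  }
  structure(list(estimates = est, state = state, hyper = hyper,
                 trace = trace, K = K, control = control),
            class = "mixehr_fit")
}

#' @export
print.mixehr_fit <- function(x, ...) {
  cat("<mixehr_fit> K=", x$K, ", ", nrow(x$trace), " sweep(s), final loglik ",
      signif(utils::tail(x$trace$loglik, 1L), 6), "\n", sep = "")
  invisible(x)
}

# Shared log-likelihood engine (tokens + observed labs), log space.
.corpus_loglik <- function(est, corpus, theta, lab_mode = "product") {
  ll <- 0
  tok <- corpus$counts
  if (nrow(tok)) {
    for (t in seq_along(corpus$W)) {
      it <- which(tok$type == t)
      if (!length(it)) next
      pr <- rowSums(theta[tok$patient[it], , drop = FALSE] *
                      est$phi[[t]][tok$feature[it], , drop = FALSE])
      if (any(pr <= 0)) {
        warning("zero predictive probability for count record(s) ",
                paste(utils::head(it[pr <= 0], 5L), collapse = ","),
                " of type ", t)
        return(-Inf)
      }
      ll <- ll + sum(tok$count[it] * log(pr))
    }
  }
  lb <- corpus$labs
  if (nrow(lb)) {
    for (l in seq_along(corpus$V)) {
      il <- which(lb$lab == l)
      if (!length(il)) next
      th <- theta[lb$patient[il], , drop = FALSE]
      etav <- est$eta[[l]][, lb$state[il], drop = FALSE]  # K x n
      psi <- est$psi[l, ]
      inner <- if (lab_mode == "product") psi * etav else psi + etav
      pr <- rowSums(th * t(inner))
      if (any(pr <= 0)) {
        warning("zero predictive probability for lab record(s) ",
                paste(utils::head(il[pr <= 0], 5L), collapse = ","),
                " of lab ", l)
        return(-Inf)
      }
      ll <- ll + sum(lb$freq[il] * log(pr))
    }
  }
  ll
}
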