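#' Configuration for stochastic collapsed variational inference
#'
#' @param batch_size minibatch size `D'` (1..D).
#' @param rho fixed learning rate in `[0, 1]` (default 0.5). Ignored when
#'   `rho_schedule` is given.
#' @param rho_schedule optional Robbins-Monro schedule `c(tau, kappa)`:
#'   at global minibatch step `s` (starting at 1) the rate is
#'   `(s + tau)^(-kappa)`.
#' @param iterations number of epochs (full passes over shuffled patients).
#' @param seed integer seed (batch shuffling and local initializations).
#' @param local_sweeps CVB0 sweeps run over each minibatch's local
#'   assignments before the global statistics are interpolated (default 1).
#' @param scale logical; scale minibatch sums by `D/D'` so the interpolation
#'   mixes same-scale quantities (default TRUE).
#' @param hyperupdate_every epochs between empirical-Bayes hyperparameter
#'   updates; 0 (default) disables them.
#' @param monitor_size number of (seeded) patients whose predictive
#'   log-likelihood is traced per epoch (default 50, capped at D).
#' @param include_lab_mass,lab_loglik as in [jcvb_control()].
#' @return list of class `scvb_control`.
#' @export
scvb_control <- function(batch_size, rho = 0.5, rho_schedule = NULL,
                         iterations = 10L, seed = 1L, local_sweeps = 1L,
                         scale = TRUE, hyperupdate_every = 0L,
                         monitor_size = 50L, include_lab_mass = TRUE,
                         lab_loglik = "product") {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  structure(list(batch_size = as.integer(batch_size), rho = rho,
                 rho_schedule = rho_schedule,
                 iterations = as.integer(iterations),
                 seed = as.integer(seed),
                 local_sweeps = as.integer(local_sweeps),
                 scale = isTRUE(scale),
                 hyperupdate_every = as.integer(hyperupdate_every),
                 monitor_size = as.integer(monitor_size),
                 include_lab_mass = isTRUE(include_lab_mass),
                 lab_loglik = match.arg(lab_loglik, c("product", "sum"))),
            class = "scvb_control")
}

#' Minibatch estimates of the global sufficient statistics
#'
#' Sums the current assignments of the batch patients — token assignments
#' weighted by count into the per-type feature statistics, observed lab
#' assignments weighted by frequency plus unobserved joint distributions
#' into the per-lab statistics — and scales by `D/D'` so the sums estimate
#' the full-corpus statistics.
#'
#' @param state a [mixehr_state] whose assignments cover (at least) the
#'   batch patients.
#' @param batch integer vector of patient indices (non-empty).
#' @param n_patients total number of patients `D` the estimate should be
#'   scaled to (default `state$D`).
#' @param scale apply the `D/D'` factor (default TRUE).
#' @return list with `n_hat` (per type, `W[t] x K`), `m_hat` (per lab,
#'   `K x V[l]`), `p_hat`, `q_hat` (`L x K`), and the unscaled per-patient
#'   masses `n_jk`, `m_jk` (rows outside the batch are zero).
#' @export
minibatch_statistics <- function(state, batch, n_patients = state$D,
                                 scale = TRUE) {
  if (length(batch) == 0L) stop("empty minibatch")
  fac <- if (scale) n_patients / length(batch) else 1
  K <- state$K
  T_ <- length(state$W); L <- length(state$V)
  inb <- logical(state$D); inb[batch] <- TRUE
  n_jk <- matrix(0, state$D, K)
  n_hat <- lapply(seq_len(T_), function(t) matrix(0, state$W[t], K))
  ti <- which(inb[state$tok$patient])
  if (length(ti)) {
    cg <- state$gamma[ti, , drop = FALSE] * state$tok$count[ti]
    n_jk <- .rowsum_full(cg, state$tok$patient[ti], state$D)
    for (t in seq_len(T_)) {
      it <- ti[state$tok$type[ti] == t]
      if (!length(it)) next
      n_hat[[t]] <- .rowsum_full(state$gamma[it, , drop = FALSE] *
                                   state$tok$count[it],
                                 state$tok$feature[it], state$W[t])
    }
  }
  m_jk <- matrix(0, state$D, K)
  m_hat <- lapply(seq_len(L), function(l) matrix(0, K, state$V[l]))
  p_hat <- matrix(0, max(L, 0L), K)
  q_hat <- matrix(0, max(L, 0L), K)
  oi <- which(inb[state$obs$patient])
  if (length(oi)) {
    yl <- state$lambda[oi, , drop = FALSE] * state$obs$freq[oi]
    m_jk <- m_jk + .rowsum_full(yl, state$obs$patient[oi], state$D)
    p_hat <- .rowsum_full(yl, state$obs$lab[oi], L)
    for (l in seq_len(L)) {
      il <- oi[state$obs$lab[oi] == l]
      if (!length(il)) next
      m_hat[[l]] <- t(.rowsum_full(state$lambda[il, , drop = FALSE] *
                                     state$obs$freq[il],
                                   state$obs$state[il], state$V[l]))
    }
  }
  mi <- which(inb[state$miss$patient])
  if (length(mi)) {
    for (l in seq_len(L)) {
      il <- mi[state$miss$lab[mi] == l]
      if (!length(il)) next
      Vl <- state$V[l]
      blkidx <- outer(state$pi_off[il], seq_len(K * Vl), `+`)
      P <- matrix(state$pi[blkidx], nrow = length(il))
      m_hat[[l]] <- m_hat[[l]] + matrix(colSums(P), nrow = K)
      kmass <- matrix(sapply(seq_len(K), function(k)
        rowSums(P[, k + K * (seq_len(Vl) - 1L), drop = FALSE])),
        nrow = length(il))
      m_jk <- m_jk + .rowsum_full(kmass, state$miss$patient[il], state$D)
      q_hat[l, ] <- q_hat[l, ] + colSums(kmass)
    }
  }
  list(n_hat = lapply(n_hat, `*`, fac),
       m_hat = lapply(m_hat, `*`, fac),
       p_hat = p_hat * fac, q_hat = q_hat * fac,
       n_jk = n_jk, m_jk = m_jk)
}

#' Natural-gradient interpolation of the global statistics
#'
#' Replaces each global statistic by `(1 - rho) * old + rho * new`,
#' elementwise; all other state is untouched.  Non-negativity is preserved
#' for any `rho` in `[0, 1]`.
#'
#' @param state a [mixehr_state].
#' @param n_hat,m_hat minibatch estimates (per type / per lab) as returned
#'   by [minibatch_statistics()].
#' @param rho learning rate in `[0, 1]`.
#' @param p_hat,q_hat optional minibatch estimates of the lab observation
#'   Beta statistics, interpolated with the same rate when given.
#' @return the state with interpolated statistics.
#' @export
scvb_step <- function(state, n_hat, m_hat, rho, p_hat = NULL, q_hat = NULL) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
  s <- state$stats
  s$n_wk <- lapply(seq_along(s$n_wk), function(t)
    (1 - rho) * s$n_wk[[t]] + rho * n_hat[[t]])
  s$m_lkv <- lapply(seq_along(s$m_lkv), function(l)
    (1 - rho) * s$m_lkv[[l]] + rho * m_hat[[l]])
  if (!is.null(p_hat)) s$p <- (1 - rho) * s$p + rho * p_hat
  if (!is.null(q_hat)) s$q <- (1 - rho) * s$q + rho * q_hat
  state$stats <- s
  state
}

# Global statistics of the perturbed-uniform initialization, accumulated
# patient by patient so no full assignment table is ever materialized.
.init_global_stats <- function(corpus, K, seed) {
  D <- corpus$D
  T_ <- length(corpus$W); L <- length(corpus$V)
  n_jk <- matrix(0, D, K); m_jk <- matrix(0, D, K)
  n_wk <- lapply(seq_len(T_), function(t) matrix(0, corpus$W[t], K))
  m_lkv <- lapply(seq_len(L), function(l) matrix(0, K, corpus$V[l]))
  p <- matrix(0, max(L, 0L), K); q <- matrix(0, max(L, 0L), K)
  tok <- corpus$counts; lb <- corpus$labs
  miss <- .missing_pairs(corpus)
  for (j in seq_len(D)) {
    ti <- which(tok$patient == j)
    oi <- which(lb$patient == j)
    ini <- .patient_local_init(seed, j, length(ti), length(oi), K)
    if (length(ti)) {
      cg <- ini$gamma * tok$count[ti]
      n_jk[j, ] <- colSums(cg)
      for (r in seq_along(ti)) {
        t <- tok$type[ti[r]]; w <- tok$feature[ti[r]]
        n_wk[[t]][w, ] <- n_wk[[t]][w, ] + cg[r, ]
      }
    }
    if (length(oi)) {
      yl <- ini$lambda * lb$freq[oi]
      m_jk[j, ] <- m_jk[j, ] + colSums(yl)
      for (r in seq_along(oi)) {
        l <- lb$lab[oi[r]]; v <- lb$state[oi[r]]
        m_lkv[[l]][, v] <- m_lkv[[l]][, v] + yl[r, ]
        p[l, ] <- p[l, ] + yl[r, ]
      }
    }
    mi <- which(miss$patient == j)
    for (r in mi) {
      l <- miss$lab[r]; Vl <- corpus$V[l]
      m_jk[j, ] <- m_jk[j, ] + 1 / K
      m_lkv[[l]] <- m_lkv[[l]] + 1 / (K * Vl)
      q[l, ] <- q[l, ] + 1 / K
    }
  }
  list(n_jk = n_jk, n_wk = n_wk, m_jk = m_jk, m_lkv = m_lkv, p = p, q = q)
}

# Local state for one minibatch: corpus records restricted to the batch,
# fresh per-patient initial assignments (same RNG stream as
# initialize_state), working statistics = global statistics with the
# batch patients' local masses substituted.
.batch_substate <- function(corpus, batch, K, seed, global) {
  inb <- logical(corpus$D); inb[batch] <- TRUE
  tok <- corpus$counts[inb[corpus$counts$patient], , drop = FALSE]
  obs <- corpus$labs[inb[corpus$labs$patient], , drop = FALSE]
  rownames(tok) <- rownames(obs) <- NULL
  miss_all <- .missing_pairs(corpus)
  miss <- miss_all[inb[miss_all$patient], , drop = FALSE]
  rownames(miss) <- NULL
  gamma <- matrix(0, nrow(tok), K)
  lambda <- matrix(0, nrow(obs), K)
  for (j in batch) {
    ti <- which(tok$patient == j)
    oi <- which(obs$patient == j)
    ini <- .patient_local_init(seed, j, length(ti), length(oi), K)
    if (length(ti)) gamma[ti, ] <- ini$gamma
    if (length(oi)) lambda[oi, ] <- ini$lambda
  }
  blk <- if (nrow(miss)) K * corpus$V[miss$lab] else integer(0)
  pi_off <- c(0L, cumsum(blk))[seq_len(max(nrow(miss), 0L))]
  pi_flat <- if (length(blk)) unlist(lapply(blk, function(n) rep(1 / n, n)),
                                     use.names = FALSE) else numeric(0)
  st <- structure(list(K = as.integer(K), D = corpus$D, W = corpus$W,
                       V = corpus$V, tok = tok, gamma = gamma, obs = obs,
                       lambda = lambda, miss = miss, pi = pi_flat,
                       pi_off = pi_off, M = NULL, stats = NULL),
                  class = "mixehr_state")
  local <- minibatch_statistics(st, batch, scale = FALSE)
  n_jk <- global$n_jk; n_jk[batch, ] <- local$n_jk[batch, ]
  m_jk <- global$m_jk; m_jk[batch, ] <- local$m_jk[batch, ]
  st$stats <- list(n_jk = n_jk, n_wk = global$n_wk, m_jk = m_jk,
                   m_lkv = global$m_lkv, p = global$p, q = global$q)
  st
}

#' Fit the topic model by stochastic collapsed variational inference
#'
#' Constant-memory training: each epoch shuffles the patients into
#' minibatches of `D'`; for each minibatch, local assignments are freshly
#' initialized and updated by [e_step()] sweeps against the current global
#' statistics, the batch sums are scaled to full-corpus size
#' ([minibatch_statistics()]), and the global feature/lab statistics are
#' moved toward them by natural-gradient interpolation ([scvb_step()]),
#' the lab observation Beta statistics included.  Assignments of
#' out-of-batch patients are never materialized.  With `D' = D`,
#' `rho = 1` and one local sweep, an epoch reproduces one batch JCVB
#' sweep exactly.
#'
#' @param corpus a [mixehr_corpus()].
#' @param K number of topics.
#' @param control an [scvb_control()].
#' @param hyper starting hyperparameters; default [default_hyper()].
#' @return object of class `mixehr_fit` with `estimates`, `hyper`, `trace`
#'   (per-epoch monitored predictive log-likelihood on a fixed seeded
#'   patient subset) and `stats` (the final global statistics). No
#'   per-record assignments are retained.
#' @export
fit_scvb <- function(corpus, K, control, hyper = NULL) {
  if (is.null(hyper)) hyper <- default_hyper(K, corpus)
  D <- corpus$D
  if (control$batch_size < 1L || control$batch_size > D)
    stop("batch_size must lie in 1..D")
  global <- .init_global_stats(corpus, K, control$seed)
  set.seed(control$seed)
  monitor <- sort(sample.int(D, min(control$monitor_size, D)))
  mon_rec <- lapply(monitor, function(j) patient_record(corpus, j))
  trace <- data.frame(epoch = integer(0), loglik = numeric(0))
  step <- 0L
  max_local_rows <- 0L
  ll_of <- function(est) {
    th <- do.call(rbind, lapply(mon_rec, function(rec)
      infer_patient_mixture(est, rec, sweeps = 5L)))
    sub <- mixehr_corpus(
      corpus$counts[corpus$counts$patient %in% monitor, , drop = FALSE],
      corpus$labs[corpus$labs$patient %in% monitor, , drop = FALSE],
      corpus$D, corpus$W, corpus$V)
    idx <- integer(corpus$D); idx[monitor] <- seq_along(monitor)
    theta_full <- matrix(1 / K, corpus$D, K)
    theta_full[monitor, ] <- th
    .corpus_loglik(est, sub, theta_full, control$lab_loglik)
  }
  mkstate <- function() {
    structure(list(K = as.integer(K), D = D, W = corpus$W, V = corpus$V,
                   stats = global),
              class = "mixehr_state")
  }
  est <- estimate_parameters(mkstate(), hyper, control$include_lab_mass)
  trace <- rbind(trace, data.frame(epoch = 0L, loglik = ll_of(est)))
  for (ep in seq_len(control$iterations)) {
    set.seed((control$seed + 7907L * ep) %% 2147483647L)
    perm <- sample.int(D)
    starts <- seq(1L, D, by = control$batch_size)
    for (b in starts) {
      batch <- sort(perm[b:min(b + control$batch_size - 1L, D)])
      step <- step + 1L
      rho <- if (!is.null(control$rho_schedule))
        (step + control$rho_schedule[1L])^(-control$rho_schedule[2L])
      else control$rho
      sub <- .batch_substate(corpus, batch, K, control$seed, global)
      max_local_rows <- max(max_local_rows, nrow(sub$gamma))
      for (sw in seq_len(control$local_sweeps))
        sub <- e_step(sub, hyper, patients = batch)
      mb <- minibatch_statistics(sub, batch, n_patients = D,
                                 scale = control$scale)
      global$n_wk <- lapply(seq_along(global$n_wk), function(t)
        (1 - rho) * global$n_wk[[t]] + rho * mb$n_hat[[t]])
      global$m_lkv <- lapply(seq_along(global$m_lkv), function(l)
        (1 - rho) * global$m_lkv[[l]] + rho * mb$m_hat[[l]])
      global$p <- (1 - rho) * global$p + rho * mb$p_hat
      global$q <- (1 - rho) * global$q + rho * mb$q_hat
      global$n_jk[batch, ] <- mb$n_jk[batch, ]
      global$m_jk[batch, ] <- mb$m_jk[batch, ]
    }
    if (control$hyperupdate_every > 0L &&
        ep %% control$hyperupdate_every == 0L)
      hyper <- update_hyperparameters(mkstate(), hyper)
    est <- estimate_parameters(mkstate(), hyper, control$include_lab_mass)
    ll <- trace_ll <- ll_of(est)
    if (!is.finite(ll))
      stop("divergence: non-finite monitored likelihood at epoch ", ep)
    trace <- rbind(trace, data.frame(epoch = ep, loglik = ll))
  }
  structure(list(estimates = est, hyper = hyper, trace = trace,
                 stats = global, K = K, control = control,
                 max_local_rows = max_local_rows),
            class = "mixehr_fit")
}
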