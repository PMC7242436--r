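#' Loop-literal reference oracles
#'
#' Independent brute-force implementations of the collapsed model's
#' sufficient statistics, update rules and marginal likelihood, written as
#' plain nested loops over records with no caching, no vectorization and
#' no code shared with the optimized inference path.  They exist to
#' cross-validate the fast implementation on tiny instances and are used
#' throughout the test suite (and by [mixehr_selftest()]).
#'
#' @name oracles
NULL

#' Hard-assignment sufficient statistics
#'
#' Literal evaluation of the collapsed model's count statistics from hard
#' topic assignments: token counts `n_jk` / `n_wk` per type, lab result
#' counts `m_jk` / `m_lkv`, and the Beta observation masses `p` (observed
#' pairs, weighted by total result frequency) and `q` (unobserved pairs).
#'
#' @param corpus a [mixehr_corpus()].
#' @param z integer vector of topic assignments aligned with the token
#'   instances of `corpus$counts` expanded by `count`, in row order.
#' @param h `L x D` integer matrix of lab topic assignments (used for all
#'   pairs, observed or not).
#' @return list with `n_jk`, `n_wk`, `m_jk`, `m_lkv`, `p`, `q`.
#' @export
oracle_suffstats <- function(corpus, z, h) {
  K <- max(c(1L, z, as.integer(h)))
  D <- corpus$D
  T_ <- length(corpus$W)
  L <- length(corpus$V)
  n_jk <- matrix(0, D, K)
  n_wk <- lapply(seq_len(T_), function(t) matrix(0, corpus$W[t], K))
  pos <- 0L
  for (r in seq_len(nrow(corpus$counts))) {
    j <- corpus$counts$patient[r]; t <- corpus$counts$type[r]
    w <- corpus$counts$feature[r]
    for (rep_i in seq_len(corpus$counts$count[r])) {
      pos <- pos + 1L
      k <- z[pos]
      n_jk[j, k] <- n_jk[j, k] + 1
      n_wk[[t]][w, k] <- n_wk[[t]][w, k] + 1
    }
  }
  m_jk <- matrix(0, D, K)
  m_lkv <- lapply(seq_len(L), function(l) matrix(0, K, corpus$V[l]))
  p <- matrix(0, max(L, 0L), K)
  q <- matrix(0, max(L, 0L), K)
  for (l in seq_len(L)) {
    for (j in seq_len(D)) {
      k <- h[l, j]
      if (corpus$r[l, j] == 1L) {
        ytot <- 0
        for (rr in seq_len(nrow(corpus$labs))) {
          if (corpus$labs$patient[rr] == j && corpus$labs$lab[rr] == l) {
            v <- corpus$labs$state[rr]; y <- corpus$labs$freq[rr]
            m_jk[j, k] <- m_jk[j, k] + y
            m_lkv[[l]][k, v] <- m_lkv[[l]][k, v] + y
            ytot <- ytot + y
          }
        }
        p[l, k] <- p[l, k] + ytot
      } else {
        q[l, k] <- q[l, k] + 1
      }
    }
  }
  list(n_jk = n_jk, n_wk = n_wk, m_jk = m_jk, m_lkv = m_lkv, p = p, q = q)
}

#' Soft (expected) sufficient statistics by quadruple loops
#'
#' Literal summation of the variational expectations of the sufficient
#' statistics from the assignment tables of a state: token masses from
#' `gamma` (count-weighted), observed lab masses from `lambda`
#' (frequency-weighted), unobserved masses from `pi`.  The reference for
#' [refresh_statistics()].
#'
#' @param state a [mixehr_state].
#' @return list with `n_jk`, `n_wk`, `m_jk`, `m_lkv`, `p`, `q`.
#' @export
oracle_soft_suffstats <- function(state) {
  K <- state$K; D <- state$D
  T_ <- length(state$W); L <- length(state$V)
  n_jk <- matrix(0, D, K)
  n_wk <- lapply(seq_len(T_), function(t) matrix(0, state$W[t], K))
  for (r in seq_len(nrow(state$tok))) {
    j <- state$tok$patient[r]; t <- state$tok$type[r]
    w <- state$tok$feature[r]; cc <- state$tok$count[r]
    for (k in seq_len(K)) {
      n_jk[j, k] <- n_jk[j, k] + cc * state$gamma[r, k]
      n_wk[[t]][w, k] <- n_wk[[t]][w, k] + cc * state$gamma[r, k]
    }
  }
  m_jk <- matrix(0, D, K)
  m_lkv <- lapply(seq_len(L), function(l) matrix(0, K, state$V[l]))
  p <- matrix(0, max(L, 0L), K)
  q <- matrix(0, max(L, 0L), K)
  for (r in seq_len(nrow(state$obs))) {
    j <- state$obs$patient[r]; l <- state$obs$lab[r]
    v <- state$obs$state[r]; y <- state$obs$freq[r]
    for (k in seq_len(K)) {
      m_jk[j, k] <- m_jk[j, k] + y * state$lambda[r, k]
      m_lkv[[l]][k, v] <- m_lkv[[l]][k, v] + y * state$lambda[r, k]
      p[l, k] <- p[l, k] + y * state$lambda[r, k]
    }
  }
  for (r in seq_len(nrow(state$miss))) {
    j <- state$miss$patient[r]; l <- state$miss$lab[r]
    for (v in seq_len(state$V[l])) {
      for (k in seq_len(K)) {
        pival <- state$pi[state$pi_off[r] + (v - 1L) * K + k]
        m_jk[j, k] <- m_jk[j, k] + pival
        m_lkv[[l]][k, v] <- m_lkv[[l]][k, v] + pival
        q[l, k] <- q[l, k] + pival
      }
    }
  }
  list(n_jk = n_jk, n_wk = n_wk, m_jk = m_jk, m_lkv = m_lkv, p = p, q = q)
}

#' Loop-literal single-record update
#'
#' Term-by-term scalar evaluation of the CVB0 update of one record, with
#' every exclusion statistic recomputed by explicit summation over all
#' other records' current assignments (no caches).  The reference for
#' [update_gamma()], [update_lambda()], [update_pi()] and the compiled
#' sweep.
#'
#' @param state a [mixehr_state] (only its assignment tables are read).
#' @param hyper a [mixehr_hyper()].
#' @param record `c(j, t, w)` for `"gamma"`, `c(j, l, v)` for `"lambda"`,
#'   `c(j, l)` for `"pi"`.
#' @param which one of `"gamma"`, `"lambda"`, `"pi"`.
#' @return normalized `K`-vector, or `K x V[l]` matrix for `"pi"`.
#' @export
oracle_update <- function(state, hyper, record,
                          which = c("gamma", "lambda", "pi")) {
  which <- match.arg(which)
  K <- state$K
  alpha <- hyper$alpha
  j <- record[1L]
  # patient j's lab mass, optionally excluding one lab entirely
  lab_mass <- function(excl_lab) {
    m <- numeric(K)
    for (r in seq_len(nrow(state$obs))) {
      if (state$obs$patient[r] != j || state$obs$lab[r] == excl_lab) next
      for (k in seq_len(K))
        m[k] <- m[k] + state$obs$freq[r] * state$lambda[r, k]
    }
    for (r in seq_len(nrow(state$miss))) {
      if (state$miss$patient[r] != j || state$miss$lab[r] == excl_lab) next
      l2 <- state$miss$lab[r]
      for (v in seq_len(state$V[l2]))
        for (k in seq_len(K))
          m[k] <- m[k] + state$pi[state$pi_off[r] + (v - 1L) * K + k]
    }
    m
  }
  if (which == "gamma") {
    t <- record[2L]; w <- record[3L]
    i <- base::which(state$tok$patient == j & state$tok$type == t &
               state$tok$feature == w)
    n_ex <- numeric(K); nw_ex <- numeric(K); nk_ex <- numeric(K)
    for (r in seq_len(nrow(state$tok))) {
      if (r == i) next
      cc <- state$tok$count[r]
      for (k in seq_len(K)) {
        if (state$tok$patient[r] == j)
          n_ex[k] <- n_ex[k] + cc * state$gamma[r, k]
        if (state$tok$type[r] == t) {
          nk_ex[k] <- nk_ex[k] + cc * state$gamma[r, k]
          if (state$tok$feature[r] == w)
            nw_ex[k] <- nw_ex[k] + cc * state$gamma[r, k]
        }
      }
    }
    m_jk <- lab_mass(excl_lab = 0L)
    val <- numeric(K)
    for (k in seq_len(K))
      val[k] <- (alpha[k] + n_ex[k] + m_jk[k]) *
        (hyper$beta[[t]][w] + nw_ex[k]) /
        (sum(hyper$beta[[t]]) + nk_ex[k])
    return(val / sum(val))
  }
  l <- record[2L]
  # full token mass of patient j (no exclusion in the lab updates)
  n_jk <- numeric(K)
  for (r in seq_len(nrow(state$tok))) {
    if (state$tok$patient[r] != j) next
    for (k in seq_len(K))
      n_jk[k] <- n_jk[k] + state$tok$count[r] * state$gamma[r, k]
  }
  # per-state lab-l masses excluding one record's own contribution
  m_lkv_excl <- function(skip_obs, skip_miss_entry) {
    m <- matrix(0, K, state$V[l])
    for (r in seq_len(nrow(state$obs))) {
      if (state$obs$lab[r] != l || r == skip_obs) next
      v2 <- state$obs$state[r]
      for (k in seq_len(K))
        m[k, v2] <- m[k, v2] + state$obs$freq[r] * state$lambda[r, k]
    }
    for (r in seq_len(nrow(state$miss))) {
      if (state$miss$lab[r] != l) next
      for (v2 in seq_len(state$V[l]))
        for (k in seq_len(K)) {
          if (!is.null(skip_miss_entry) && r == skip_miss_entry$r &&
              v2 == skip_miss_entry$v && k == skip_miss_entry$k) next
          m[k, v2] <- m[k, v2] + state$pi[state$pi_off[r] + (v2 - 1L) * K + k]
        }
    }
    m
  }
  p_full <- numeric(K); q_full <- numeric(K)
  p_ex <- numeric(K); q_ex <- numeric(K)
  for (r in seq_len(nrow(state$obs))) {
    if (state$obs$lab[r] != l) next
    for (k in seq_len(K)) {
      add <- state$obs$freq[r] * state$lambda[r, k]
      p_full[k] <- p_full[k] + add
      if (state$obs$patient[r] != j) p_ex[k] <- p_ex[k] + add
    }
  }
  for (r in seq_len(nrow(state$miss))) {
    if (state$miss$lab[r] != l) next
    for (v2 in seq_len(state$V[l]))
      for (k in seq_len(K)) {
        add <- state$pi[state$pi_off[r] + (v2 - 1L) * K + k]
        q_full[k] <- q_full[k] + add
        if (state$miss$patient[r] != j) q_ex[k] <- q_ex[k] + add
      }
  }
  m_jk_ex <- lab_mass(excl_lab = l)
  if (which == "lambda") {
    v <- record[3L]
    i <- base::which(state$obs$patient == j & state$obs$lab == l &
               state$obs$state == v)
    val <- numeric(K)
    for (k in seq_len(K)) {
      m_ex <- m_lkv_excl(skip_obs = i, skip_miss_entry = NULL)
      denom <- 0
      for (v2 in seq_len(state$V[l]))
        denom <- denom + hyper$zeta[[l]][v2] + m_ex[k, v2]
      val[k] <- (alpha[k] + n_jk[k] + m_jk_ex[k]) *
        (hyper$zeta[[l]][v] + m_ex[k, v]) / denom *
        (hyper$a[l] + p_ex[k]) /
        (hyper$a[l] + p_ex[k] + hyper$b[l] + q_full[k])
    }
    return(val / sum(val))
  }
  # which == "pi"
  i <- base::which(state$miss$patient == j & state$miss$lab == l)
  Vl <- state$V[l]
  val <- matrix(0, K, Vl)
  for (v in seq_len(Vl)) {
    for (k in seq_len(K)) {
      m_ex <- m_lkv_excl(skip_obs = 0L,
                         skip_miss_entry = list(r = i, v = v, k = k))
      denom <- 0
      for (v2 in seq_len(Vl))
        denom <- denom + hyper$zeta[[l]][v2] + m_ex[k, v2]
      val[k, v] <- (alpha[k] + n_jk[k] + m_jk_ex[k]) *
        (hyper$zeta[[l]][v] + m_ex[k, v]) / denom *
        (hyper$b[l] + q_ex[k]) /
        (hyper$a[l] + p_full[k] + hyper$b[l] + q_ex[k])
    }
  }
  val / sum(val)
}

#' Loop-literal full E-step sweep
#'
#' Applies [oracle_update()] to every record in the same deterministic
#' order as the compiled sweep (patients ascending; per patient: token
#' records, observed lab records, unobserved pairs), updating the
#' assignment tables in place so later records see earlier updates.
#' Exclusion statistics are recomputed from the tables at every record.
#'
#' @param state a [mixehr_state].
#' @param hyper a [mixehr_hyper()].
#' @return the state with updated `gamma`, `lambda`, `pi` (its cached
#'   `stats` are untouched and stale; the fast path is compared on the
#'   assignment tables and on [oracle_soft_suffstats()]).
#' @export
oracle_e_step <- function(state, hyper) {
  K <- state$K
  for (j in seq_len(state$D)) {
    for (r in which(state$tok$patient == j)) {
      state$gamma[r, ] <- oracle_update(
        state, hyper,
        c(j, state$tok$type[r], state$tok$feature[r]), "gamma")
    }
    for (r in which(state$obs$patient == j)) {
      state$lambda[r, ] <- oracle_update(
        state, hyper,
        c(j, state$obs$lab[r], state$obs$state[r]), "lambda")
    }
    for (r in which(state$miss$patient == j)) {
      B <- oracle_update(state, hyper, c(j, state$miss$lab[r]), "pi")
      Vl <- state$V[state$miss$lab[r]]
      for (v in seq_len(Vl))
        for (k in seq_len(K))
          state$pi[state$pi_off[r] + (v - 1L) * K + k] <- B[k, v]
    }
  }
  state
}

#' Collapsed joint log-likelihood from hard assignments
#'
#' Literal log-space evaluation of the closed-form collapsed joint
#' distribution of the data and hard topic assignments — the product of
#' Dirichlet-multinomial and Beta-binomial Gamma-function ratios — used to
#' verify the hyperparameter fixed points and to sanity-check that
#' better-fitting assignments score higher.
#'
#' @param corpus a [mixehr_corpus()].
#' @param z,h hard assignments as in [oracle_suffstats()].
#' @param hyper a [mixehr_hyper()].
#' @return scalar log-likelihood.
#' @export
oracle_collapsed_loglik <- function(corpus, z, h, hyper) {
  .check_hyper(hyper)
  K <- length(hyper$alpha)
  s <- oracle_suffstats(corpus, z, h)
  # pad statistics to K topics if the assignments used fewer
  pad <- function(m, K) {
    if (ncol(m) < K) cbind(m, matrix(0, nrow(m), K - ncol(m))) else m
  }
  n_jk <- pad(s$n_jk, K); m_jk <- pad(s$m_jk, K)
  ll <- 0
  for (j in seq_len(corpus$D)) {
    ll <- ll + lgamma(sum(hyper$alpha)) - sum(lgamma(hyper$alpha))
    tot <- 0
    for (k in seq_len(K)) {
      cnt <- n_jk[j, k] + m_jk[j, k]
      ll <- ll + lgamma(hyper$alpha[k] + cnt)
      tot <- tot + cnt
    }
    ll <- ll - lgamma(sum(hyper$alpha) + tot)
  }
  for (t in seq_along(hyper$beta)) {
    bt <- hyper$beta[[t]]
    nw <- pad(s$n_wk[[t]], K)
    for (k in seq_len(K)) {
      ll <- ll + lgamma(sum(bt)) - sum(lgamma(bt)) +
        sum(lgamma(bt + nw[, k])) - lgamma(sum(bt) + sum(nw[, k]))
    }
  }
  for (l in seq_along(hyper$zeta)) {
    zl <- hyper$zeta[[l]]
    ml <- s$m_lkv[[l]]
    if (nrow(ml) < K) ml <- rbind(ml, matrix(0, K - nrow(ml), ncol(ml)))
    pl <- pad(s$p, K); ql <- pad(s$q, K)
    for (k in seq_len(K)) {
      ll <- ll + lgamma(sum(zl)) - sum(lgamma(zl)) +
        sum(lgamma(zl + ml[k, ])) - lgamma(sum(zl) + sum(ml[k, ]))
      ll <- ll + lgamma(hyper$a[l] + hyper$b[l]) - lgamma(hyper$a[l]) -
        lgamma(hyper$b[l]) + lgamma(hyper$a[l] + pl[l, k]) +
        lgamma(hyper$b[l] + ql[l, k]) -
        lgamma(hyper$a[l] + pl[l, k] + hyper$b[l] + ql[l, k])
    }
  }
  ll
}

#' Collapsed marginal-likelihood term of one Dirichlet family
#'
#' The part of the collapsed log-likelihood that depends on one Dirichlet
#' concentration vector, given its (possibly expected) count matrix, plus
#' the Gamma hyper-prior log-density terms — the 1-D objective whose
#' coordinate-wise maximum the empirical-Bayes fixed point
#' ([update_hyperparameters()]) attains.
#'
#' @param conc concentration vector (length `n_components`).
#' @param counts `n_components x n_groups` count matrix.
#' @param prior `(shape, rate)` of the Gamma hyper-prior.
#' @return scalar objective value.
#' @export
oracle_dirichlet_objective <- function(conc, counts, prior) {
  val <- 0
  for (g in seq_len(ncol(counts))) {
    val <- val + lgamma(sum(conc)) - sum(lgamma(conc)) +
      sum(lgamma(conc + counts[, g])) - lgamma(sum(conc) + sum(counts[, g]))
  }
  val + sum((prior[["shape"]] - 1) * log(conc) - prior[["rate"]] * conc)
}

#' Run the oracle cross-validation suite
#'
#' Compares the optimized inference path with the loop-literal oracles on
#' the fixed tiny fixture: statistics refresh vs quadruple-loop sums, one
#' full compiled E-step vs the loop-literal sweep, and single-record
#' updates vs term-by-term evaluation.
#'
#' @param seed seed for the state initialization (default 42).
#' @return data.frame with columns `op`, `max_dev`, `instance`, `pass`.
#' @export
mixehr_selftest <- function(seed = 42L) {
  fx <- make_fixture()
  K <- 2L
  hyper <- mixehr_hyper(alpha = c(0.8, 1.2),
                        beta = list(c(0.5, 0.4, 0.3, 0.2, 0.1),
                                    c(0.3, 0.3, 0.2, 0.2)),
                        zeta = list(c(0.7, 0.5), c(0.4, 0.6)),
                        a = c(1.5, 0.8), b = c(0.9, 1.1))
  st <- initialize_state(fx$corpus, K, seed)
  rows <- list()
  add <- function(op, dev, inst, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      op = op, max_dev = dev, instance = inst, pass = dev < tol)
  }
  oso <- oracle_soft_suffstats(st)
  dev <- max(abs(oso$n_jk - st$stats$n_jk), abs(oso$m_jk - st$stats$m_jk),
             abs(oso$p - st$stats$p), abs(oso$q - st$stats$q),
             max(mapply(function(a, b) max(abs(a - b)), oso$n_wk, st$stats$n_wk)),
             max(mapply(function(a, b) max(abs(a - b)), oso$m_lkv, st$stats$m_lkv)))
  add("refresh_statistics", dev, "fixture, K=2", 1e-10)
  devs <- c(
    max(abs(update_gamma(st, hyper, c(1, 1, 1)) -
              oracle_update(st, hyper, c(1, 1, 1), "gamma"))),
    max(abs(update_lambda(st, hyper, c(2, 1, 2)) -
              oracle_update(st, hyper, c(2, 1, 2), "lambda"))),
    max(abs(update_pi(st, hyper, c(3, 1)) -
              oracle_update(st, hyper, c(3, 1), "pi"))))
  add("single_record_updates", max(devs), "3 records on fixture", 1e-10)
  fast <- e_step(st, hyper)
  slow <- oracle_e_step(st, hyper)
  dev <- max(abs(fast$gamma - slow$gamma), abs(fast$lambda - slow$lambda),
             abs(fast$pi - slow$pi))
  add("e_step_sweep", dev, "one full sweep on fixture", 1e-10)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
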