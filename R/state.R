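#' Variational state of the collapsed inference
#'
#' Internal representation (class `mixehr_state`):
#' \itemize{
#'   \item `tok`: the distinct count records `(j, t, w, c)` in sweep order
#'     (patient-major); `gamma` holds one row of `K` assignment
#'     probabilities per record, shared by the `c` identical tokens.
#'   \item `obs`: observed lab records `(j, l, v, y)`; `lambda` holds one
#'     row of `K` probabilities per record.
#'   \item `miss`: unobserved `(j, l)` pairs; `pi` is a flat vector of
#'     `K x V[l]` joint topic-result blocks (entry `(k, v)` of pair `i`
#'     sits at `pi[pi_off[i] + (v-1)*K + k]`), each block summing to 1.
#'   \item `stats`: cached sufficient statistics — token masses `n_jk`
#'     (`D x K`) and `n_wk[[t]]` (`W[t] x K`), lab masses `m_jk` (`D x K`)
#'     and `m_lkv[[l]]` (`K x V[l]`), and the Beta masses `p` / `q`
#'     (`L x K`, observed / unobserved).
#' }
#' @name mixehr_state
NULL

.patient_local_init <- function(seed, j, n_tok, n_obs, K) {
  # Per-patient RNG stream so batch (stochastic) and full-state
  # initialization agree record-for-record at equal seeds.
  set.seed((as.integer(seed) + j * 131071L) %% 2147483647L)
  eps <- 0.1 / K
  g <- l <- NULL
  if (n_tok > 0L) {
    g <- matrix(stats::runif(n_tok * K, 1 / K - eps, 1 / K + eps), nrow = n_tok)
    g <- g / rowSums(g)
  }
  if (n_obs > 0L) {
    l <- matrix(stats::runif(n_obs * K, 1 / K - eps, 1 / K + eps), nrow = n_obs)
    l <- l / rowSums(l)
  }
  list(gamma = g, lambda = l)
}

#' Initialize the variational state
#'
#' Token and observed-lab assignment probabilities are drawn as normalized
#' positive perturbations of the uniform distribution (entries uniform in
#' `[1/K - 0.1/K, 1/K + 0.1/K]` before normalization); the joint
#' topic-result distributions of unobserved labs start uniform over
#' `K x V[l]`.  All cached sufficient statistics are computed from these
#' assignments, so every state invariant holds at initialization.
#' Deterministic given `seed`.
#'
#' @param corpus a [mixehr_corpus()].
#' @param K number of topics (>= 1).
#' @param seed integer RNG seed.
#' @return a [mixehr_state] object.
#' @export
initialize_state <- function(corpus, K, seed) {
  if (K < 1L) stop("K must be >= 1")
  D <- corpus$D
  L <- length(corpus$V)
  tok <- corpus$counts
  obs <- corpus$labs
  names(obs) <- c("patient", "lab", "state", "freq")
  miss <- .missing_pairs(corpus)
  gamma <- matrix(0, nrow = nrow(tok), ncol = K)
  lambda <- matrix(0, nrow = nrow(obs), ncol = K)
  for (j in seq_len(D)) {
    ti <- which(tok$patient == j)
    oi <- which(obs$patient == j)
    ini <- .patient_local_init(seed, j, length(ti), length(oi), K)
    if (length(ti)) gamma[ti, ] <- ini$gamma
    if (length(oi)) lambda[oi, ] <- ini$lambda
  }
  blk <- if (nrow(miss)) K * corpus$V[miss$lab] else integer(0)
  pi_off <- c(0L, cumsum(blk))
  pi <- numeric(sum(blk))
  if (nrow(miss))
    pi <- unlist(lapply(seq_len(nrow(miss)), function(i)
      rep(1 / blk[i], blk[i])), use.names = FALSE)
  st <- structure(list(K = as.integer(K), D = D, W = corpus$W, V = corpus$V,
                       tok = tok, gamma = gamma, obs = obs, lambda = lambda,
                       miss = miss, pi = pi,
                       pi_off = pi_off[seq_len(max(nrow(miss), 0L))],
                       M = token_totals(corpus), stats = NULL),
                  class = "mixehr_state")
  refresh_statistics(st, corpus)
}

.missing_pairs <- function(corpus) {
  L <- length(corpus$V)
  if (L == 0L || corpus$D == 0L)
    return(data.frame(patient = integer(0), lab = integer(0)))
  idx <- which(corpus$r == 0L, arr.ind = TRUE)  # rows: (lab, patient)
  miss <- data.frame(patient = idx[, 2L], lab = idx[, 1L])
  miss <- miss[order(miss$patient, miss$lab), , drop = FALSE]
  rownames(miss) <- NULL
  miss
}

#' Recompute all cached sufficient statistics from scratch
#'
#' Replaces the incrementally maintained caches by exact sums over the
#' current assignments: token masses from `gamma` (count-weighted),
#' observed lab masses from `lambda` (frequency-weighted), unobserved
#' masses from `pi`.  Run once per sweep to cancel floating-point drift of
#' the incremental bookkeeping.
#'
#' @param state a [mixehr_state].
#' @param corpus the corpus the state was built from (supplies dimensions).
#' @return the state with fresh `stats`.
#' @export
refresh_statistics <- function(state, corpus) {
  K <- state$K; D <- state$D
  T_ <- length(state$W); L <- length(state$V)
  lev_j <- seq_len(D)
  n_jk <- matrix(0, D, K)
  if (nrow(state$tok)) {
    cg <- state$gamma * state$tok$count
    n_jk <- .rowsum_full(cg, state$tok$patient, D)
  }
  n_wk <- lapply(seq_len(T_), function(t) {
    it <- which(state$tok$type == t)
    if (!length(it)) return(matrix(0, state$W[t], K))
    .rowsum_full(state$gamma[it, , drop = FALSE] * state$tok$count[it],
                 state$tok$feature[it], state$W[t])
  })
  m_jk <- matrix(0, D, K)
  p <- matrix(0, max(L, 0L), K)
  q <- matrix(0, max(L, 0L), K)
  m_lkv <- lapply(seq_len(L), function(l) matrix(0, K, state$V[l]))
  if (nrow(state$obs)) {
    yl <- state$lambda * state$obs$freq
    m_jk <- m_jk + .rowsum_full(yl, state$obs$patient, D)
    p <- .rowsum_full(yl, state$obs$lab, L)
    for (l in seq_len(L)) {
      il <- which(state$obs$lab == l)
      if (!length(il)) next
      m_lkv[[l]] <- t(.rowsum_full(yl[il, , drop = FALSE],
                                   state$obs$state[il], state$V[l]))
    }
  }
  if (nrow(state$miss)) {
    for (l in seq_len(L)) {
      il <- which(state$miss$lab == l)
      if (!length(il)) next
      Vl <- state$V[l]
      blkidx <- outer(state$pi_off[il], seq_len(K * Vl), `+`)
      P <- matrix(state$pi[blkidx], nrow = length(il))
      m_lkv[[l]] <- m_lkv[[l]] + matrix(colSums(P), nrow = K)
      kmass <- sapply(seq_len(K), function(k)
        rowSums(P[, k + K * (seq_len(Vl) - 1L), drop = FALSE]))
      kmass <- matrix(kmass, nrow = length(il))
      m_jk <- m_jk + .rowsum_full(kmass, state$miss$patient[il], D)
      q[l, ] <- q[l, ] + colSums(kmass)
    }
  }
  state$stats <- list(n_jk = n_jk, n_wk = n_wk, m_jk = m_jk,
                      m_lkv = m_lkv, p = p, q = q)
  state
}

.rowsum_full <- function(x, group, nlev) {
  out <- matrix(0, nlev, ncol(x))
  rs <- rowsum(x, group = group)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Posterior-mean parameter estimates from a variational state
#'
#' Dirichlet/Beta posterior means under the collapsed model:
#' `theta[j,k] = (alpha_k + n_jk) / sum_k'(...)` where by default `n_jk`
#' includes both token mass and lab mass (configurable),
#' `phi[[t]][w,k] = (beta_wt + n_wk) / sum_w'(...)` (column-stochastic),
#' `eta[[l]][k,v] = (zeta_lv + m_lkv) / sum_v'(...)` (row-stochastic), and
#' `psi[l,k] = (a_l + p_lk) / (a_l + p_lk + b_l + q_lk)`.
#'
#' @param state a [mixehr_state] with fresh statistics.
#' @param hyper a [mixehr_hyper()].
#' @param include_lab_mass logical; include the lab-topic mass `m_jk` in the
#'   patient mixture estimate (default TRUE).
#' @return object of class `mixehr_estimates` with fields `theta`, `phi`,
#'   `eta`, `psi`, `hyper`, `include_lab_mass`.
#' @export
estimate_parameters <- function(state, hyper, include_lab_mass = TRUE) {
  s <- state$stats
  K <- state$K
  njk <- s$n_jk + if (include_lab_mass) s$m_jk else 0
  theta <- njk + matrix(rep(hyper$alpha, each = nrow(njk)), nrow(njk), K)
  theta <- theta / rowSums(theta)
  phi <- lapply(seq_along(state$W), function(t) {
    m <- s$n_wk[[t]] + hyper$beta[[t]]
    sweep(m, 2L, colSums(m), `/`)
  })
  L <- length(state$V)
  eta <- lapply(seq_len(L), function(l) {
    m <- s$m_lkv[[l]] +
      matrix(rep(hyper$zeta[[l]], each = K), K, state$V[l])
    m / rowSums(m)
  })
  psi <- if (L > 0L) (hyper$a + s$p) / (hyper$a + s$p + hyper$b + s$q)
         else matrix(0, 0L, K)
  structure(list(theta = theta, phi = phi, eta = eta, psi = psi,
                 hyper = hyper, include_lab_mass = include_lab_mass),
            class = "mixehr_estimates")
}

#' @export
print.mixehr_estimates <- function(x, ...) {
  cat("<mixehr_estimates> K=", ncol(x$theta), ", D=", nrow(x$theta),
      ", T=", length(x$phi), ", L=", length(x$eta), "\n", sep = "")
  invisible(x)
}
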