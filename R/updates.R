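#' Single-record CVB0 updates
#'
#' These compute the new assignment distribution of one record from the
#' current cached statistics, with the record's own (count-weighted)
#' contribution excluded and clipped at zero.  They are the unit-testable
#' surface of the update rules; [e_step()] applies the same arithmetic to
#' every record of the corpus in sweep order via the compiled kernel.
#'
#' @param state a [mixehr_state] with consistent statistics.
#' @param hyper a [mixehr_hyper()].
#' @param record for `update_gamma` a vector `c(j, t, w)`; for
#'   `update_lambda` a vector `c(j, l, v)`; for `update_pi` a vector
#'   `c(j, l)`.
#' @return `update_gamma`/`update_lambda`: a normalized `K`-vector;
#'   `update_pi`: a `K x V[l]` matrix summing to 1 over all entries.
#' @name cvb0_updates
NULL

#' @rdname cvb0_updates
#' @export
update_gamma <- function(state, hyper, record) {
  j <- record[1L]; t <- record[2L]; w <- record[3L]
  i <- which(state$tok$patient == j & state$tok$type == t &
             state$tok$feature == w)
  if (length(i) != 1L) stop("no such count record (", j, ",", t, ",", w, ")")
  s <- state$stats
  cg <- state$tok$count[i] * state$gamma[i, ]
  njk_ex <- pmax(s$n_jk[j, ] - cg, 0)
  nwk_ex <- pmax(s$n_wk[[t]][w, ] - cg, 0)
  nk_ex <- pmax(colSums(s$n_wk[[t]]) - cg, 0)
  val <- (hyper$alpha + njk_ex + s$m_jk[j, ]) *
    (hyper$beta[[t]][w] + nwk_ex) / (sum(hyper$beta[[t]]) + nk_ex)
  val / sum(val)
}

#' @rdname cvb0_updates
#' @export
update_lambda <- function(state, hyper, record) {
  j <- record[1L]; l <- record[2L]; v <- record[3L]
  gi <- which(state$obs$patient == j & state$obs$lab == l)
  if (!length(gi))
    stop("update_lambda called on unobserved lab pair (", l, ",", j, ")")
  i <- gi[state$obs$state[gi] == v]
  if (length(i) != 1L) stop("no such lab record (", j, ",", l, ",", v, ")")
  s <- state$stats
  y <- state$obs$freq[i]
  mass <- colSums(state$lambda[gi, , drop = FALSE] * state$obs$freq[gi])
  mjk_ex <- pmax(s$m_jk[j, ] - mass, 0)
  p_ex <- pmax(s$p[l, ] - mass, 0)
  mrow <- s$m_lkv[[l]]
  own <- y * state$lambda[i, ]
  mlkv_ex <- pmax(mrow[, v] - own, 0)
  denom <- sum(hyper$zeta[[l]]) + (rowSums(mrow) - mrow[, v]) + mlkv_ex
  val <- (hyper$alpha + s$n_jk[j, ] + mjk_ex) *
    (hyper$zeta[[l]][v] + mlkv_ex) / denom *
    (hyper$a[l] + p_ex) / (hyper$a[l] + p_ex + hyper$b[l] + s$q[l, ])
  val / sum(val)
}

#' @rdname cvb0_updates
#' @export
update_pi <- function(state, hyper, record) {
  j <- record[1L]; l <- record[2L]
  i <- which(state$miss$patient == j & state$miss$lab == l)
  if (length(i) != 1L)
    stop("update_pi called on observed lab pair (", l, ",", j, ")")
  s <- state$stats
  K <- state$K; Vl <- state$V[l]
  B <- matrix(state$pi[state$pi_off[i] + seq_len(K * Vl)], nrow = K)
  mass <- rowSums(B)
  mjk_ex <- pmax(s$m_jk[j, ] - mass, 0)
  q_ex <- pmax(s$q[l, ] - mass, 0)
  mrow <- s$m_lkv[[l]]
  Mex <- pmax(mrow - B, 0)
  denom <- (rowSums(mrow) - mrow) + Mex + sum(hyper$zeta[[l]])
  left <- hyper$alpha + s$n_jk[j, ] + mjk_ex
  right <- (hyper$b[l] + q_ex) / (hyper$a[l] + s$p[l, ] + hyper$b[l] + q_ex)
  zmat <- matrix(rep(hyper$zeta[[l]], each = K), K, Vl)
  val <- (left * right) * (Mex + zmat) / denom
  val / sum(val)
}
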