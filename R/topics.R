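#' Topic embedding of the codes of one data type
#'
#' Each code's embedding is its row of the fitted topic matrix `phi[[type]]`
#' — the probability of the code under each topic — optionally renormalized
#' to a distribution over topics.
#'
#' @param model a `mixehr_estimates`.
#' @param type data type index.
#' @param codes optional integer vector of feature indices (default all).
#' @param renormalize divide each row by its sum (default FALSE).
#' @return object of class `mixehr_embedding`: list with `codes` and the
#'   `length(codes) x K` matrix `vectors`.
#' @export
code_embedding <- function(model, type, codes = NULL, renormalize = FALSE) {
  phi <- model$phi[[type]]
  if (is.null(codes)) codes <- seq_len(nrow(phi))
  vec <- phi[codes, , drop = FALSE]
  if (renormalize) vec <- vec / rowSums(vec)
  structure(list(codes = codes, vectors = vec), class = "mixehr_embedding")
}

#' Pairwise Pearson correlation of code topic embeddings
#'
#' Codes whose embedding has zero variance across topics are dropped with
#' a warning (their correlation is undefined).
#'
#' @param embedding a [code_embedding()].
#' @return symmetric correlation matrix with unit diagonal, with
#'   `dimnames` set to the code indices.
#' @export
code_correlation_matrix <- function(embedding) {
  v <- embedding$vectors
  if (ncol(v) < 2L)
    stop("correlation across topics undefined for K < 2")
  sds <- apply(v, 1L, stats::sd)
  keep <- sds > 0
  if (any(!keep))
    warning("dropped ", sum(!keep), " zero-variance code(s)")
  v <- v[keep, , drop = FALSE]
  if (nrow(v) < 2L) stop("need at least 2 codes with nonzero variance")
  cc <- stats::cor(t(v))
  dimnames(cc) <- list(embedding$codes[keep], embedding$codes[keep])
  cc
}

#' Permutation significance of correlations with a target code
#'
#' The null distribution is built by shuffling the target code's topic
#' probabilities across topics and recomputing its correlation with every
#' other code; the (add-one) permutation p-value of code `s` is
#' `(1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)` for the two-sided test
#' (one-sided: `r_null >= r_obs`).
#'
#' @param embedding a [code_embedding()].
#' @param target_code the target code (a value of `embedding$codes`).
#' @param n_perm number of permutations (>= 1; default 999).
#' @param seed integer RNG seed.
#' @param sided `"two"` (default) or `"greater"`.
#' @param threshold display/flagging threshold on the p-value
#'   (default 0.01).
#' @return data.frame with columns `code`, `r`, `p`, `flagged`, one row
#'   per non-target code.
#' @export
permutation_significance <- function(embedding, target_code, n_perm = 999L,
                                     seed = 1L, sided = c("two", "greater"),
                                     threshold = 0.01) {
  sided <- match.arg(sided)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  ti <- match(target_code, embedding$codes)
  if (is.na(ti)) stop("target code not present in embedding")
  x <- embedding$vectors[ti, ]
  if (stats::sd(x) == 0) stop("zero-variance target code")
  others <- embedding$vectors[-ti, , drop = FALSE]
  ocodes <- embedding$codes[-ti]
  osd <- apply(others, 1L, stats::sd)
  if (any(osd == 0)) {
    warning("dropped ", sum(osd == 0), " zero-variance code(s)")
    others <- others[osd > 0, , drop = FALSE]
    ocodes <- ocodes[osd > 0]
  }
  robs <- as.numeric(stats::cor(x, t(others)))
  set.seed(as.integer(seed))
  K <- length(x)
  exceed <- integer(length(robs))
  for (s in seq_len(n_perm)) {
    rn <- as.numeric(stats::cor(x[sample.int(K)], t(others)))
    exceed <- exceed + if (sided == "two") (abs(rn) >= abs(robs))
                       else (rn >= robs)
  }
  p <- (1 + exceed) / (1 + n_perm)
  data.frame(code = ocodes, r = robs, p = p, flagged = p < threshold)
}
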