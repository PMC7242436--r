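#' Fold-in inference of a new patient's topic mixture
#'
#' Runs patient-local CVB0 updates for one patient against the frozen
#' global parameters of a trained model: token assignments use the topic
#' feature probabilities `phi`, observed lab assignments use `eta * psi`,
#' and (optionally) the patient's unobserved labs contribute their joint
#' topic-result distributions weighted by `1 - psi`.  Only the patient's
#' own topic masses are updated; the global statistics never change.
#'
#' A record with no observations of any kind is the degenerate case and
#' returns the prior mean `alpha / sum(alpha)` directly.
#'
#' @param model a `mixehr_estimates` (carries the hyperparameters).
#' @param record a patient record as returned by [patient_record()]: list
#'   with data.frames `tokens` (`type`, `feature`, `count`) and `labs`
#'   (`lab`, `state`, `freq`). Features outside the model vocabulary are
#'   skipped with a warning count.
#' @param sweeps number of local update sweeps (default 10).
#' @param use_missing_labs logical; let the patient's unobserved labs
#'   contribute mass through the non-missing-at-random mechanism
#'   (default TRUE, matching training).
#' @return a normalized `K`-vector `theta`.
#' @export
infer_patient_mixture <- function(model, record, sweeps = 10L,
                                  use_missing_labs = TRUE) {
  alpha <- model$hyper$alpha
  K <- length(alpha)
  tok <- record$tokens
  lab <- record$labs
  if (is.null(tok) || nrow(tok) == 0L)
    tok <- data.frame(type = integer(0), feature = integer(0),
                      count = integer(0))
  if (is.null(lab) || nrow(lab) == 0L)
    lab <- data.frame(lab = integer(0), state = integer(0), freq = integer(0))
  T_ <- length(model$phi)
  L <- length(model$eta)
  keep <- tok$type >= 1L & tok$type <= T_
  keep[keep] <- tok$feature[keep] <= vapply(tok$type[keep],
                                            function(t) nrow(model$phi[[t]]), 1L)
  if (any(!keep))
    warning(sum(!keep), " token record(s) outside the model vocabulary skipped")
  tok <- tok[keep, , drop = FALSE]
  if (nrow(tok) == 0L && nrow(lab) == 0L)
    return(alpha / sum(alpha))
  ntok <- nrow(tok)
  gamma <- matrix(1 / K, max(ntok, 0L), K)
  nobs <- nrow(lab)
  lambda <- matrix(1 / K, max(nobs, 0L), K)
  obs_labs <- unique(lab$lab)
  miss_labs <- if (use_missing_labs && L > 0L)
    setdiff(seq_len(L), obs_labs) else integer(0)
  piL <- lapply(miss_labs, function(l)
    matrix(1 / (K * ncol(model$eta[[l]])), K, ncol(model$eta[[l]])))
  n_loc <- if (ntok) colSums(gamma * tok$count) else numeric(K)
  m_loc <- numeric(K)
  if (nobs) m_loc <- m_loc + colSums(lambda * lab$freq)
  for (B in piL) m_loc <- m_loc + rowSums(B)
  for (sw in seq_len(sweeps)) {
    for (i in seq_len(ntok)) {
      cg <- tok$count[i] * gamma[i, ]
      ex <- pmax(n_loc - cg, 0)
      val <- (alpha + ex + m_loc) * model$phi[[tok$type[i]]][tok$feature[i], ]
      val <- val / sum(val)
      gamma[i, ] <- val
      n_loc <- ex + tok$count[i] * val
    }
    for (i in seq_len(nobs)) {
      l <- lab$lab[i]
      gi <- which(lab$lab == l)
      mass <- colSums(lambda[gi, , drop = FALSE] * lab$freq[gi])
      ex <- pmax(m_loc - mass, 0)
      val <- (alpha + n_loc + ex) * model$eta[[l]][, lab$state[i]] *
        model$psi[l, ]
      val <- val / sum(val)
      delta <- lab$freq[i] * (val - lambda[i, ])
      lambda[i, ] <- val
      m_loc <- ex + mass + delta
    }
    for (i in seq_along(miss_labs)) {
      l <- miss_labs[i]
      B <- piL[[i]]
      mass <- rowSums(B)
      ex <- pmax(m_loc - mass, 0)
      val <- (alpha + n_loc + ex) * (1 - model$psi[l, ]) * model$eta[[l]]
      val <- val / sum(val)
      piL[[i]] <- val
      m_loc <- ex + rowSums(val)
    }
  }
  th <- alpha + n_loc + if (isTRUE(model$include_lab_mass)) m_loc else 0
  th / sum(th)
}

#' Held-out predictive log-likelihood
#'
#' Evaluates the probability of a test corpus under a trained model and
#' given patient mixtures, in log space: the token term is
#' `sum log sum_k theta_jk phi_wk` (count-weighted) and the observed-lab
#' term combines the topic observation probability `psi` and result
#' distribution `eta` — by their product (default, the generative reading)
#' or by their sum (`lab_mode = "sum"`, as an alternative combination rule).
#'
#' @param model a `mixehr_estimates`.
#' @param test a [mixehr_corpus()]; an empty corpus yields 0.
#' @param theta matrix `D_test x K` of row-normalized patient mixtures
#'   (row `j` for test patient `j`).
#' @param lab_mode `"product"` (default) or `"sum"`.
#' @return scalar log-likelihood; `-Inf` (with a diagnostic warning naming
#'   the offending records) if any record has zero predictive probability.
#' @export
predictive_log_likelihood <- function(model, test, theta,
                                      lab_mode = c("product", "sum")) {
  lab_mode <- match.arg(lab_mode)
  if (nrow(test$counts) == 0L && nrow(test$labs) == 0L) return(0)
  .corpus_loglik(model, test, theta, lab_mode)
}

#' Choose the number of topics by cross-validated predictive likelihood
#'
#' Partitions patients into folds; for each fold and each candidate `K`,
#' trains on the remaining folds and evaluates each held-out patient by
#' feature completion: a random half of the patient's tokens (stratified
#' per data type) and observed labs is used to fold in the mixture, the
#' predictive log-likelihood of the other half is recorded.
#'
#' @param corpus a [mixehr_corpus()].
#' @param K_grid integer vector of candidate topic numbers (non-empty).
#' @param folds number of folds (>= 2).
#' @param seed integer seed (fold assignment and 50/50 splits).
#' @param control a [jcvb_control()] for the training runs.
#' @return data.frame with columns `K`, `mean_loglik` (mean per-patient
#'   held-out predictive log-likelihood).
#' @export
cross_validate_K <- function(corpus, K_grid, folds = 5L, seed = 1L,
                             control = jcvb_control()) {
  if (length(K_grid) == 0L) stop("K_grid must be non-empty")
  if (folds < 2L) stop("folds must be >= 2")
  D <- corpus$D
  set.seed(as.integer(seed))
  fold_of <- sample(rep_len(seq_len(folds), D))
  splits <- lapply(seq_len(D), function(j) .split_record(
    patient_record(corpus, j), (seed + 17L * j) %% 2147483647L))
  res <- matrix(NA_real_, nrow = length(K_grid), ncol = D)
  for (f in seq_len(folds)) {
    train_j <- which(fold_of != f)
    test_j <- which(fold_of == f)
    tr <- .subset_corpus(corpus, train_j)
    for (ki in seq_along(K_grid)) {
      fit <- fit_jcvb(tr, K_grid[ki], control = control, seed = seed)
      for (j in test_j) {
        sp <- splits[[j]]
        th <- infer_patient_mixture(fit$estimates, sp$fit)
        res[ki, j] <- .record_loglik(fit$estimates, sp$eval, th,
                                     fit$control$lab_loglik)
      }
    }
  }
  data.frame(K = K_grid, mean_loglik = rowMeans(res, na.rm = TRUE))
}

# 50/50 feature split of one patient record, stratified per data type;
# observed lab (l) pairs split 50/50 as whole pairs.
.split_record <- function(rec, seed) {
  set.seed(as.integer(seed))
  fit_tok <- eval_tok <- list()
  for (t in unique(rec$tokens$type)) {
    rt <- rec$tokens[rec$tokens$type == t, , drop = FALSE]
    inst <- rep(seq_len(nrow(rt)), rt$count)
    n <- length(inst)
    pick <- sample.int(n, floor(n / 2))
    rest <- setdiff(seq_len(n), pick)
    collapse <- function(rows) {
      if (!length(rows)) return(NULL)
      tb <- table(rows)
      data.frame(type = t, feature = rt$feature[as.integer(names(tb))],
                 count = as.integer(tb))
    }
    fit_tok[[length(fit_tok) + 1L]] <- collapse(inst[pick])
    eval_tok[[length(eval_tok) + 1L]] <- collapse(inst[rest])
  }
  bindnull <- function(x) {
    x <- Filter(Negate(is.null), x)
    if (length(x)) do.call(rbind, x)
    else data.frame(type = integer(0), feature = integer(0), count = integer(0))
  }
  obs_labs <- unique(rec$labs$lab)
  lf <- sample(length(obs_labs))
  half <- obs_labs[lf[seq_len(floor(length(obs_labs) / 2))]]
  list(fit = list(tokens = bindnull(fit_tok),
                  labs = rec$labs[rec$labs$lab %in% half, , drop = FALSE]),
       eval = list(tokens = bindnull(eval_tok),
                   labs = rec$labs[!(rec$labs$lab %in% half), , drop = FALSE]))
}

.record_loglik <- function(model, rec, theta, lab_mode) {
  cn <- rec$tokens
  lb <- rec$labs
  corp1 <- mixehr_corpus(
    if (nrow(cn)) cbind(patient = 1L, cn) else cn,
    if (nrow(lb)) cbind(patient = 1L, lb) else lb,
    n_patients = 1L,
    n_features = vapply(model$phi, nrow, 1L),
    n_states = vapply(model$eta, ncol, 1L))
  predictive_log_likelihood(model, corp1, matrix(theta, nrow = 1L),
                            lab_mode = lab_mode)
}

.subset_corpus <- function(corpus, patients) {
  map <- integer(corpus$D)
  map[patients] <- seq_along(patients)
  cn <- corpus$counts[corpus$counts$patient %in% patients, , drop = FALSE]
  cn$patient <- map[cn$patient]
  lb <- corpus$labs[corpus$labs$patient %in% patients, , drop = FALSE]
  lb$patient <- map[lb$patient]
  mixehr_corpus(cn, lb, length(patients), corpus$W, corpus$V)
}

#' k nearest training patients in topic space
#'
#' Euclidean distance between topic mixtures; ties are broken by ascending
#' training patient index.
#'
#' @param theta_test `K`-vector, the test patient's mixture.
#' @param theta_train `D x K` matrix of training mixtures.
#' @param k number of neighbours (1..D).
#' @return data.frame with columns `index`, `distance`, sorted by
#'   non-decreasing distance.
#' @export
knn_neighbors <- function(theta_test, theta_train, k) {
  D <- nrow(theta_train)
  if (k < 1L || k > D) stop("k must lie in 1..", D)
  d <- sqrt(colSums((t(theta_train) - theta_test)^2))
  ord <- order(d, seq_len(D))[seq_len(k)]
  data.frame(index = ord, distance = d[ord])
}

#' kNN probability of an EHR code
#'
#' The predicted probability is the average binary presence of the code
#' among the `k` nearest neighbours; classification uses the threshold
#' `1/k`.
#'
#' @param neighbors data.frame from [knn_neighbors()] with `k` rows.
#' @param code_indicator 0/1 vector over training patients.
#' @param k neighbourhood size (must equal `nrow(neighbors)`).
#' @return probability in `{0, 1/k, ..., 1}`.
#' @export
predict_code <- function(neighbors, code_indicator, k) {
  if (nrow(neighbors) != k) stop("neighbors must have exactly k rows")
  mean(code_indicator[neighbors$index] > 0)
}

#' Impute a masked lab result by topic-space nearest neighbours
#'
#' The target lab is removed from the test record, the mixture is folded
#' in from everything else, the `k` nearest training patients *with the
#' target lab observed* are found in topic space, and their normalized
#' result-state frequency distributions for that lab are averaged.
#'
#' @param model a `mixehr_estimates`.
#' @param train_theta `D x K` training mixtures (rows align with
#'   `train_corpus` patients).
#' @param train_corpus the training [mixehr_corpus()].
#' @param record the test patient's record ([patient_record()]); any
#'   entries for `lab` are masked before fold-in.
#' @param lab target lab index.
#' @param k neighbourhood size (default 25); if fewer training patients
#'   have the lab observed, all are used with a warning.
#' @param sweeps fold-in sweeps (default 10).
#' @return a `V[lab]`-vector of imputed state probabilities.
#' @export
impute_lab_result <- function(model, train_theta, train_corpus, record,
                              lab, k = 25L, sweeps = 10L) {
  masked <- record
  masked$labs <- record$labs[record$labs$lab != lab, , drop = FALSE]
  th <- infer_patient_mixture(model, masked, sweeps = sweeps)
  eligible <- which(train_corpus$r[lab, ] == 1L)
  if (!length(eligible))
    stop("unimputable: no training patient has lab ", lab, " observed")
  k_use <- min(k, length(eligible))
  if (k_use < k)
    warning("only ", k_use, " eligible neighbours for lab ", lab)
  nn <- knn_neighbors(th, train_theta[eligible, , drop = FALSE], k_use)
  neigh <- eligible[nn$index]
  Vl <- train_corpus$V[lab]
  out <- numeric(Vl)
  for (j in neigh) {
    rows <- train_corpus$labs[train_corpus$labs$patient == j &
                                train_corpus$labs$lab == lab, , drop = FALSE]
    fr <- numeric(Vl)
    fr[rows$state] <- rows$freq
    out <- out + fr / sum(fr)
  }
  out / k_use
}

#' Binary classification metrics for code prediction
#'
#' Accuracy at a threshold, area under the ROC curve, and area under the
#' precision-recall curve (average precision).  With single-class labels
#' the ranking metrics are undefined and returned as `NA`.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector aligned with `scores`.
#' @param threshold classification threshold for accuracy (e.g. `1/k`).
#' @return list with `accuracy`, `auroc`, `auprc`.
#' @export
evaluate_binary_predictions <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels > 0)
  acc <- mean((scores >= threshold) == (labels == 1L))
  if (length(unique(labels)) < 2L)
    return(list(accuracy = acc, auroc = NA_real_, auprc = NA_real_))
  auroc <- as.numeric(pROC::auc(pROC::roc(response = labels,
                                          predictor = scores,
                                          levels = c(0, 1),
                                          direction = "<", quiet = TRUE)))
  ord <- order(scores, decreasing = TRUE)
  lab_sorted <- labels[ord]
  sc_sorted <- scores[ord]
  # average precision with tied scores grouped
  grp <- cumsum(!duplicated(sc_sorted))
  tp_g <- tapply(lab_sorted, grp, sum)
  n_g <- tapply(lab_sorted, grp, length)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  rec_prev <- c(0, utils::head(tp_cum, -1)) / sum(labels)
  rec <- tp_cum / sum(labels)
  auprc <- sum((rec - rec_prev) * prec)
  list(accuracy = acc, auroc = auroc, auprc = auprc)
}
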