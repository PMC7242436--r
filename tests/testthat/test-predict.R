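test_that("fold-in degenerates to the prior mean and recovers pure patients", {
  fx <- make_fixture()
  hyper <- mixehr_hyper(alpha = c(2, 1), beta = 0.1, zeta = 1, a = 1, b = 1,
                        W = fx$corpus$W, V = fx$corpus$V)
  est <- estimate_parameters(initialize_state(fx$corpus, 2L, 1L), hyper)
  empty <- list(tokens = NULL, labs = NULL)
  expect_equal(infer_patient_mixture(est, empty), c(2, 1) / 3)

  est1 <- estimate_parameters(initialize_state(fx$corpus, 1L, 1L),
                              default_hyper(1L, fx$corpus))
  expect_equal(infer_patient_mixture(est1, patient_record(fx$corpus, 1L)), 1)

  # unknown features are skipped with a warning, not an error
  rec <- list(tokens = data.frame(type = 1L, feature = 99L, count = 1L),
              labs = NULL)
  expect_warning(th <- infer_patient_mixture(est, rec), "vocabulary")
  expect_equal(th, c(2, 1) / 3)

  # patients generated from a single topic are assigned to it
  bm <- simulate_benchmark("recovery", D = 300L, seed = 71L)
  fit <- fit_jcvb(bm$corpus, 3L, jcvb_control(max_iter = 40L, min_iter = 10L),
                  seed = 72L)
  tr <- bm$truth
  tr$theta <- matrix(rep(c(1, 0, 0), each = 200L), ncol = 3L)
  pure <- sample_corpus(tr, c(40L, 40L), seed = 73L)
  k_hat <- which.max(col_cosine(fit$estimates$phi[[1]],
                                tr$phi[[1]][, c(1, 1, 1)]))
  hits <- vapply(seq_len(200L), function(j)
    which.max(infer_patient_mixture(fit$estimates,
                                    patient_record(pure, j))) == k_hat, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("fold-in reproduces training mixtures once self-mass is negligible", {
  bm <- simulate_benchmark("recovery", D = 300L, seed = 71L)
  fit <- fit_jcvb(bm$corpus, 3L, jcvb_control(max_iter = 40L, min_iter = 10L),
                  seed = 72L)
  tv <- vapply(seq_len(40L), function(j) {
    th <- infer_patient_mixture(fit$estimates, patient_record(bm$corpus, j))
    0.5 * sum(abs(th - fit$estimates$theta[j, ]))
  }, 1.0)
  expect_lt(max(tv), 0.02)
})

test_that("the predictive likelihood matches closed forms and a loop oracle", {
  # K = 1, uniform phi over 4 features, two tokens, no labs: 2 * log(1/4)
  est <- structure(list(
    theta = matrix(1, 1L, 1L),
    phi = list(matrix(0.25, 4L, 1L)),
    eta = list(), psi = matrix(0, 0L, 1L),
    hyper = mixehr_hyper(alpha = 1, beta = 1, W = 4L, V = integer(0),
                         a = numeric(0), b = numeric(0)),
    include_lab_mass = TRUE), class = "mixehr_estimates")
  test1 <- mixehr_corpus(data.frame(patient = 1L, type = 1L,
                                    feature = c(1L, 3L), count = c(1L, 1L)),
                         empty_labs(), 1L, 4L, integer(0))
  expect_equal(predictive_log_likelihood(est, test1, matrix(1, 1L, 1L)),
               2 * log(0.25), tolerance = 1e-12)

  empty <- mixehr_corpus(empty_counts(), empty_labs(), 0L, 4L, integer(0))
  expect_equal(predictive_log_likelihood(est, empty, matrix(0, 0L, 1L)), 0)

  # fixture vs an explicit double loop, in both lab-term modes
  fx <- make_fixture()
  hyper <- default_hyper(2L, fx$corpus)
  fit <- fit_jcvb(fx$corpus, 2L, jcvb_control(max_iter = 10L, min_iter = 5L),
                  seed = 3L)
  est2 <- fit$estimates
  for (mode in c("product", "sum")) {
    ll <- predictive_log_likelihood(est2, fx$corpus, est2$theta,
                                    lab_mode = mode)
    ref <- 0
    for (r in seq_len(nrow(fx$corpus$counts))) {
      j <- fx$corpus$counts$patient[r]
      t <- fx$corpus$counts$type[r]
      w <- fx$corpus$counts$feature[r]
      ref <- ref + fx$corpus$counts$count[r] *
        log(sum(est2$theta[j, ] * est2$phi[[t]][w, ]))
    }
    for (r in seq_len(nrow(fx$corpus$labs))) {
      j <- fx$corpus$labs$patient[r]
      l <- fx$corpus$labs$lab[r]
      v <- fx$corpus$labs$state[r]
      inner <- if (mode == "product") est2$psi[l, ] * est2$eta[[l]][, v]
               else est2$psi[l, ] + est2$eta[[l]][, v]
      ref <- ref + fx$corpus$labs$freq[r] * log(sum(est2$theta[j, ] * inner))
    }
    expect_equal(ll, ref, tolerance = 1e-10)
  }

  # invariant under a joint permutation of the topic index
  pm <- c(2L, 1L)
  est_p <- est2
  est_p$theta <- est2$theta[, pm]
  est_p$phi <- lapply(est2$phi, function(m) m[, pm])
  est_p$eta <- lapply(est2$eta, function(m) m[pm, ])
  est_p$psi <- est2$psi[, pm]
  expect_equal(predictive_log_likelihood(est_p, fx$corpus, est_p$theta),
               predictive_log_likelihood(est2, fx$corpus, est2$theta),
               tolerance = 1e-10)
})

test_that("cross-validation over K is deterministic in the seed", {
  bm <- simulate_benchmark("recovery", D = 60L, seed = 81L)
  ctl <- jcvb_control(max_iter = 10L, min_iter = 5L)
  cv1 <- cross_validate_K(bm$corpus, c(1L, 2L), folds = 2L, seed = 9L,
                          control = ctl)
  cv2 <- cross_validate_K(bm$corpus, c(1L, 2L), folds = 2L, seed = 9L,
                          control = ctl)
  expect_identical(cv1, cv2)
  expect_equal(cv1$K, c(1L, 2L))
  expect_true(all(is.finite(cv1$mean_loglik)))
  expect_error(cross_validate_K(bm$corpus, integer(0), folds = 2L, seed = 1L),
               "non-empty")
  expect_error(cross_validate_K(bm$corpus, 2L, folds = 1L, seed = 1L),
               "folds")
})

test_that("nearest neighbours are exact and ties break by patient index", {
  expect_equal(knn_neighbors(c(1, 0), rbind(c(1, 0), c(0, 1)), 2L),
               data.frame(index = 1:2, distance = c(0, sqrt(2))))
  # tie: two identical candidates, lower index first
  nn <- knn_neighbors(c(0.5, 0.5), rbind(c(0.4, 0.6), c(0.4, 0.6)), 2L)
  expect_equal(nn$index, 1:2)

  set.seed(13)
  cand <- matrix(runif(100 * 3), ncol = 3L)
  cand <- cand / rowSums(cand)
  q <- c(0.2, 0.3, 0.5)
  nn <- knn_neighbors(q, cand, 100L)
  d_ref <- sqrt(colSums((t(cand) - q)^2))
  expect_equal(nn$index, order(d_ref, seq_len(100L)))
  expect_false(is.unsorted(nn$distance))
  expect_error(knn_neighbors(q, cand, 101L), "k must lie")
})

test_that("code prediction averages neighbour presence on the 1/k grid", {
  nn <- data.frame(index = 1:5, distance = seq(0, 0.4, 0.1))
  expect_equal(predict_code(nn, rep(1, 10), 5L), 1)
  expect_equal(predict_code(nn, rep(0, 10), 5L), 0)
  expect_equal(predict_code(nn, c(1, 1, 1, 0, 0, 1, 1, 1, 1, 1), 5L), 0.6)
  expect_error(predict_code(nn, rep(1, 10), 4L), "exactly k rows")
  # grid property on random indicators
  set.seed(4)
  for (i in 1:20) {
    p <- predict_code(nn, rbinom(10, 1, 0.5), 5L)
    expect_true(p %in% ((0:5) / 5))
  }
})

test_that("lab imputation averages the neighbours' state distributions", {
  # hand-built model: two clusters of training patients; topic-1 patients
  # are abnormal (state 2) on the lab, topic-2 patients normal
  theta <- rbind(matrix(c(0.9, 0.1), 15L, 2L, byrow = TRUE),
                 matrix(c(0.1, 0.9), 15L, 2L, byrow = TRUE))
  hyper <- mixehr_hyper(alpha = c(1, 1), beta = 0.1, zeta = 1, a = 1, b = 1,
                        W = c(4L), V = c(2L))
  phi1 <- matrix(c(0.4, 0.4, 0.1, 0.1,   # topic 1 favours features 1-2
                   0.1, 0.1, 0.4, 0.4), 4L, 2L)
  est <- structure(list(theta = theta,
                        phi = list(phi1),
                        eta = list(matrix(0.5, 2L, 2L)),
                        psi = matrix(0.5, 1L, 2L),
                        hyper = hyper, include_lab_mass = TRUE),
                   class = "mixehr_estimates")
  labs <- data.frame(patient = 1:30, lab = 1L,
                     state = rep(c(2L, 1L), each = 15L), freq = 1L)
  counts <- data.frame(patient = 1:30, type = 1L, feature = 1L, count = 1L)
  train <- mixehr_corpus(counts, labs, 30L, c(4L), c(2L))

  # a topic-1-looking test patient: folds in near (0.8, 0.2), so its 10
  # nearest training patients all carry state 2
  rec <- list(tokens = data.frame(type = 1L, feature = 1L, count = 5L),
              labs = data.frame(lab = 1L, state = 1L, freq = 1L))
  imp <- impute_lab_result(est, theta, train, rec, 1L, k = 10L)
  expect_equal(imp, c(0, 1))

  # the full neighbourhood straddles both clusters evenly
  imp2 <- impute_lab_result(est, theta, train, rec, 1L, k = 30L)
  expect_equal(imp2, c(0.5, 0.5))

  # fewer eligible neighbours than k: all used, with a warning
  train_small <- mixehr_corpus(counts[1:3, ], labs[1:3, ], 30L, c(4L), c(2L))
  expect_warning(imp3 <- impute_lab_result(est, theta, train_small, rec, 1L,
                                           k = 10L), "eligible")
  expect_equal(imp3, c(0, 1))

  nolab <- mixehr_corpus(counts, empty_labs(), 30L, c(4L), c(2L))
  expect_error(impute_lab_result(est, theta, nolab, rec, 1L), "unimputable")
})

test_that("binary metrics handle separation, noise and degenerate labels", {
  m <- evaluate_binary_predictions(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(m$auroc, 1)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auprc, 1)

  set.seed(6)
  n <- 3000L
  labels <- rbinom(n, 1L, 0.5)
  scores <- runif(n)
  m2 <- evaluate_binary_predictions(scores, labels, 0.5)
  n1 <- sum(labels); n0 <- n - n1
  se <- sqrt((n1 + n0 + 1) / (12 * n1 * n0))
  expect_lt(abs(m2$auroc - 0.5), 3 * se)

  m3 <- evaluate_binary_predictions(c(0.2, 0.8), c(1, 1), 0.5)
  expect_true(is.na(m3$auroc))
  expect_equal(m3$accuracy, 0.5)
})
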