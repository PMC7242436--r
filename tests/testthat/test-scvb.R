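test_that("the natural-gradient interpolation is exact arithmetic", {
  fx <- make_fixture()
  st <- initialize_state(fx$corpus, 2L, 1L)
  n_hat <- lapply(st$stats$n_wk, function(m) 2 * m)
  m_hat <- lapply(st$stats$m_lkv, function(m) 2 * m)

  st0 <- scvb_step(st, n_hat, m_hat, rho = 0)
  expect_identical(st0$stats$n_wk, st$stats$n_wk)

  st1 <- scvb_step(st, n_hat, m_hat, rho = 1)
  expect_identical(st1$stats$n_wk, n_hat)

  st5 <- scvb_step(st, n_hat, m_hat, rho = 0.5)
  expect_equal(st5$stats$n_wk[[1]], 1.5 * st$stats$n_wk[[1]])
  expect_equal(st5$stats$m_lkv[[2]], 1.5 * st$stats$m_lkv[[2]])

  expect_error(scvb_step(st, n_hat, m_hat, rho = 1.2), "rho")
  expect_error(scvb_control(batch_size = 2L, rho = -0.1), "rho")
})

test_that("minibatch sums match full statistics and a loop oracle", {
  fx <- make_fixture()
  st <- initialize_state(fx$corpus, 2L, 6L)

  # full batch at scale 1 equals the refreshed statistics exactly
  mb <- minibatch_statistics(st, batch = 1:6, scale = TRUE)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       mb$n_hat, st$stats$n_wk)), 1e-12)
  expect_lt(max(mapply(function(a, b) max(abs(a - b)),
                       mb$m_hat, st$stats$m_lkv)), 1e-12)
  expect_lt(max(abs(mb$p_hat - st$stats$p)), 1e-12)
  expect_lt(max(abs(mb$q_hat - st$stats$q)), 1e-12)

  # one patient with a single token: only that feature row is nonzero
  corp <- one_token_corpus(W = 3L)
  st1 <- initialize_state(corp, 2L, 1L)
  mb1 <- minibatch_statistics(st1, batch = 1L)
  expect_true(all(mb1$n_hat[[1]][2:3, ] == 0))
  expect_equal(sum(mb1$n_hat[[1]][1, ]), 1)

  # random batch against an explicit loop over the batch records
  batch <- c(2L, 5L)
  mb2 <- minibatch_statistics(st, batch, scale = TRUE)
  fac <- 6 / 2
  n_ref <- matrix(0, 5L, 2L)
  for (r in which(st$tok$patient %in% batch & st$tok$type == 1L))
    n_ref[st$tok$feature[r], ] <- n_ref[st$tok$feature[r], ] +
      st$tok$count[r] * st$gamma[r, ]
  expect_lt(max(abs(mb2$n_hat[[1]] - fac * n_ref)), 1e-12)
  m_ref <- matrix(0, 2L, 2L)
  for (r in which(st$obs$patient %in% batch & st$obs$lab == 1L))
    m_ref[, st$obs$state[r]] <- m_ref[, st$obs$state[r]] +
      st$obs$freq[r] * st$lambda[r, ]
  for (r in which(st$miss$patient %in% batch & st$miss$lab == 1L))
    for (v in 1:2)
      m_ref[, v] <- m_ref[, v] + st$pi[st$pi_off[r] + (v - 1L) * 2L + 1:2]
  expect_lt(max(abs(mb2$m_hat[[1]] - fac * m_ref)), 1e-12)

  expect_error(minibatch_statistics(st, integer(0)), "empty")
})

test_that("a full-batch rho=1 epoch reproduces one batch sweep exactly", {
  fx <- make_fixture()
  K <- 2L
  hyper <- default_hyper(K, fx$corpus)
  st <- initialize_state(fx$corpus, K, 7L)
  st1 <- refresh_statistics(e_step(st, hyper), fx$corpus)
  sc <- fit_scvb(fx$corpus, K,
                 scvb_control(batch_size = 6L, rho = 1, iterations = 1L,
                              seed = 7L, local_sweeps = 1L,
                              monitor_size = 3L),
                 hyper = hyper)
  expect_lt(max_stats_dev(sc$stats, st1$stats), 1e-10)
})

test_that("stochastic training keeps memory bounded and improves held-out fit", {
  bm <- simulate_benchmark("recovery", D = 120L, seed = 31L)
  oks <- vapply(c(31L, 32L, 33L), function(s) {
    fit <- fit_scvb(bm$corpus, 3L,
                    scvb_control(batch_size = 30L, rho_schedule = c(10, 0.7),
                                 iterations = 8L, seed = s,
                                 local_sweeps = 2L, monitor_size = 30L))
    tail(fit$trace$loglik, 1L) >= fit$trace$loglik[1L]
  }, TRUE)
  expect_true(all(oks))

  fit <- fit_scvb(bm$corpus, 3L,
                  scvb_control(batch_size = 30L, rho = 0.5, iterations = 2L,
                               seed = 31L, monitor_size = 20L))
  # no per-record assignments retained; local tables bounded by the batch
  expect_null(fit$state)
  expect_null(fit$gamma)
  batch_tok_max <- max(vapply(split(bm$corpus$counts$patient,
                                    bm$corpus$counts$patient), length, 1L)) * 30L
  expect_lte(fit$max_local_rows, batch_tok_max)
  expect_lt(fit$max_local_rows, nrow(bm$corpus$counts))
})

test_that("minibatch training still recovers well-separated topics", {
  bm <- simulate_benchmark("recovery", D = 300L, seed = 55L)
  fit <- fit_scvb(bm$corpus, 3L,
                  scvb_control(batch_size = 50L, rho_schedule = c(10, 0.7),
                               iterations = 15L, seed = 56L,
                               local_sweeps = 2L, monitor_size = 30L))
  align <- best_phi_alignment(fit$estimates$phi, bm$truth$phi)
  expect_gte(align$cosine, 0.85)
})
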