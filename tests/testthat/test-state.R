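test_that("initialization satisfies the state invariants", {
  fx <- make_fixture()
  st <- initialize_state(fx$corpus, 2L, 1L)

  expect_lt(max(abs(rowSums(st$gamma) - 1)), 1e-12)
  expect_lt(max(abs(rowSums(st$lambda) - 1)), 1e-12)
  # each pi block sums to 1 jointly over (k, v)
  for (i in seq_len(nrow(st$miss))) {
    Vl <- st$V[st$miss$lab[i]]
    expect_equal(sum(st$pi[st$pi_off[i] + seq_len(2L * Vl)]), 1)
  }
  # token conservation at initialization
  expect_lt(max(abs(rowSums(st$stats$n_jk) - rowSums(token_totals(fx$corpus)))),
            1e-8)
  # deterministic in the seed
  st2 <- initialize_state(fx$corpus, 2L, 1L)
  expect_identical(st$gamma, st2$gamma)
  expect_identical(st$pi, st2$pi)
  expect_false(identical(st$gamma, initialize_state(fx$corpus, 2L, 2L)$gamma))
  expect_error(initialize_state(fx$corpus, 0L, 1L), "K must be >= 1")
})

test_that("K = 1 collapses every assignment to certainty", {
  fx <- make_fixture()
  st <- initialize_state(fx$corpus, 1L, 1L)
  expect_true(all(st$gamma == 1))
  expect_true(all(st$lambda == 1))
  expect_equal(st$stats$n_jk[, 1], rowSums(token_totals(fx$corpus)))
})

test_that("refreshed statistics equal the quadruple-loop sums", {
  fx <- make_fixture()
  hyper <- default_hyper(2L, fx$corpus)
  st <- initialize_state(fx$corpus, 2L, 3L)
  expect_lt(max_stats_dev(st$stats, oracle_soft_suffstats(st)), 1e-10)
  # still exact after assignments have moved off their initialization
  st <- refresh_statistics(e_step(st, hyper), fx$corpus)
  expect_lt(max_stats_dev(st$stats, oracle_soft_suffstats(st)), 1e-10)
})

test_that("a corpus without labs has zero lab statistics", {
  corp <- one_token_corpus()
  st <- initialize_state(corp, 2L, 1L)
  expect_true(all(st$stats$m_jk == 0))
  expect_equal(nrow(st$stats$p), 0L)
  expect_length(st$stats$m_lkv, 0L)
})

test_that("posterior-mean estimates reduce to prior means at zero counts", {
  corp <- mixehr_corpus(empty_counts(), empty_labs(), n_patients = 2L,
                        n_features = c(3L, 2L), n_states = c(2L, 2L))
  # patients with no observations at all are allowed; labs all unobserved
  # would still carry pi mass, so zero out the statistics directly
  hyper <- mixehr_hyper(alpha = c(2, 1), beta = 0.5, zeta = c(1, 1),
                        a = 2, b = 3, W = c(3L, 2L), V = c(2L, 2L))
  st <- initialize_state(corp, 2L, 1L)
  st$stats <- lapply(st$stats, function(x)
    if (is.list(x)) lapply(x, function(m) m * 0) else x * 0)
  est <- estimate_parameters(st, hyper)
  expect_equal(est$theta[1, ], c(2, 1) / 3)
  expect_equal(est$eta[[1]][1, ], c(0.5, 0.5))
  expect_equal(unname(est$psi[1, 1]), 2 / 5)
  expect_equal(est$phi[[1]][, 1], rep(1 / 3, 3))
})

test_that("estimates satisfy stochasticity and match the closed formulas", {
  fx <- make_fixture()
  hyper <- mixehr_hyper(alpha = c(0.8, 1.2),
                        beta = list(c(0.5, 0.4, 0.3, 0.2, 0.1),
                                    c(0.3, 0.3, 0.2, 0.2)),
                        zeta = list(c(0.7, 0.5), c(0.4, 0.6)),
                        a = c(1.5, 0.8), b = c(0.9, 1.1))
  st <- refresh_statistics(e_step(initialize_state(fx$corpus, 2L, 5L), hyper),
                           fx$corpus)
  est <- estimate_parameters(st, hyper)
  expect_lt(max(abs(rowSums(est$theta) - 1)), 1e-12)
  for (t in 1:2) expect_lt(max(abs(colSums(est$phi[[t]]) - 1)), 1e-12)
  for (l in 1:2) expect_lt(max(abs(rowSums(est$eta[[l]]) - 1)), 1e-12)
  expect_true(all(est$psi > 0 & est$psi < 1))

  # direct formula evaluation
  s <- st$stats
  th1 <- (hyper$alpha + s$n_jk[1, ] + s$m_jk[1, ]) /
    sum(hyper$alpha + s$n_jk[1, ] + s$m_jk[1, ])
  expect_lt(max(abs(est$theta[1, ] - th1)), 1e-12)
  ph <- (hyper$beta[[1]] + s$n_wk[[1]][, 1]) /
    sum(hyper$beta[[1]] + s$n_wk[[1]][, 1])
  expect_lt(max(abs(est$phi[[1]][, 1] - ph)), 1e-12)
  ps <- (hyper$a[1] + s$p[1, ]) / (hyper$a[1] + s$p[1, ] + hyper$b[1] + s$q[1, ])
  expect_lt(max(abs(est$psi[1, ] - ps)), 1e-12)

  # excluding lab mass changes only theta
  est2 <- estimate_parameters(st, hyper, include_lab_mass = FALSE)
  th1b <- (hyper$alpha + s$n_jk[1, ]) / sum(hyper$alpha + s$n_jk[1, ])
  expect_lt(max(abs(est2$theta[1, ] - th1b)), 1e-12)
  expect_identical(est2$phi, est$phi)
})
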