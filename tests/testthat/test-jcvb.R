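test_that("assignments stay normalized and tokens conserved after sweeps", {
  fx <- make_fixture()
  hyper <- default_hyper(2L, fx$corpus)
  st <- initialize_state(fx$corpus, 2L, 2L)
  M <- rowSums(token_totals(fx$corpus))
  for (sweep in 1:3) {
    st <- e_step(st, hyper)
    expect_lt(max(abs(rowSums(st$gamma) - 1)), 1e-10)
    expect_lt(max(abs(rowSums(st$lambda) - 1)), 1e-10)
    for (i in seq_len(nrow(st$miss))) {
      Vl <- st$V[st$miss$lab[i]]
      expect_lt(abs(sum(st$pi[st$pi_off[i] + seq_len(2L * Vl)]) - 1), 1e-10)
    }
    st <- refresh_statistics(st, fx$corpus)
    expect_lt(max(abs(rowSums(st$stats$n_jk) - M)), 1e-8)
    # per-pair lab mass: y total for observed, 1 for unobserved
    for (l in 1:2) {
      obs_j <- which(fx$corpus$r[l, ] == 1L)
      for (j in obs_j) {
        rows <- st$obs$lab == l & st$obs$patient == j
        mass <- sum(st$lambda[rows, , drop = FALSE] * st$obs$freq[rows])
        expect_lt(abs(mass - sum(st$obs$freq[rows])), 1e-8)
      }
    }
  }
})

test_that("the compiled sweep reproduces the loop-literal sweep", {
  res <- mixehr_selftest()
  expect_true(all(res$pass))
  expect_lt(max(res$max_dev), 1e-10)
})

test_that("hyperparameter fixed point hits the analytic zero-count value", {
  corp0 <- mixehr_corpus(empty_counts(), empty_labs(), n_patients = 0L,
                         n_features = 3L, n_states = integer(0))
  gp <- lapply(stats::setNames(nm = c("alpha", "beta", "zeta", "a", "b")),
               function(f) c(shape = 2, rate = 1))
  h0 <- mixehr_hyper(alpha = c(0.5, 0.5), beta = 0.3, W = 3L,
                     V = integer(0), a = numeric(0), b = numeric(0),
                     gamma_prior = gp)
  st0 <- initialize_state(corp0, 2L, 1L)
  h1 <- update_hyperparameters(st0, h0)
  # (shape - 1) / rate = 1 exactly; digamma terms cancel at zero counts
  expect_equal(h1$beta[[1]], rep(1, 3), tolerance = 1e-14)
  expect_equal(h1$alpha, rep(1, 2), tolerance = 1e-14)
})

test_that("hyperparameter updates stay positive and reach the 1-D argmax", {
  fx <- make_fixture()
  hyper <- default_hyper(2L, fx$corpus)
  st <- refresh_statistics(e_step(initialize_state(fx$corpus, 2L, 5L), hyper),
                           fx$corpus)
  h1 <- update_hyperparameters(st, hyper)
  expect_true(all(h1$alpha > 0) && all(unlist(h1$beta) > 0) &&
                all(unlist(h1$zeta) > 0) && all(h1$a > 0) && all(h1$b > 0))

  # iterate the w = 1 coordinate of type 1 to convergence, others fixed
  n1 <- st$stats$n_wk[[1]]
  prior <- c(shape = 1.5, rate = 1)
  bet <- hyper$beta[[1]]
  bw <- bet[1]
  for (it in 1:200) {
    bfull <- bet
    bfull[1] <- bw
    num <- prior[["shape"]] - 1 + bw * sum(digamma(bw + n1[1, ]) - digamma(bw))
    den <- prior[["rate"]] +
      sum(digamma(sum(bfull) + colSums(n1)) - digamma(sum(bfull)))
    bw <- num / den
  }
  obj <- function(x) {
    b2 <- bet
    b2[1] <- x
    oracle_dirichlet_objective(b2, n1, prior)
  }
  argmax <- stats::optimize(function(x) -obj(x), c(1e-4, 5))$minimum
  expect_lt(abs(bw - argmax), 1e-3)
})

test_that("K = 1 training recovers the smoothed empirical distribution", {
  fx <- make_fixture()
  hyper <- default_hyper(1L, fx$corpus)
  fit <- fit_jcvb(fx$corpus, 1L, jcvb_control(max_iter = 1L, min_iter = 1L,
                                              hyperupdate_every = 0L),
                  hyper = hyper, seed = 1L)
  for (t in 1:2) {
    cnt <- numeric(fx$corpus$W[t])
    it <- fx$corpus$counts$type == t
    agg <- tapply(fx$corpus$counts$count[it], fx$corpus$counts$feature[it], sum)
    cnt[as.integer(names(agg))] <- agg
    expect_equal(fit$estimates$phi[[t]][, 1],
                 (hyper$beta[[t]] + cnt) / sum(hyper$beta[[t]] + cnt),
                 tolerance = 1e-12)
  }
})

test_that("training is deterministic and its monitored likelihood improves", {
  fx <- make_fixture()
  ctl <- jcvb_control(max_iter = 15L, min_iter = 5L)
  fit1 <- fit_jcvb(fx$corpus, 2L, ctl, seed = 4L)
  fit2 <- fit_jcvb(fx$corpus, 2L, ctl, seed = 4L)
  expect_identical(fit1$estimates$theta, fit2$estimates$theta)
  expect_identical(fit1$trace, fit2$trace)
  expect_true(all(is.finite(fit1$trace$loglik)))
  expect_gte(tail(fit1$trace$loglik, 1L), fit1$trace$loglik[1L])
})

test_that("the collapsed likelihood closed form checks out on tiny cases", {
  # one patient, one token, K = 1, W = 2, symmetric beta = 1: the
  # Dirichlet-multinomial ratio leaves exactly log(1/2)
  corp <- one_token_corpus(W = 2L)
  h <- mixehr_hyper(alpha = 1, beta = 1, W = 2L, V = integer(0),
                    a = numeric(0), b = numeric(0))
  ll <- oracle_collapsed_loglik(corp, z = 1L, h = matrix(0L, 0L, 1L), h)
  expect_equal(ll, log(0.5), tolerance = 1e-12)

  # relabeling topics leaves the likelihood unchanged under symmetric priors
  fx <- make_fixture()
  hy <- default_hyper(2L, fx$corpus)
  set.seed(8)
  z <- sample(1:2, 35L, replace = TRUE)
  hh <- matrix(sample(1:2, 12L, replace = TRUE), nrow = 2L)
  ll1 <- oracle_collapsed_loglik(fx$corpus, z, hh, hy)
  ll2 <- oracle_collapsed_loglik(fx$corpus, 3L - z, 3L - hh, hy)
  expect_equal(ll1, ll2, tolerance = 1e-10)
})
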