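test_that("interval BGR is exactly 1 for identical chains and large when separated", {
  set.seed(1)
  x <- rnorm(500)
  s <- bgr_statistic(list(x, x))
  expect_identical(attr(s, "final"), 1)
  expect_true(all(s$Rhat == 1))

  far <- bgr_statistic(list(rnorm(500), rnorm(500, mean = 10)))
  expect_gte(attr(far, "final"), 2)

  expect_error(bgr_statistic(list(x)), "two chains")
  expect_error(bgr_statistic(list(x, x[-1])), "equal lengths")
})

test_that("interval BGR of well-mixed chains settles near 1", {
  set.seed(2)
  vals <- replicate(5, {
    s <- bgr_statistic(list(rnorm(20000), rnorm(20000)))
    attr(s, "final")
  })
  expect_true(all(vals <= 1.05 & vals >= 0.95))
})

test_that("BGR is invariant to a common affine transform", {
  set.seed(3)
  ch <- list(cumsum(rnorm(400)), cumsum(rnorm(400)))
  s1 <- bgr_statistic(ch)
  s2 <- bgr_statistic(lapply(ch, function(x) 3.7 * x - 11))
  expect_equal(s1$Rhat, s2$Rhat, tolerance = 1e-12)
  expect_equal(bgr_scalar(ch), bgr_scalar(lapply(ch, function(x) 3.7 * x - 11)),
               tolerance = 1e-10)
  expect_gt(bgr_scalar(list(rnorm(200), rnorm(200, 10))), 2)
})

test_that("posterior summaries report equal-tailed type-7 intervals", {
  mk <- function(x) {
    m <- matrix(x, ncol = 1, dimnames = list(NULL, "H[1]"))
    fake_draws(list(m), S = 1)
  }
  s <- posterior_summary(mk(rep(4.2, 50)))
  expect_equal(unlist(s[1, c("mean", "median", "lower", "upper")]),
               c(mean = 4.2, median = 4.2, lower = 4.2, upper = 4.2))

  # type-7 quantile oracle by direct interpolation of order statistics
  x <- as.numeric(1:100)
  s2 <- posterior_summary(mk(x), level = 0.95)
  q7 <- function(p) { h <- (100 - 1) * p + 1; lo <- floor(h); x[lo] + (h - lo) * (x[lo + 1] - x[lo]) }
  expect_equal(s2$lower, q7(0.025))
  expect_equal(s2$upper, q7(0.975))

  sym <- mk(c(-(1:50), 1:50))
  expect_false(posterior_summary(sym)$credible)

  widths <- vapply(c(0.5, 0.8, 0.9, 0.95, 0.99), function(l) {
    ss <- posterior_summary(mk(rnorm(500)), level = l)
    ss$upper - ss$lower
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
  expect_error(posterior_summary(mk(x), level = 1.2), "level")
})

test_that("DIC decomposes exactly and degenerates to zero pD", {
  sim <- simulate_dataset(synthetic_scenario(seed = 13))
  spec <- lhfi_model("model1")
  design <- build_centered_design(sim$covariates, spec$health_covariates)
  dr <- run_chains(sim$counts, design, sim$covariates, spec,
                   config = mcmc_config(n_iter = 800L, burn_in = 300L,
                                        thin = 10L, seed = 6L))
  d <- dic(dr, sim$counts, design, sim$covariates)
  expect_equal(d$DIC, 2 * d$Dbar - (d$Dbar - d$pD), tolerance = 1e-9)
  expect_gt(d$pD, 0)

  # degenerate posterior: every draw identical -> pD = 0, DIC = D(theta-bar);
  # also cross-checks the compiled deviance against the R likelihood
  frozen <- dr
  one <- dr$chains[[1]][nrow(dr$chains[[1]]), , drop = FALSE]
  frozen$chains <- list(one[rep(1, 50), ], one[rep(1, 50), ])
  frozen$burn_in <- 10L
  d0 <- dic(frozen, sim$counts, design, sim$covariates)
  expect_equal(d0$pD, 0, tolerance = 1e-6)
  expect_equal(d0$DIC, d0$Dbar, tolerance = 1e-6)

  # a parameter the deviance ignores leaves DIC unchanged
  aug <- dr
  aug$chains <- lapply(dr$chains, function(m)
    cbind(m, ignored = rnorm(nrow(m))))
  aug$param_names <- c(dr$param_names, "ignored")
  d2 <- dic(aug, sim$counts, design, sim$covariates)
  expect_equal(d2$DIC, d$DIC, tolerance = 1e-9)
})

test_that("pD approximates the parameter count on a conjugate Gaussian toy", {
  # p independent means, known unit variance, flat-ish prior: pD ~ p
  set.seed(14)
  p <- 5; n <- 40; M <- 40000
  y <- matrix(rnorm(p * n, mean = rep(1:p, each = n)), nrow = n)
  ybar <- colMeans(y)
  mu_draws <- matrix(rnorm(M * p, mean = rep(ybar, each = M),
                           sd = 1 / sqrt(n)), nrow = M)
  dev <- vapply(seq_len(M), function(m) {
    -2 * sum(dnorm(y, rep(mu_draws[m, ], each = n), 1, log = TRUE))
  }, numeric(1))
  dev_at_mean <- -2 * sum(dnorm(y, rep(colMeans(mu_draws), each = n), 1,
                                log = TRUE))
  out <- lhfi:::.dic_core(dev, dev_at_mean)
  expect_lt(abs(out$pD - p) / p, 0.1)
  expect_equal(out$DIC, out$Dbar + out$pD)
})

test_that("health tables rank sites and flag interval overlap", {
  mk <- function(h1, h2, sd = 0.1) {
    m <- cbind("H[1]" = rnorm(400, h1, sd), "H[2]" = rnorm(400, h2, sd))
    fake_draws(list(m), S = 2)
  }
  set.seed(15)
  ht <- health_table(mk(-3, 3))
  expect_equal(ht$rank, c(1L, 2L))
  expect_equal(ht$n_ci_overlap, c(0L, 0L))

  ht2 <- health_table(mk(0, 0, sd = 1))
  expect_equal(attr(ht2, "pairwise_overlap"), 1)

  m1 <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "H[1]"))
  ht3 <- health_table(fake_draws(list(m1), S = 1))
  expect_equal(ht3$rank, 1L)
})

test_that("sites simulated far apart in health get disjoint intervals and the right order", {
  sc <- synthetic_scenario(seed = 23, truth = synthetic_truth(
    beta = c(dd = 1.2), sigma_eps = 0.05))
  sim <- simulate_dataset(sc)
  spec <- lhfi_model("model1")
  design <- build_centered_design(sim$covariates, spec$health_covariates)
  dr <- run_chains(sim$counts, design, sim$covariates, spec,
                   config = mcmc_config(n_iter = 3000L, burn_in = 1000L,
                                        thin = 10L, seed = 7L))
  ht <- health_table(dr)
  # site 1 (dd = 0) and site 18 (dd = 5.45) differ in truth by ~6.5 latent sd
  expect_lt(ht$rank[1], ht$rank[18])
  expect_lt(ht$upper[1], ht$lower[18])
})

test_that("variance-ratio posterior summarizes per-draw ratios", {
  spec3 <- lhfi_model("model3")
  mk <- function(bsal, se, ss) {
    m <- cbind("H[1]" = rnorm(200), "beta[salinity]" = bsal,
               sigma_eps = se, sigma_s = ss)
    fake_draws(list(m), spec = spec3, S = 1)
  }
  vr <- variance_ratio_posterior(mk(0, runif(200, 0.5, 2), runif(200, 0.5, 2)))
  expect_true(all(vr$draws == 1))

  set.seed(16)
  vr2 <- variance_ratio_posterior(mk(rnorm(200), runif(200, 0.5, 2),
                                     runif(200, 0.5, 2)))
  expect_true(all(vr2$draws > 0 & vr2$draws <= 1))

  m <- matrix(rnorm(100), ncol = 1, dimnames = list(NULL, "H[1]"))
  expect_error(variance_ratio_posterior(fake_draws(list(m), S = 1)),
               "two-level")
})
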