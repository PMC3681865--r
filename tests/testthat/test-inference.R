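empty_counts <- function() {
  benthic_dataset(data.frame(site = integer(0), month = character(0),
                             replicate = integer(0), m1 = integer(0),
                             m2 = integer(0), m3 = integer(0),
                             m4 = integer(0), m5 = integer(0),
                             total = integer(0)))
}

test_that("initial states are seeded, dispersed and valid", {
  cov <- synthetic_covariate_table(seed = 1)
  spec <- lhfi_model("model1")
  design <- build_centered_design(cov, spec$health_covariates)
  data <- read_counts_csv(system.file("extdata", "synthetic_counts.csv",
                                      package = "lhfi"))

  s1 <- initialize_state(spec, data, design, seed = 1)
  s1b <- initialize_state(spec, data, design, seed = 1)
  s2 <- initialize_state(spec, data, design, seed = 2)
  expect_identical(s1, s1b)
  expect_false(isTRUE(all.equal(s1$H, s2$H)))
  expect_true(is.finite(log_posterior(s1, data, design, cov, spec)))
  expect_true(state_in_support(s1, spec))
})

test_that("hierarchical centering is a bijection preserving the density", {
  cov <- synthetic_covariate_table(seed = 2)
  spec <- lhfi_model("model1")
  design <- build_centered_design(cov, spec$health_covariates)
  st <- rand_state(design, spec, seed = 5)
  st$H <- rnorm(nrow(cov))

  back <- hierarchical_uncenter(hierarchical_center(st, design, spec),
                                design, spec)
  expect_equal(back$H, st$H, tolerance = 1e-12)

  # the location shift has unit Jacobian: the centered deviations evaluated
  # against a zero-mean regression give the same density value
  ctr <- hierarchical_center(st, design, spec)
  ctr$beta0 <- 0
  ctr$beta[] <- 0
  expect_equal(latent_health_loglik(ctr, design, spec),
               latent_health_loglik(st, design, spec), tolerance = 1e-12)

  # with no regression signal the transform is the identity on H
  st0 <- st
  st0$beta0 <- 0
  st0$beta[] <- 0
  expect_equal(hierarchical_center(st0, design, spec)$H, st0$H)
})

test_that("chains are bit-reproducible for a fixed seed", {
  sim <- simulate_dataset(synthetic_scenario(seed = 8))
  spec <- lhfi_model("model1")
  design <- build_centered_design(sim$covariates, spec$health_covariates)
  cfg <- mcmc_config(n_iter = 400L, burn_in = 100L, thin = 10L, seed = 33L)
  d1 <- run_chains(sim$counts, design, sim$covariates, spec, config = cfg)
  d2 <- run_chains(sim$counts, design, sim$covariates, spec, config = cfg)
  expect_identical(d1$chains, d2$chains)
  d3 <- run_chains(sim$counts, design, sim$covariates, spec,
                   config = mcmc_config(n_iter = 400L, burn_in = 100L,
                                        thin = 10L, seed = 34L))
  expect_false(identical(d1$chains[[1]], d3$chains[[1]]))
})

test_that("every stored draw respects the parameter support", {
  sim <- simulate_dataset(synthetic_scenario(seed = 9))
  spec <- model_spec("dd", metric_cov_structure = "block_diagonal",
                     name = "blk")
  design <- build_centered_design(sim$covariates, spec$health_covariates)
  dr <- run_chains(sim$counts, design, sim$covariates, spec,
                   config = mcmc_config(n_iter = 600L, burn_in = 200L,
                                        thin = 10L, seed = 2L))
  pooled <- do.call(rbind, dr$chains)
  expect_true(all(pooled[, "sigma_eps"] > 0))
  for (r in sample(nrow(pooled), 25)) {
    st <- lhfi:::.row_to_state(pooled[r, ], spec, dr$S)
    expect_true(state_in_support(st, spec))
  }
  expect_false(any(dr$meta$divergent))
})

test_that("with no count data the sampler reproduces the prior for beta0", {
  cov <- synthetic_covariate_table(seed = 4)
  spec <- lhfi_model("model1")
  design <- build_centered_design(cov, spec$health_covariates)
  dr <- run_chains(empty_counts(), design, cov, spec,
                   config = mcmc_config(n_chains = 2L, n_iter = 6000L,
                                        burn_in = 1000L, thin = 10L, seed = 5L))
  b0 <- do.call(rbind, lapply(dr$chains, function(m) m[1001:6000, "beta0"]))
  m <- mean(b0); v <- var(as.numeric(b0))
  # batch-means Monte Carlo s.e. for the mean of an autocorrelated chain
  bm <- tapply(as.numeric(t(b0)), rep(1:100, length.out = length(b0)), mean)
  se <- sd(bm) / sqrt(length(bm))
  expect_lt(abs(m - 0), 4 * se + 0.5)
  expect_gt(v, 100 * 0.6)
  expect_lt(v, 100 * 1.5)
})

test_that("permuting site order permutes health draws and fixes scalars", {
  sc <- synthetic_scenario(seed = 21)
  sim <- simulate_dataset(sc)
  spec <- lhfi_model("model1")
  perm <- c(10:18, 1:9)
  inv <- order(perm)

  cov_p <- as.data.frame(sim$covariates)[perm, ]
  cov_p$site <- seq_len(18)
  cov_p <- covariate_table(cov_p)
  cnt_p <- as.data.frame(sim$counts)
  cnt_p$site <- inv[cnt_p$site]
  cnt_p <- benthic_dataset(cnt_p)

  cfg <- mcmc_config(n_iter = 6000L, burn_in = 2000L, thin = 10L, seed = 3L)
  d1 <- run_chains(sim$counts,
                   build_centered_design(sim$covariates, "dd"),
                   sim$covariates, spec, config = cfg)
  d2 <- run_chains(cnt_p, build_centered_design(cov_p, "dd"), cov_p, spec,
                   config = cfg)
  s1 <- posterior_summary(d1)
  s2 <- posterior_summary(d2)
  get <- function(s, p) s$mean[s$parameter == p]
  for (p in c("beta[dd]", "sigma_eps", "beta0"))
    expect_equal(get(s1, p), get(s2, p), tolerance = 0.12)
  h1 <- vapply(1:18, function(i) get(s1, sprintf("H[%d]", i)), numeric(1))
  h2 <- vapply(1:18, function(i) get(s2, sprintf("H[%d]", i)), numeric(1))
  expect_equal(h2, h1[perm], tolerance = 0.25)
})
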