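test_that("linear predictor combines group, metric and signed health effects", {
  expect_equal(linear_predictor(0, 0, 0, 1), 0)
  expect_equal(linear_predictor(1.5, 0.2, -0.1, -1), -1.4)
  h <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(linear_predictor(h, 0.3, 0.1, 1)) > 0))
  expect_true(all(diff(linear_predictor(h, 0.3, 0.1, -1)) < 0))
})

test_that("generalized-logit probabilities match the closed form", {
  expect_equal(group_probabilities(c(0, 0)), c(1, 1, 1) / 3,
               ignore_attr = TRUE)
  expect_equal(group_probabilities(log(2)), c(2 / 3, 1 / 3),
               ignore_attr = TRUE)
  set.seed(1)
  for (k in 1:50) {
    etas <- runif(sample(1:4, 1), -6, 6)
    p <- group_probabilities(etas)
    direct <- c(exp(etas), 1) / (1 + sum(exp(etas)))
    expect_equal(p, direct, tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0 & p < 1))
  }
  # overflow guard: huge predictors stay finite and normalized
  p <- group_probabilities(c(800, 805, -3))
  expect_true(all(is.finite(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_error(group_probabilities(c(0, NaN)), "non-finite")
})

test_that("shifting all predictors by c scales the odds against the baseline by exp(c)", {
  etas <- c(0.4, -1.2, 2.1)
  for (c0 in c(-1, 0.5, 2)) {
    p0 <- group_probabilities(etas)
    p1 <- group_probabilities(etas + c0)
    odds0 <- p0[1:3] / p0[4]
    odds1 <- p1[1:3] / p1[4]
    expect_equal(odds1, exp(c0) * odds0, tolerance = 1e-10)
  }
})

test_that("observation log-likelihood matches the multinomial pmf oracle", {
  scheme <- metric_scheme()
  # single organism classified into metric 1, all effects zero:
  # plus term log(1/3), minus term log(1/4)
  d1 <- benthic_dataset(data.frame(site = 1L, month = "Sep", replicate = 1L,
                                   m1 = 1L, m2 = 0L, m3 = 0L, m4 = 0L,
                                   m5 = 0L, total = 1L))
  st0 <- param_state(H = 0, delta_minus = 0, gamma = numeric(5))
  expect_equal(observation_loglik(d1, scheme, st0), log(1 / 3) + log(1 / 4),
               tolerance = 1e-12)

  # all organisms unclassified: total * (log p0_plus + log p0_minus)
  d2 <- benthic_dataset(data.frame(site = 1L, month = "Sep", replicate = 1L,
                                   m1 = 0L, m2 = 0L, m3 = 0L, m4 = 0L,
                                   m5 = 0L, total = 12L))
  expect_equal(observation_loglik(d2, scheme, st0),
               12 * (log(1 / 3) + log(1 / 4)), tolerance = 1e-10)

  # random datasets and states against the independent dmultinom oracle
  for (seed in 1:20) {
    data <- rand_small_data(S = 3, seed = seed)
    design <- build_centered_design(tiny_cov(), "dd")
    st <- rand_state(design, lhfi_model("model1"), seed = seed)
    st$H <- rnorm(3)
    expect_equal(observation_loglik(data, scheme, st),
                 oracle_obs_loglik(data, scheme, st), tolerance = 1e-10)
  }
})

test_that("raising health raises plus-group and lowers minus-group probabilities", {
  scheme <- metric_scheme()
  st <- param_state(H = 0, delta_minus = 0.3, gamma = c(0.2, -0.1, 0.4, 0, -0.2))
  probs_at <- function(h) {
    pp <- group_probabilities(linear_predictor(h, 0, st$gamma[1:2], 1))
    pm <- group_probabilities(linear_predictor(h, st$delta_minus, st$gamma[3:5], -1))
    list(plus = pp[1:2], minus = pm[1:3], rem = c(pp[3], pm[4]))
  }
  lo <- probs_at(-0.5); hi <- probs_at(0.5)
  expect_true(all(hi$plus > lo$plus))
  expect_true(all(hi$minus < lo$minus))
  expect_lt(hi$rem[1], lo$rem[1])   # plus-group remainder falls
  expect_gt(hi$rem[2], lo$rem[2])   # minus-group remainder rises
})

test_that("latent health regression density matches the normal oracle", {
  cov <- synthetic_covariate_table(seed = 5)
  spec <- lhfi_model("model1")
  design <- build_centered_design(cov, spec$health_covariates)
  S <- nrow(cov)

  st <- rand_state(design, spec, seed = 2)
  st$H <- st$beta0 + as.numeric(design$X %*% st$beta)  # at the mean
  st$sigma_eps <- 1
  expect_equal(latent_health_loglik(st, design, spec), -S / 2 * log(2 * pi),
               tolerance = 1e-12)
  st$sigma_eps <- 2
  expect_equal(latent_health_loglik(st, design, spec),
               -S / 2 * log(2 * pi) - S * log(2), tolerance = 1e-12)

  st <- rand_state(design, spec, seed = 3)
  mu <- st$beta0 + as.numeric(design$X %*% st$beta)
  expect_equal(latent_health_loglik(st, design, spec),
               sum(dnorm(st$H, mu, st$sigma_eps, log = TRUE)),
               tolerance = 1e-12)
  st$beta <- c(st$beta, extra = 1)
  expect_error(latent_health_loglik(st, design, spec), "length")
})

test_that("salinity regression density matches the least-squares oracle", {
  cov <- synthetic_covariate_table(seed = 6)
  spec3 <- lhfi_model("model3")
  design <- build_centered_design(cov, spec3$health_covariates)
  S <- nrow(cov)

  st <- rand_state(design, spec3, seed = 4)
  st$b0 <- 0; st$b1 <- 0; st$sigma_s <- 1
  # with a zero regression the density is that of the centered residuals
  expect_equal(salinity_loglik(cov, design, st, spec3),
               sum(dnorm(design$centered_salinity, 0, 1, log = TRUE)),
               tolerance = 1e-12)

  # an exact fit at sigma_s = 1 gives -(S/2) log(2 pi)
  fit <- lm(design$centered_salinity ~ design$centered_dd)
  st$b0 <- coef(fit)[1]; st$b1 <- coef(fit)[2]
  res <- residuals(fit)
  expect_equal(salinity_loglik(cov, design, st, spec3),
               sum(dnorm(res, 0, 1, log = TRUE)), tolerance = 1e-10)

  st2 <- st
  expect_error(salinity_loglik(cov, design, st2, lhfi_model("model1")),
               "two-level")
})

test_that("metric-effect prior handles iid, block and unstructured covariances", {
  spec_iid <- lhfi_model("model1")
  spec_blk <- model_spec("dd", metric_cov_structure = "block_diagonal")
  spec_un <- model_spec("dd", metric_cov_structure = "unstructured")

  st <- param_state(H = 0, gamma = numeric(5), sigma_gamma = 1,
                    Sigma = list(pp = diag(2), mm = diag(3), pm = matrix(0, 2, 3)))
  expect_equal(metric_effect_logprior(numeric(5), st, spec_iid),
               -5 / 2 * log(2 * pi), tolerance = 1e-12)

  set.seed(7)
  g <- rnorm(5)
  expect_equal(metric_effect_logprior(g, st, spec_blk),
               metric_effect_logprior(g, st, spec_iid), tolerance = 1e-12)

  # unstructured SPD covariance against a determinant/solve oracle
  A <- matrix(rnorm(25), 5)
  Sig <- crossprod(A) + diag(5)
  st$Sigma <- list(pp = Sig[1:2, 1:2], mm = Sig[3:5, 3:5], pm = Sig[1:2, 3:5])
  oracle <- -0.5 * (5 * log(2 * pi) +
                    determinant(Sig, logarithm = TRUE)$modulus[1] +
                    drop(t(g) %*% solve(Sig) %*% g))
  expect_equal(metric_effect_logprior(g, st, spec_un), oracle,
               tolerance = 1e-10, ignore_attr = TRUE)

  st$Sigma$pp <- matrix(c(1, 2, 2, 1), 2)  # not positive definite
  expect_error(metric_effect_logprior(g, st, spec_blk), "positive definite")
})

test_that("joint log prior matches its component densities and support rules", {
  spec <- lhfi_model("model1")
  st <- param_state(H = numeric(2), delta_minus = 0, gamma = numeric(5),
                    beta0 = 0, beta = c(dd = 0), sigma_eps = 1,
                    sigma_gamma = 1)
  pr <- prior_spec()
  ld_ig <- function(v, a, b) a * log(b) - lgamma(a) - (a + 1) * log(v) - b / v
  expected <- 3 * dnorm(0, 0, 10, log = TRUE) +     # delta, beta0, beta[dd]
    2 * ld_ig(1, 1, 1) +                            # sigma_eps^2, sigma_gamma^2
    5 * dnorm(0, 0, 1, log = TRUE)                  # gamma | sigma_gamma
  expect_equal(log_prior(st, spec, pr), expected, tolerance = 1e-12)

  st_bad <- st
  st_bad$sigma_eps <- -1
  expect_identical(log_prior(st_bad, spec, pr), -Inf)

  # bivariate coefficient prior with rho = 0 factorizes
  spec4 <- lhfi_model("model4")
  spec3 <- lhfi_model("model3")
  st2 <- param_state(H = numeric(2), gamma = numeric(5),
                     beta = c(salinity = 0.4), sigma_eps = 1, sigma_gamma = 1,
                     b0 = 0.3, b1 = -0.7, sigma_s = 1, rho = 0)
  expect_equal(log_prior(st2, spec4, pr), log_prior(st2, spec3, pr) + log(0.5),
               tolerance = 1e-12)
})

test_that("log posterior is the sum of its components and ignores inactive levels", {
  scheme <- metric_scheme()
  data <- tiny_counts()
  cov <- tiny_cov()
  spec <- lhfi_model("model1")
  design <- build_centered_design(cov, spec$health_covariates)
  st <- rand_state(design, spec, seed = 11)

  expect_equal(log_posterior(st, data, design, cov, spec),
               observation_loglik(data, scheme, st) +
                 latent_health_loglik(st, design, spec) +
                 log_prior(st, spec, prior_spec()),
               tolerance = 1e-12)

  # dropping a site's records changes the posterior by that site's likelihood
  sub <- benthic_dataset(as.data.frame(data[data$site == 1, ]))
  one <- benthic_dataset(local({
    d <- as.data.frame(data[data$site == 2, ]); d$site <- 1L; d
  }))
  st1 <- st; st1$H <- st$H[2]
  expect_equal(log_posterior(st, data, design, cov, spec) -
                 log_posterior(st, sub, design, cov, spec),
               observation_loglik(one, scheme, st1), tolerance = 1e-10)

  # single-level models do not depend on the salinity-regression block
  st_b <- st
  st_b$b0 <- 5; st_b$b1 <- -3; st_b$sigma_s <- 0.1
  expect_equal(log_posterior(st_b, data, design, cov, spec),
               log_posterior(st, data, design, cov, spec), tolerance = 1e-12)
})

test_that("iid and identity-block structures agree up to the variance hyperprior", {
  data <- tiny_counts()
  cov <- tiny_cov()
  spec_iid <- lhfi_model("model1")
  spec_blk <- model_spec("dd", metric_cov_structure = "block_diagonal")
  design <- build_centered_design(cov, "dd")
  st <- rand_state(design, spec_iid, seed = 12)
  st$sigma_gamma <- 1
  st$Sigma <- list(pp = diag(2), mm = diag(3), pm = matrix(0, 2, 3))
  gap <- function(g) {
    st$gamma <- g
    log_posterior(st, data, design, cov, spec_iid) -
      log_posterior(st, data, design, cov, spec_blk)
  }
  # the difference is the hyperprior normalizing terms only: constant in gamma
  gaps <- vapply(1:5, function(s) gap(rnorm(5)), numeric(1))
  expect_lt(diff(range(gaps)), 1e-10)
})

test_that("the two-level model collapses to a single DD regression", {
  expect_equal(collapse_two_level(1.2, 0, 3, 4, 0.5, 2),
               list(intercept = 1.2, dd_coefficient = 0,
                    total_error_variance = 0.25))
  col <- collapse_two_level(0, 1, 0, 0.77, 1, 1)
  expect_equal(col$dd_coefficient, 0.77)
  expect_equal(col$total_error_variance, 2)
})

test_that("variance ratio behaves as an explained-variation share", {
  expect_equal(variance_ratio(1, 0, 5), 1)
  expect_equal(variance_ratio(1, 1, 1), 0.5)
  bs <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(variance_ratio(1, bs, 1)) < 0))
  ss <- seq(0.1, 3, by = 0.1)
  expect_true(all(diff(variance_ratio(1, 1, ss)) < 0))
})
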