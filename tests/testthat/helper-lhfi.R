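# Shared fixtures and independent oracles, all built in code.

# a small two-site dataset with known counts
tiny_counts <- function() {
  benthic_dataset(data.frame(
    site = c(1L, 1L, 2L, 2L, 2L),
    month = c("Sep", "Sep", "Oct", "Oct", "Oct"),
    replicate = c(1L, 2L, 1L, 2L, 3L),
    m1 = c(3L, 5L, 0L, 2L, 1L), m2 = c(0L, 1L, 4L, 0L, 2L),
    m3 = c(10L, 8L, 2L, 5L, 3L), m4 = c(2L, 0L, 1L, 1L, 0L),
    m5 = c(0L, 1L, 0L, 3L, 2L),
    total = c(40L, 30L, 20L, 25L, 15L)
  ))
}

tiny_cov <- function() {
  covariate_table(data.frame(
    site = 1:2, month = c("Sep", "Oct"), depth_m = c(2, 5),
    temp_c = c(16, 12), salinity_ppt = c(15, 22), silt_clay = c(0.3, 0.6),
    median_grain = c(150, 120), sorting = c(1.4, 1.6),
    organic_pct = c(2, 3), dd_km = c(0, 3)
  ))
}

# a random-but-valid parameter state for a given design
rand_state <- function(design, spec, seed = 1) {
  set.seed(seed)
  S <- length(design$centered_dd)
  p <- ncol(design$X)
  param_state(
    H = rnorm(S), delta_minus = rnorm(1), gamma = rnorm(5, 0, 0.5),
    beta0 = rnorm(1), beta = setNames(rnorm(p), colnames(design$X)),
    sigma_eps = if (spec$month_specific_variance) c(Sep = 0.8, Oct = 1.2) else
      runif(1, 0.5, 1.5),
    sigma_gamma = runif(1, 0.5, 1.5),
    b0 = rnorm(1), b1 = rnorm(1), sigma_s = runif(1, 0.5, 1.5),
    Sigma = if (spec$metric_cov_structure != "iid")
      list(pp = diag(2), mm = diag(3), pm = matrix(0, 2, 3)) else NULL,
    rho = 0
  )
}

# independent oracle: observation log-likelihood by per-record dmultinom
# with naively computed softmax-with-baseline probabilities
oracle_obs_loglik <- function(data, scheme, state) {
  ll <- 0
  for (r in seq_len(nrow(data))) {
    i <- data$site[r]
    n <- data$total[r]
    y <- as.numeric(data[r, paste0("m", 1:5)])
    ep <- state$gamma[scheme$plus] + state$H[i]
    pp <- c(exp(ep), 1) / (1 + sum(exp(ep)))
    yp <- c(y[scheme$plus], n - sum(y[scheme$plus]))
    em <- state$delta_minus + state$gamma[scheme$minus] - state$H[i]
    pm <- c(exp(em), 1) / (1 + sum(exp(em)))
    ym <- c(y[scheme$minus], n - sum(y[scheme$minus]))
    ll <- ll + dmultinom(yp, prob = pp, log = TRUE) +
      dmultinom(ym, prob = pm, log = TRUE)
  }
  ll
}

# a random small dataset consistent with the model's support
rand_small_data <- function(S = 3, seed = 1) {
  set.seed(seed)
  recs <- lapply(seq_len(S), function(i) {
    nr <- sample(2:3, 1)
    total <- sample(10:40, nr, replace = TRUE)
    counts <- t(vapply(total, function(n) {
      y <- as.integer(rmultinom(1, n, rep(1 / 7, 7))[1:5])
      y
    }, integer(5)))
    data.frame(site = i, month = if (i %% 2) "Sep" else "Oct",
               replicate = seq_len(nr), m1 = counts[, 1], m2 = counts[, 2],
               m3 = counts[, 3], m4 = counts[, 4], m5 = counts[, 5],
               total = total)
  })
  benthic_dataset(do.call(rbind, recs))
}

# minimal posterior_draws object wrapping given chain matrices
fake_draws <- function(chains, spec = lhfi_model("model1"), burn_in = 0L,
                       S = NULL) {
  if (is.null(S)) {
    hcols <- grep("^H\\[", colnames(chains[[1]]))
    S <- length(hcols)
  }
  structure(list(chains = chains, param_names = colnames(chains[[1]]),
                 burn_in = burn_in, spec = spec,
                 priors = prior_spec(),
                 config = mcmc_config(n_chains = length(chains),
                                      n_iter = nrow(chains[[1]]),
                                      burn_in = max(0L, nrow(chains[[1]]) - 1L),
                                      thin = 1L),
                 S = S, meta = list()),
            class = "posterior_draws")
}
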