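## Synthetic-data generator mirroring the Richibucto study design: 18 sites
## (13 September, 5 October), 2-3 replicate grabs per site, a fixed
## distance-downstream gradient, salinity collinear with distance, and
## multinomial AMBI metric counts driven by latent site health.

#' Distance downstream (km) of the 18 Richibucto sites
#'
#' The fixed straight-line projection distances used as the default `dd`
#' gradient of the synthetic generator.
#'
#' @export
richibucto_dd <- c(0, 1.164, 1.298, 1.731, 2.179, 1.686, 2.463, 2.970, 3.433,
                   3.790, 3.358, 3.880, 4.119, 3.642, 4.179, 4.701, 5.060, 5.448)

#' Generating parameter values for synthetic datasets
#'
#' Defaults are chosen on the scale of the posterior summaries typical for
#' estuarine LHFI fits: slopes of a few tenths to about 1, error standard
#' deviations around 0.6-1.1.  When `sigma_s` is `NULL` it is derived from
#' the target DD-salinity correlation (see
#' [richibucto_like_covariates()]), keeping the generated collinearity at
#' the requested level.
#'
#' @param beta named numeric vector of health-regression coefficients; the
#'   names select which covariates drive latent health (see
#'   [build_centered_design()]).
#' @param beta0 health regression intercept.
#' @param delta_minus minus-group fixed effect.
#' @param gamma 5 metric effects.
#' @param b0,b1 salinity-on-DD intercept (centered scale) and slope (ppt/km).
#' @param sigma_eps latent regression error s.d.
#' @param sigma_s salinity regression error s.d. (`NULL` = derive from the
#'   scenario's target correlation).
#' @param sigma_gamma metric-effect s.d.
#' @return an object of class `synthetic_truth` (a list).
#' @export
synthetic_truth <- function(beta = c(dd = 0.4), beta0 = 0, delta_minus = -1.1,
                            gamma = c(-0.9, -1.3, 0.2, -0.2, 0),
                            b0 = 0, b1 = 0.77, sigma_eps = 0.7,
                            sigma_s = NULL, sigma_gamma = 1) {
  stopifnot(length(gamma) == 5, sigma_eps >= 0, sigma_gamma > 0)
  if (length(beta) > 0 && is.null(names(beta)))
    stop("truth beta must be named by covariate")
  structure(list(beta = beta, beta0 = beta0, delta_minus = delta_minus,
                 gamma = as.numeric(gamma), b0 = b0, b1 = b1,
                 sigma_eps = sigma_eps, sigma_s = sigma_s,
                 sigma_gamma = sigma_gamma),
            class = "synthetic_truth")
}

#' Synthetic study scenario
#'
#' Describes the design to emulate: number of sites (18, with the distance
#' gradient fixed to the Richibucto values), the lopsided September/October
#' split (13 vs 5 sites), 2-3 replicate grabs per site, grab totals, target
#' covariate collinearity, and the generating truth.
#'
#' @param n_sites number of sites (>= 2; 18 reproduces the study design).
#' @param oct_sites integer sites sampled in October (default 4-8, the five
#'   upper-channel sites; the rest are September).
#' @param replicates `"alternate"` (3 grabs at odd sites, 2 at even) or an
#'   integer vector of per-site replicate counts.
#' @param totals_range range of the per-grab total organism count, drawn
#'   uniformly.
#' @param target_dd_sal_corr target correlation between distance downstream
#'   and salinity (default 0.88).
#' @param target_dd_logdepth_corr,target_dd_logsc_corr target correlations
#'   of log-depth and log silt-clay with distance downstream (defaults 0.16
#'   and -0.47).
#' @param sal_mean mean salinity (ppt) at the centroid of the gradient.
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return an object of class `synthetic_scenario` (a list).
#' @export
synthetic_scenario <- function(n_sites = 18L, oct_sites = 4:8,
                               replicates = "alternate",
                               totals_range = c(150L, 400L),
                               target_dd_sal_corr = 0.88,
                               target_dd_logdepth_corr = 0.16,
                               target_dd_logsc_corr = -0.47,
                               sal_mean = 20,
                               truth = synthetic_truth(),
                               seed = 1L) {
  n_sites <- as.integer(n_sites)
  if (n_sites < 2L) stop("n_sites must be >= 2")
  if (any(totals_range < 1L)) stop("grab totals must be >= 1")
  structure(list(n_sites = n_sites, oct_sites = intersect(oct_sites, seq_len(n_sites)),
                 replicates = replicates, totals_range = as.integer(totals_range),
                 target_dd_sal_corr = target_dd_sal_corr,
                 target_dd_logdepth_corr = target_dd_logdepth_corr,
                 target_dd_logsc_corr = target_dd_logsc_corr,
                 sal_mean = sal_mean, truth = truth, seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# s.d. of the salinity noise that makes corr(dd, salinity) hit the target
.derive_sigma_s <- function(b1, dd, r) {
  if (r <= 0 || r >= 1) stop("target correlation must lie in (0, 1)")
  abs(b1) * sd(dd) * sqrt(1 / r^2 - 1)
}

#' Generate a Richibucto-like covariate table
#'
#' Distance downstream is the fixed 18-site gradient (or equally spaced over
#' the same span for other site counts).  Salinity follows the generating
#' salinity-on-DD line plus Gaussian noise whose scale is set so the
#' DD-salinity correlation targets the scenario's value (0.88 by default);
#' log-depth and log silt-clay are drawn with weak target correlations to
#' DD (0.16 and -0.47).  The remaining columns are filled with plausible
#' estuarine values and are not used by the shipped model presets.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a [covariate_table()]; the derived salinity noise s.d. is
#'   attached as attribute `"sigma_s"`.
#' @export
richibucto_like_covariates <- function(scenario = synthetic_scenario()) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(scenario$seed)

  n <- scenario$n_sites
  dd <- if (n == 18L) richibucto_dd else
    seq(0, max(richibucto_dd), length.out = n)
  tr <- scenario$truth
  sigma_s <- if (is.null(tr$sigma_s))
    .derive_sigma_s(tr$b1, dd, scenario$target_dd_sal_corr) else tr$sigma_s
  dd_c <- dd - mean(dd)
  salinity <- scenario$sal_mean + tr$b0 + tr$b1 * dd_c + rnorm(n, 0, sigma_s)

  z_dd <- as.numeric(scale(dd))
  corr_col <- function(r, mean, sdev) {
    z <- r * z_dd + sqrt(1 - r^2) * rnorm(n)
    mean + sdev * z
  }
  depth <- exp(corr_col(scenario$target_dd_logdepth_corr, log(3), 0.5))
  silt_clay <- pmin(exp(corr_col(scenario$target_dd_logsc_corr, log(0.35), 0.5)), 0.999)

  month <- ifelse(seq_len(n) %in% scenario$oct_sites, "Oct", "Sep")
  temp <- rnorm(n, ifelse(month == "Oct", 12, 16), 1.5)
  covariate_table(data.frame(
    site = seq_len(n), month = month, depth_m = depth, temp_c = temp,
    salinity_ppt = salinity, silt_clay = silt_clay,
    median_grain = exp(rnorm(n, log(150), 0.3)),
    sorting = rnorm(n, 1.5, 0.2),
    organic_pct = exp(rnorm(n, log(2), 0.4)),
    dd_km = dd
  )) -> cov
  attr(cov, "sigma_s") <- sigma_s
  cov
}

#' Convenience wrapper: a seeded Richibucto-like covariate table
#'
#' @param seed integer seed.
#' @return a [covariate_table()].
#' @export
synthetic_covariate_table <- function(seed = 1L) {
  richibucto_like_covariates(synthetic_scenario(seed = seed))
}

#' Simulate latent health from the generating regression
#'
#' `H_i = beta0 + x_i' beta + eps_i`, `eps_i ~ N(0, sigma_eps^2)`, with the
#' centered design built from the scenario's own covariate means.
#'
#' @param cov a [covariate_table()].
#' @param truth a [synthetic_truth()].
#' @param seed integer seed.
#' @return numeric vector of latent health values, one per site.
#' @export
simulate_latent <- function(cov, truth, seed = 1L) {
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  design <- build_centered_design(cov, names(truth$beta))
  mu <- truth$beta0 + if (ncol(design$X) > 0)
    as.numeric(design$X %*% truth$beta) else 0
  mu + rnorm(nrow(cov), 0, truth$sigma_eps)
}

#' Simulate metric counts given latent health
#'
#' For each grab the plus-group counts (and the grab remainder) are drawn
#' from the plus multinomial at the generalized-logit probabilities; the
#' minus-group counts are then allocated from within that remainder using
#' the minus probabilities renormalized by the plus-remainder probability,
#' `q_m = p_m / p0_plus`.  When the generating composition is feasible
#' (the five metrics together do not exceed the grab), this makes each
#' group's counts *exactly* multinomial at its own link probabilities, so
#' the only aspect the fitted two-multinomial likelihood ignores is the
#' dependence induced by the shared remainder.  Infeasible combinations are
#' capped: the renormalized probabilities are rescaled to sum to 1 and the
#' within-remainder baseline drops to 0.
#'
#' @param H latent health per site.
#' @param truth a [synthetic_truth()].
#' @param scheme a [metric_scheme()].
#' @param totals data frame with columns `site`, `month`, `replicate`,
#'   `total` (one row per grab, totals >= 1).
#' @param seed integer seed.
#' @return a [benthic_dataset()].
#' @export
simulate_counts <- function(H, truth, scheme = metric_scheme(), totals,
                            seed = 1L) {
  if (any(totals$total <= 0)) stop("grab totals must be positive")
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  n_rec <- nrow(totals)
  counts <- matrix(0L, n_rec, 5)
  for (r in seq_len(n_rec)) {
    h <- H[totals$site[r]]
    n <- totals$total[r]
    p_plus <- group_probabilities(
      linear_predictor(h, 0, truth$gamma[scheme$plus], 1))
    y_plus <- as.integer(stats::rmultinom(1, n, p_plus))
    n_rest <- y_plus[length(y_plus)]
    p_minus <- group_probabilities(
      linear_predictor(h, truth$delta_minus, truth$gamma[scheme$minus], -1))
    p0_plus <- p_plus[length(p_plus)]
    q <- p_minus[seq_along(scheme$minus)] / p0_plus
    q <- if (sum(q) > 1) c(q / sum(q), 0) else c(q, 1 - sum(q))
    y_minus <- if (n_rest > 0)
      as.integer(stats::rmultinom(1, n_rest, q)) else
      integer(length(q))
    counts[r, scheme$plus] <- y_plus[seq_along(scheme$plus)]
    counts[r, scheme$minus] <- y_minus[seq_along(scheme$minus)]
  }
  df <- data.frame(site = totals$site, month = totals$month,
                   replicate = totals$replicate, counts, total = totals$total)
  names(df)[4:8] <- paste0("m", 1:5)
  benthic_dataset(df)
}

#' Simulate a complete synthetic dataset
#'
#' End-to-end generation: covariates, latent health, per-grab totals, and
#' metric counts, with the generating truth attached for recovery studies.
#'
#' @param scenario a [synthetic_scenario()].
#' @return a list with `counts` (a [benthic_dataset()]), `covariates` (a
#'   [covariate_table()]), `truth` (the [synthetic_truth()] with any derived
#'   `sigma_s` filled in), `H` (the generated latent health), and `scenario`.
#' @export
simulate_dataset <- function(scenario = synthetic_scenario()) {
  seed <- scenario$seed
  cov <- richibucto_like_covariates(scenario)
  truth <- scenario$truth
  if (is.null(truth$sigma_s)) truth$sigma_s <- attr(cov, "sigma_s")
  H <- simulate_latent(cov, truth, seed = seed + 1L)

  n <- scenario$n_sites
  reps <- if (identical(scenario$replicates, "alternate"))
    ifelse(seq_len(n) %% 2L == 1L, 3L, 2L) else as.integer(scenario$replicates)
  if (length(reps) != n) stop("replicates must give one count per site")
  totals <- data.frame(
    site = rep(seq_len(n), reps),
    month = rep(ifelse(seq_len(n) %in% scenario$oct_sites, "Oct", "Sep"), reps),
    replicate = unlist(lapply(reps, seq_len))
  )
  old <- .save_rng_state()
  set.seed(seed + 2L)
  totals$total <- sample(seq(scenario$totals_range[1], scenario$totals_range[2]),
                         nrow(totals), replace = TRUE)
  .restore_rng_state(old)

  counts <- simulate_counts(H, truth, metric_scheme(), totals, seed = seed + 3L)
  list(counts = counts, covariates = cov, truth = truth, H = H,
       scenario = scenario)
}
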