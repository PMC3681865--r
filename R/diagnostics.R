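## Convergence diagnostics, posterior summaries, DIC, and reporting tables.

# type-1 (inverse empirical CDF) central interval width: invariant to
# duplicating the sample, so identical chains give pooled width == within width
.interval_width <- function(x, prob) {
  qs <- quantile(x, c((1 - prob) / 2, (1 + prob) / 2), type = 1, names = FALSE)
  abs(qs[2] - qs[1])
}

#' Interval-based Brooks-Gelman-Rubin diagnostic
#'
#' Computes the interval variant of the BGR statistic on successive windows:
#' for each window end, using the second half of the draws up to that point,
#' the width of the central `prob` interval of the pooled chains is divided
#' by the mean width of the per-chain intervals.  Convergence is suggested by
#' the ratio approaching 1 while the pooled and within widths approach the
#' same constant.  Empirical (inverse-CDF) quantiles are used, so two
#' identical chains give a ratio of exactly 1.
#'
#' @param chains list of equal-length numeric vectors (one trace per chain),
#'   or a matrix with one column per chain.
#' @param bins number of windows.
#' @param prob central interval probability (default 0.8).
#' @return a data frame with columns `iteration`, `Rhat`, `pooled_width`,
#'   `within_width`; the final ratio is in attribute `"final"`.
#' @export
bgr_statistic <- function(chains, bins = 20L, prob = 0.8) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2L) stop("BGR needs at least two chains")
  n <- unique(vapply(chains, length, integer(1)))
  if (length(n) != 1L) stop("chains must have equal lengths")
  ends <- unique(pmax(4L, floor(n * seq_len(bins) / bins)))
  rows <- lapply(ends, function(t_end) {
    start <- floor(t_end / 2) + 1L
    seg <- lapply(chains, function(x) x[start:t_end])
    within <- mean(vapply(seg, .interval_width, numeric(1), prob = prob))
    pooled <- .interval_width(unlist(seg), prob)
    rhat <- if (pooled == 0 && within == 0) 1 else pooled / within
    data.frame(iteration = t_end, Rhat = rhat, pooled_width = pooled,
               within_width = within)
  })
  out <- do.call(rbind, rows)
  attr(out, "final") <- out$Rhat[nrow(out)]
  out
}

#' Scalar (ratio-of-variances) potential scale reduction factor
#'
#' The classical Gelman-Rubin statistic
#' `sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean within-chain variance
#' and `B` the between-chain variance of the chain means times `n`.
#'
#' @inheritParams bgr_statistic
#' @return the scalar PSRF.
#' @export
bgr_scalar <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)), function(j) chains[, j])
  if (length(chains) < 2L) stop("BGR needs at least two chains")
  n <- length(chains[[1]])
  W <- mean(vapply(chains, var, numeric(1)))
  B <- n * var(vapply(chains, mean, numeric(1)))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Largest final interval-BGR over all model parameters
#'
#' @param draws a `posterior_draws` object with at least two chains.
#' @param bins,prob passed to [bgr_statistic()].
#' @return the maximum final interval-BGR over all parameters (deviance
#'   columns excluded); parameters with no variability count as 1.
#' @export
max_bgr <- function(draws, bins = 10L, prob = 0.8) {
  keep <- seq(draws$burn_in + 1L, nrow(draws$chains[[1]]))
  pars <- setdiff(draws$param_names, c("deviance_obs", "deviance_sal"))
  rhats <- vapply(pars, function(p) {
    tr <- lapply(draws$chains, function(m) m[keep, p])
    if (all(vapply(tr, function(x) length(unique(x)) == 1L, logical(1)))) return(1)
    attr(bgr_statistic(tr, bins = bins, prob = prob), "final")
  }, numeric(1))
  max(rhats)
}

#' Posterior summary table
#'
#' Pooled post-burn-in posterior mean, median and equal-tailed credible
#' interval per parameter (type-7 sample quantiles).  The `credible` flag
#' marks parameters whose interval excludes 0 — the screening rule used for
#' slopes and correlations.
#'
#' @param draws a `posterior_draws` object.
#' @param level credible level in (0, 1) (default 0.95).
#' @return a data frame with columns `parameter`, `mean`, `median`, `lower`,
#'   `upper`, `credible`.
#' @export
posterior_summary <- function(draws, level = 0.95) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop("level must lie in (0, 1)")
  pooled <- .pooled_draws(draws)
  a <- (1 - level) / 2
  out <- data.frame(
    parameter = colnames(pooled),
    mean = colMeans(pooled),
    median = apply(pooled, 2, median),
    lower = apply(pooled, 2, quantile, probs = a, type = 7, names = FALSE),
    upper = apply(pooled, 2, quantile, probs = 1 - a, type = 7, names = FALSE),
    row.names = NULL
  )
  out$credible <- out$lower > 0 | out$upper < 0
  out
}

# DIC decomposition from a vector of deviances and the plug-in deviance
.dic_core <- function(dev_draws, dev_at_mean) {
  Dbar <- mean(dev_draws)
  pD <- Dbar - dev_at_mean
  list(DIC = Dbar + pD, Dbar = Dbar, pD = pD)
}

#' Deviance information criterion
#'
#' The deviance focuses on the observed metrics (and, for two-level models,
#' the salinity response): `D(theta) = -2 * (observation loglik + salinity
#' loglik)`, conditional on the latent quantities (plug-in at their posterior
#' means for `D(theta-bar)`).  `DIC = Dbar + pD` with `pD = Dbar -
#' D(theta-bar)`; the identity `DIC = 2*Dbar - D(theta-bar)` holds by
#' construction.
#'
#' @param draws a `posterior_draws` object (its stored per-iteration deviance
#'   is used for `Dbar`).
#' @param data,design,cov the data the model was fitted to.
#' @param scheme a [metric_scheme()].
#' @return `list(DIC, Dbar, pD, n_excluded)`; non-evaluable draws are
#'   excluded from `Dbar` with a warning count.
#' @export
dic <- function(draws, data, design, cov, scheme = metric_scheme()) {
  spec <- draws$spec
  pooled <- .pooled_draws(draws)
  dev <- pooled[, "deviance_obs"]
  if (spec$two_level) dev <- dev + pooled[, "deviance_sal"]
  bad <- !is.finite(dev)
  if (any(bad))
    warning(sum(bad), " draw(s) with non-evaluable deviance excluded")
  dev <- dev[!bad]
  mean_state <- .row_to_state(colMeans(pooled[!bad, , drop = FALSE]), spec, draws$S)
  d_hat <- -2 * observation_loglik(data, scheme, mean_state)
  if (spec$two_level)
    d_hat <- d_hat - 2 * salinity_loglik(cov, design, mean_state, spec)
  out <- .dic_core(dev, d_hat)
  out$n_excluded <- sum(bad)
  out
}

#' Per-site latent health (LHFI) score table
#'
#' Posterior mean, median and credible interval of each site's latent health,
#' with sites ranked by posterior mean (rank 1 = lowest health score) and a
#' count of other sites whose intervals overlap.  Health values are
#' interpretable only relatively, as in any analysis-of-covariance layout.
#'
#' @param draws a `posterior_draws` object.
#' @param site_labels optional site labels (default `1:S`).
#' @param level credible level.
#' @return a data frame sorted by site with columns `site`, `mean`, `median`,
#'   `lower`, `upper`, `rank`, `n_ci_overlap`; the mean pairwise overlap
#'   fraction is attached as attribute `"pairwise_overlap"`.
#' @export
health_table <- function(draws, site_labels = NULL, level = 0.95) {
  S <- draws$S
  if (is.null(site_labels)) site_labels <- seq_len(S)
  pooled <- .pooled_draws(draws)
  h <- pooled[, paste0("H[", seq_len(S), "]"), drop = FALSE]
  a <- (1 - level) / 2
  out <- data.frame(
    site = site_labels,
    mean = colMeans(h),
    median = apply(h, 2, median),
    lower = apply(h, 2, quantile, probs = a, type = 7, names = FALSE),
    upper = apply(h, 2, quantile, probs = 1 - a, type = 7, names = FALSE),
    row.names = NULL
  )
  out$rank <- rank(out$mean, ties.method = "first")
  overlap <- outer(seq_len(S), seq_len(S), function(i, j)
    out$lower[i] <= out$upper[j] & out$lower[j] <= out$upper[i])
  diag(overlap) <- NA
  out$n_ci_overlap <- rowSums(overlap, na.rm = TRUE)
  attr(out, "pairwise_overlap") <- if (S > 1)
    mean(overlap[!is.na(overlap)]) else NA_real_
  out
}

#' Posterior of the two-level error-variance ratio
#'
#' Computes `sigma_eps^2 / (sigma_eps^2 + beta_sal^2 sigma_s^2)` draw by draw
#' ([variance_ratio()]) and summarizes it.  A smaller ratio means the
#' implicit salinity covariate explains more of the latent regression error
#' variation.
#'
#' @param draws a `posterior_draws` object from a two-level model.
#' @param level credible level.
#' @return a list with `mean`, `median`, `lower`, `upper` and the per-draw
#'   `draws` vector.
#' @export
variance_ratio_posterior <- function(draws, level = 0.95) {
  spec <- draws$spec
  if (!spec$two_level)
    stop("variance_ratio_posterior needs draws from a two-level model")
  pooled <- .pooled_draws(draws)
  se_col <- if (spec$month_specific_variance) "sigma_eps[Sep]" else "sigma_eps"
  r <- variance_ratio(pooled[, se_col], pooled[, "beta[salinity]"],
                      pooled[, "sigma_s"])
  a <- (1 - level) / 2
  list(mean = mean(r), median = median(r),
       lower = quantile(r, a, type = 7, names = FALSE),
       upper = quantile(r, 1 - a, type = 7, names = FALSE),
       draws = r)
}
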