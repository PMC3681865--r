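## Observation model: generalized-logit links for the two overlapping
## multinomials (plus and minus metric groups, each with the unclassified
## remainder of the grab as baseline) and the Gaussian latent regressions.

#' Linear predictor of a metric
#'
#' For metric `m` in group `g` at site `i` the linear predictor is
#' `eta = delta_g + gamma_gm + sign_g * H_i`: the group fixed effect, the
#' metric random effect, and latent health entering with sign +1 for the plus
#' group and -1 for the minus group (the "inverted" generalized logit), so
#' that large minus-group counts reflect poor health.
#'
#' @param H_i latent health of the site.
#' @param delta_g group fixed effect (0 for the plus group).
#' @param gamma_gm metric effect.
#' @param sign_g +1 (plus group) or -1 (minus group).
#' @return the linear predictor value (vectorized over its arguments).
#' @export
linear_predictor <- function(H_i, delta_g, gamma_gm, sign_g) {
  delta_g + gamma_gm + sign_g * H_i
}

#' Generalized-logit (softmax with fixed baseline) probabilities
#'
#' Maps the linear predictors of the metrics in one group to category
#' probabilities, with the remainder (baseline) category's predictor fixed at
#' 0: `p_m = exp(eta_m) / (1 + sum(exp(eta)))` and
#' `p_0 = 1 / (1 + sum(exp(eta)))`.  Guarded against overflow by max
#' subtraction; finite input never yields NaN.
#'
#' @param etas numeric vector of linear predictors for the group's metrics.
#' @return numeric vector `c(etas probabilities, remainder)`; all in (0, 1),
#'   summing to 1.
#' @export
#' @examples
#' group_probabilities(c(0, 0))      # 1/3 each
#' group_probabilities(log(2))       # 2/3, 1/3
group_probabilities <- function(etas) {
  if (any(!is.finite(etas))) stop("non-finite linear predictor")
  m <- max(0, etas)
  e <- exp(etas - m)
  e0 <- exp(-m)
  denom <- e0 + sum(e)
  c(e / denom, remainder = e0 / denom)
}

# 5 x S matrix of linear predictors for every metric at every site
.eta_matrix <- function(state, scheme) {
  S <- length(state$H)
  eta <- matrix(NA_real_, nrow = length(scheme$metric_ids), ncol = S)
  for (m in scheme$plus)
    eta[m, ] <- linear_predictor(state$H, 0, state$gamma[m], 1)
  for (m in scheme$minus)
    eta[m, ] <- linear_predictor(state$H, state$delta_minus, state$gamma[m], -1)
  eta
}

# multinomial log-pmf for one group's counts across all records
.group_loglik <- function(counts, totals, eta_site, site) {
  # counts: records x k; eta_site: k x S
  k <- ncol(counts)
  rem <- totals - rowSums(counts)
  if (any(rem < 0)) stop("metric counts exceed total")
  ll <- 0
  for (r in seq_len(nrow(counts))) {
    p <- group_probabilities(eta_site[, site[r]])
    y <- c(counts[r, ], rem[r])
    ll <- ll + lgamma(totals[r] + 1) - sum(lgamma(y + 1)) + sum(y * log(p))
  }
  ll
}

#' Observation log-likelihood of the metric counts
#'
#' Sum over sites, replicates and both metric groups of the multinomial
#' log-pmf of the group's counts together with the remainder-of-grab count
#' (total minus the group's metric counts) at the generalized-logit
#' probabilities.  The two groups share the remainder, so their joint
#' distribution is deliberately over-counted; this overlap is accounted for
#' only crudely, through the group and metric effects.
#'
#' @param data a [benthic_dataset()].
#' @param scheme a [metric_scheme()].
#' @param state a [param_state()] whose `H` has one entry per site in `data`.
#' @return the log-likelihood (a scalar).
#' @export
observation_loglik <- function(data, scheme, state) {
  if (nrow(data) == 0L) return(0)
  counts <- as.matrix(data[paste0("m", 1:5)])
  eta <- .eta_matrix(state, scheme)
  .group_loglik(counts[, scheme$plus, drop = FALSE], data$total,
                eta[scheme$plus, , drop = FALSE], data$site) +
    .group_loglik(counts[, scheme$minus, drop = FALSE], data$total,
                  eta[scheme$minus, , drop = FALSE], data$site)
}

#' Log-density of the latent health regression
#'
#' `H_i ~ Normal(beta0 + x_i' beta, sigma_eps^2)`, with the error variance
#' optionally month-specific.
#'
#' @param state a [param_state()].
#' @param design a [build_centered_design()] result matching `state$beta`.
#' @param spec a [model_spec()].
#' @return the summed log-density of `H` given the regression.
#' @export
latent_health_loglik <- function(state, design, spec) {
  p <- ncol(design$X)
  if (length(state$beta) != p)
    stop("beta has length ", length(state$beta), " but the design has ", p, " columns")
  mu <- state$beta0 + if (p > 0) as.numeric(design$X %*% state$beta) else 0
  sig <- if (spec$month_specific_variance) {
    s <- state$sigma_eps
    if (length(s) != 2L) stop("month-specific variance needs sigma_eps of length 2")
    unname(s[as.integer(design$month)])
  } else state$sigma_eps[1L]
  sum(dnorm(state$H, mu, sig, log = TRUE))
}

#' Log-density of the salinity-on-DD regression level
#'
#' `s_i ~ Normal(b0 + b1 * d_i, sigma_s^2)` with centered salinity `s_i` and
#' centered distance downstream `d_i`.
#'
#' @param cov a [covariate_table()] (kept in the signature for symmetry with
#'   the other likelihood components; the centered values live in `design`).
#' @param design a [build_centered_design()] result.
#' @param state a [param_state()].
#' @param spec a [model_spec()]; must have `two_level = TRUE`.
#' @return the summed log-density of centered salinity given centered DD.
#' @export
salinity_loglik <- function(cov, design, state, spec) {
  if (!spec$two_level)
    stop("salinity_loglik applies only to two-level models")
  mu <- state$b0 + state$b1 * design$centered_dd
  sum(dnorm(design$centered_salinity, mu, state$sigma_s, log = TRUE))
}
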