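## Priors, the metric-effect covariance structures, and the joint log
## posterior assembling likelihoods and priors.

# log density of an inverse-Gamma(shape, scale) at variance v
.ld_invgamma <- function(v, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(v) - scale / v
}

# mean-zero multivariate normal log density via Cholesky
.ld_mvnorm0 <- function(x, Sigma) {
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) stop("covariance matrix is not positive definite")
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

# log multivariate gamma function
.lmvgamma <- function(p, a) {
  p * (p - 1) / 4 * log(pi) + sum(lgamma(a + (1 - seq_len(p)) / 2))
}

# inverse-Wishart(df, Psi) log density at Sigma
.ld_invwishart <- function(Sigma, df, Psi) {
  p <- nrow(Sigma)
  R <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(R)) stop("covariance matrix is not positive definite")
  ldet_S <- 2 * sum(log(diag(R)))
  ldet_P <- determinant(Psi, logarithm = TRUE)$modulus[1]
  tr <- sum(diag(solve(Sigma, Psi)))
  df / 2 * ldet_P - df * p / 2 * log(2) - .lmvgamma(p, df / 2) -
    (df + p + 1) / 2 * ldet_S - tr / 2
}

#' Log prior of the metric effects
#'
#' Under the iid structure the five metric effects are independent mean-zero
#' Gaussians with common s.d. `sigma_gamma`.  Under the block-diagonal
#' structure the plus-group pair and minus-group triple are separate
#' mean-zero multivariate normals with unstructured covariances `Sigma$pp`
#' and `Sigma$mm` and zero cross-covariance; the unstructured structure uses
#' the assembled 5x5 covariance including `Sigma$pm`.
#'
#' @param gamma numeric vector of 5 metric effects.
#' @param state a [param_state()] carrying `sigma_gamma` or `Sigma`.
#' @param spec a [model_spec()].
#' @return the log prior density; errors if a covariance block is not
#'   positive definite (an invalid proposal, not a crash).
#' @export
metric_effect_logprior <- function(gamma, state, spec) {
  switch(spec$metric_cov_structure,
    iid = sum(dnorm(gamma, 0, state$sigma_gamma, log = TRUE)),
    block_diagonal = .ld_mvnorm0(gamma[1:2], state$Sigma$pp) +
      .ld_mvnorm0(gamma[3:5], state$Sigma$mm),
    unstructured = .ld_mvnorm0(gamma, assemble_sigma(state$Sigma))
  )
}

#' Joint log prior of all model parameters
#'
#' Mean-zero Gaussian priors with variance `priors$normal_variance` for the
#' group effect, regression intercepts and coefficients (with the
#' salinity-regression pair `(b0, b1)` jointly bivariate normal with
#' correlation `rho ~ Uniform(-1, 1)` when `spec$b_bivariate`); inverse-Gamma
#' priors for every active variance; inverse-Wishart priors for active
#' covariance blocks; and the metric-effect prior of
#' [metric_effect_logprior()].  States outside the support (a nonpositive
#' scale, `|rho| >= 1`) return `-Inf`.
#'
#' @param state a [param_state()].
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @return the log prior density (possibly `-Inf`).
#' @export
log_prior <- function(state, spec, priors = prior_spec()) {
  if (!state_in_support(state, spec)) return(-Inf)
  nv <- priors$normal_variance
  a <- priors$ig_shape; b <- priors$ig_scale
  lp <- dnorm(state$delta_minus, 0, sqrt(nv), log = TRUE) +
    dnorm(state$beta0, 0, sqrt(nv), log = TRUE) +
    sum(dnorm(state$beta, 0, sqrt(nv), log = TRUE)) +
    sum(.ld_invgamma(state$sigma_eps^2, a, b))
  if (spec$metric_cov_structure == "iid") {
    lp <- lp + .ld_invgamma(state$sigma_gamma^2, a, b)
  } else {
    w <- priors$wishart_scale
    off <- priors$wishart_df_offset
    lp <- lp + if (spec$metric_cov_structure == "block_diagonal") {
      .ld_invwishart(state$Sigma$pp, 2 + off, w * diag(2)) +
        .ld_invwishart(state$Sigma$mm, 3 + off, w * diag(3))
    } else {
      .ld_invwishart(assemble_sigma(state$Sigma), 5 + off, w * diag(5))
    }
  }
  if (spec$two_level) {
    if (spec$b_bivariate) {
      Rho <- matrix(c(1, state$rho, state$rho, 1), 2, 2)
      lp <- lp + .ld_mvnorm0(c(state$b0, state$b1), nv * Rho) + log(0.5)
    } else {
      lp <- lp + dnorm(state$b0, 0, sqrt(nv), log = TRUE) +
        dnorm(state$b1, 0, sqrt(nv), log = TRUE)
    }
    lp <- lp + .ld_invgamma(state$sigma_s^2, a, b)
  }
  lp + metric_effect_logprior(state$gamma, state, spec)
}

#' Joint log posterior (up to a constant)
#'
#' The sum of the observation log-likelihood, the latent health regression
#' log-density, the salinity-on-DD log-density (two-level models), and the
#' joint log prior.
#'
#' @param state a [param_state()].
#' @param data a [benthic_dataset()].
#' @param design a [build_centered_design()] result.
#' @param cov a [covariate_table()].
#' @param spec a [model_spec()].
#' @param priors a [prior_spec()].
#' @param scheme a [metric_scheme()].
#' @return the log posterior density (possibly `-Inf`).
#' @export
log_posterior <- function(state, data, design, cov, spec,
                          priors = prior_spec(), scheme = metric_scheme()) {
  lp <- log_prior(state, spec, priors)
  if (!is.finite(lp)) return(lp)
  ll <- observation_loglik(data, scheme, state) +
    latent_health_loglik(state, design, spec)
  if (spec$two_level) ll <- ll + salinity_loglik(cov, design, state, spec)
  lp + ll
}

#' Collapse the two-level regression into a single level
#'
#' Substituting the salinity level `s = b0 + b1 d + e_s` into the health
#' regression `H = beta0 + beta_sal s + ... + e` yields a single-level
#' regression of health on distance downstream with intercept
#' `beta0 + beta_sal b0`, DD coefficient `beta_sal * b1`, and total error
#' variance `sigma_eps^2 + beta_sal^2 sigma_s^2`.
#'
#' @param beta0 health regression intercept.
#' @param beta_sal health regression coefficient of (centered) salinity.
#' @param b0,b1 salinity regression intercept and slope on centered DD.
#' @param sigma_eps,sigma_s error s.d. of the health and salinity regressions.
#' @return `list(intercept, dd_coefficient, total_error_variance)`.
#' @export
collapse_two_level <- function(beta0, beta_sal, b0, b1, sigma_eps, sigma_s) {
  list(
    intercept = beta0 + beta_sal * b0,
    dd_coefficient = beta_sal * b1,
    total_error_variance = sigma_eps^2 + beta_sal^2 * sigma_s^2
  )
}

#' Error-variance ratio of the collapsed two-level regression
#'
#' The share of the collapsed total error variance not attributable to the
#' implicit salinity covariate: `sigma_eps^2 / (sigma_eps^2 + beta_sal^2
#' sigma_s^2)`.  Smaller values mean the salinity-on-DD level explains more
#' of the latent regression error.
#'
#' @inheritParams collapse_two_level
#' @return a value in (0, 1].
#' @export
variance_ratio <- function(sigma_eps, beta_sal, sigma_s) {
  sigma_eps^2 / (sigma_eps^2 + beta_sal^2 * sigma_s^2)
}
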