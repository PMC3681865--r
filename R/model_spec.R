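## Model specification, prior hyperparameters, and the parameter state container.

#' Specify an LHFI model variant
#'
#' @param health_covariates ordered character vector of covariate/interaction
#'   names for the latent health regression (see [build_centered_design()]).
#' @param two_level if `TRUE`, salinity is itself regressed on distance
#'   downstream as an extra level; salinity must then be a health covariate
#'   and distance downstream must not be.
#' @param metric_cov_structure covariance structure for the metric effects:
#'   `"iid"` (a common variance), `"block_diagonal"` (separate unstructured
#'   covariances for the plus and minus groups, zero cross-covariance) or
#'   `"unstructured"` (a full 5x5 covariance).
#' @param b_bivariate if `TRUE` the salinity-regression intercept and slope
#'   get a joint bivariate normal prior with unknown correlation `rho`
#'   (uniform on (-1, 1)).
#' @param month_specific_variance if `TRUE` the latent regression error
#'   variance differs between the September and October sites.
#' @param name optional label for the model.
#' @return an object of class `model_spec`.
#' @seealso [lhfi_model()] for the named presets `"model1"`..`"model5"`.
#' @export
model_spec <- function(health_covariates,
                       two_level = FALSE,
                       metric_cov_structure = c("iid", "block_diagonal", "unstructured"),
                       b_bivariate = FALSE,
                       month_specific_variance = FALSE,
                       name = NULL) {
  metric_cov_structure <- match.arg(metric_cov_structure)
  health_covariates <- as.character(health_covariates)
  if (two_level) {
    if (!"salinity" %in% health_covariates)
      stop("two-level models need salinity among the health covariates")
    if ("dd" %in% health_covariates)
      stop("two-level models must not include dd in the health regression ",
           "(dd enters through the salinity level)")
  }
  if (b_bivariate && !two_level)
    stop("b_bivariate requires the two-level structure")
  structure(
    list(
      health_covariates = health_covariates,
      two_level = isTRUE(two_level),
      metric_cov_structure = metric_cov_structure,
      b_bivariate = isTRUE(b_bivariate),
      month_specific_variance = isTRUE(month_specific_variance),
      name = if (is.null(name)) "custom" else as.character(name)
    ),
    class = "model_spec"
  )
}

#' Load a model preset or model config file
#'
#' Presets `"model1"`..`"model5"` ship with the package as YAML config files
#' and correspond to the five fitted model variants: (1) distance downstream
#' only; (2) salinity only; (3) salinity-on-DD two-level; (4) salinity-on-DD
#' with bivariate (correlated) salinity-regression coefficients; (5)
#' log-depth, log silt-clay, their interaction, and salinity-on-DD.
#'
#' @param model preset name (`"model1"`..`"model5"`) or path to a YAML model
#'   config with keys matching the arguments of [model_spec()].
#' @return a `model_spec`.
#' @export
lhfi_model <- function(model) {
  if (inherits(model, "model_spec")) return(model)
  path <- if (file.exists(model)) model else
    system.file("models", paste0(model, ".yaml"), package = "lhfi")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown model preset or missing config file: ", model)
  cfg <- yaml::read_yaml(path)
  known <- c("health_covariates", "two_level", "metric_cov_structure",
             "b_bivariate", "month_specific_variance", "name")
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop("unknown key(s) in model config: ", paste(bad, collapse = ", "))
  do.call(model_spec, cfg)
}

#' Prior hyperparameters
#'
#' Fixed effects and regression coefficients get mean-zero Gaussian priors
#' with a common (large) variance; variances get inverse-Gamma priors with
#' unit shape and scale; unstructured metric-effect covariance blocks get
#' inverse-Wishart priors with identity scale and degrees of freedom equal to
#' the block dimension plus an offset; the optional correlation of the
#' salinity-regression coefficients gets a uniform prior on (-1, 1).
#'
#' @param normal_variance prior variance of Gaussian priors (default 100).
#' @param ig_shape,ig_scale inverse-Gamma shape and scale for variances
#'   (default 1 and 1).
#' @param wishart_df_offset added to the block dimension to give the
#'   inverse-Wishart degrees of freedom (default 1, the smallest integer
#'   offset giving a proper, diffuse prior).
#' @param wishart_scale multiplier of the identity scale matrix (default 1).
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(normal_variance = 100, ig_shape = 1, ig_scale = 1,
                       wishart_df_offset = 1, wishart_scale = 1) {
  stopifnot(normal_variance > 0, ig_shape > 0, ig_scale > 0,
            wishart_df_offset > 0, wishart_scale > 0)
  structure(
    list(normal_variance = normal_variance, ig_shape = ig_shape,
         ig_scale = ig_scale, wishart_df_offset = wishart_df_offset,
         wishart_scale = wishart_scale, rho_prior = "uniform(-1,1)"),
    class = "prior_spec"
  )
}

#' Parameter state of an LHFI model
#'
#' Bundles one value of every unknown: latent health per site `H`; the minus
#' group fixed effect `delta_minus` (the plus group effect is fixed at 0 for
#' identifiability); metric effects `gamma` (5 values); health regression
#' intercept `beta0` and coefficients `beta` (named by covariate); the
#' salinity-regression intercept `b0`, slope `b1` and error s.d. `sigma_s`
#' (two-level models); latent regression error s.d. `sigma_eps` (length 2,
#' named `Sep`/`Oct`, when the variance is month-specific); metric-effect
#' s.d. `sigma_gamma` (iid structure) or covariance blocks `Sigma`
#' (`list(pp, mm, pm)`); and the coefficient-prior correlation `rho`.
#'
#' @param H numeric vector of latent health values, one per site.
#' @param delta_minus minus-group fixed effect.
#' @param gamma numeric vector of 5 metric effects.
#' @param beta0 health regression intercept.
#' @param beta named numeric vector of health regression coefficients.
#' @param sigma_eps latent regression error s.d. (scalar, or length 2 named
#'   `Sep`,`Oct`).
#' @param sigma_gamma metric-effect s.d. (iid structure).
#' @param b0,b1,sigma_s salinity-on-DD regression parameters (two-level).
#' @param Sigma `NULL`, or `list(pp = 2x2, mm = 3x3, pm = 2x3)` covariance
#'   blocks (`pm` used only for the unstructured structure).
#' @param rho correlation of the (b0, b1) prior, in (-1, 1).
#' @return an object of class `param_state`.
#' @export
param_state <- function(H, delta_minus = 0, gamma = numeric(5), beta0 = 0,
                        beta = numeric(0), sigma_eps = 1, sigma_gamma = 1,
                        b0 = 0, b1 = 0, sigma_s = 1, Sigma = NULL, rho = 0) {
  structure(
    list(H = as.numeric(H), delta_minus = delta_minus,
         gamma = as.numeric(gamma), beta0 = beta0, beta = beta,
         sigma_eps = sigma_eps, sigma_gamma = sigma_gamma,
         b0 = b0, b1 = b1, sigma_s = sigma_s, Sigma = Sigma, rho = rho),
    class = "param_state"
  )
}

.is_spd <- function(A, tol = 1e-10) {
  if (any(abs(A - t(A)) > tol)) return(FALSE)
  ev <- tryCatch(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  all(is.finite(ev)) && min(ev) > 0
}

#' Check whether a parameter state lies in the support of the model
#'
#' @param state a [param_state()].
#' @param spec a [model_spec()].
#' @return `TRUE` if all scale parameters are positive, covariance blocks are
#'   symmetric positive definite (and their 5x5 assembly is, for the
#'   unstructured case), and `rho` lies in (-1, 1); otherwise `FALSE`.
#' @export
state_in_support <- function(state, spec) {
  if (any(!is.finite(unlist(state[c("H", "delta_minus", "gamma", "beta0", "beta")]))))
    return(FALSE)
  if (any(state$sigma_eps <= 0)) return(FALSE)
  if (spec$metric_cov_structure == "iid") {
    if (state$sigma_gamma <= 0) return(FALSE)
  } else {
    if (is.null(state$Sigma)) return(FALSE)
    if (!.is_spd(state$Sigma$pp) || !.is_spd(state$Sigma$mm)) return(FALSE)
    if (spec$metric_cov_structure == "unstructured" &&
        !.is_spd(assemble_sigma(state$Sigma))) return(FALSE)
  }
  if (spec$two_level && state$sigma_s <= 0) return(FALSE)
  if (spec$b_bivariate && abs(state$rho) >= 1) return(FALSE)
  TRUE
}

#' Assemble the full 5x5 metric-effect covariance from its blocks
#'
#' @param Sigma `list(pp = 2x2, mm = 3x3, pm = 2x3)`; a missing/NULL `pm`
#'   gives the block-diagonal assembly.
#' @return a 5x5 symmetric matrix ordered as metrics 1..5.
#' @export
assemble_sigma <- function(Sigma) {
  pm <- if (is.null(Sigma$pm)) matrix(0, 2, 3) else Sigma$pm
  rbind(cbind(Sigma$pp, pm), cbind(t(pm), Sigma$mm))
}
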