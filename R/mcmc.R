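## Multi-chain MCMC driver around the compiled Metropolis-within-Gibbs kernel.

#' MCMC configuration
#'
#' @param n_chains number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param n_iter total iterations per chain.
#' @param burn_in iterations to discard, or `"auto"` to discard the first
#'   half and verify convergence by the Brooks-Gelman-Rubin statistic.
#' @param thin thinning interval for *stored trace exports* (summaries always
#'   use every post-burn-in draw).
#' @param seed integer seed; fully determines the sampler output.
#' @return an object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 50000L, burn_in = "auto",
                        thin = 100L, seed = 1L) {
  n_chains <- as.integer(n_chains)
  n_iter <- as.integer(n_iter)
  thin <- as.integer(thin)
  if (n_chains < 1L) stop("n_chains must be >= 1")
  if (thin < 1L) stop("thin must be >= 1")
  if (!identical(burn_in, "auto")) {
    burn_in <- as.integer(burn_in)
    if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  }
  structure(list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed)),
            class = "mcmc_config")
}

#' Dispersed-but-valid initial state
#'
#' Coefficients and effects are jittered around 0, variances start at 1,
#' latent health at standard normal draws, covariance blocks at the identity.
#' Distinct seeds give distinct (overdispersed) starting points; the initial
#' state always has a finite log posterior on valid data.
#'
#' @param spec a [model_spec()].
#' @param data a [benthic_dataset()] (unused beyond its site count fallback).
#' @param design a [build_centered_design()] result.
#' @param seed integer seed.
#' @return a [param_state()].
#' @export
initialize_state <- function(spec, data, design, seed) {
  S <- length(design$centered_dd)
  p <- ncol(design$X)
  old <- .save_rng_state()
  on.exit(.restore_rng_state(old), add = TRUE)
  set.seed(seed)
  st <- param_state(
    H = rnorm(S),
    delta_minus = rnorm(1),
    gamma = rnorm(5) * 0.5,
    beta0 = rnorm(1),
    beta = setNames(rnorm(p), colnames(design$X)),
    sigma_eps = if (spec$month_specific_variance) c(Sep = 1, Oct = 1) else 1,
    sigma_gamma = 1,
    b0 = if (spec$two_level) rnorm(1) else 0,
    b1 = if (spec$two_level) rnorm(1) else 0,
    sigma_s = 1,
    Sigma = if (spec$metric_cov_structure != "iid")
      list(pp = diag(2), mm = diag(3), pm = matrix(0, 2, 3)) else NULL,
    rho = 0
  )
  st
}

.save_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng_state <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Hierarchical centering reparameterization
#'
#' Re-expresses the latent health values as deviations from their regression
#' means, `H_i - (beta0 + x_i' beta)`, the reparameterization under which
#' random effects mix well in Gibbs-type samplers.  The transform is a
#' location shift, so it is bijective, Jacobian-free, and the inverse
#' ([hierarchical_uncenter()]) recovers the original state exactly.
#'
#' @param state a [param_state()].
#' @param design a [build_centered_design()] result.
#' @param spec a [model_spec()].
#' @return the reparameterized state, with attribute `"centered" = TRUE`.
#' @export
hierarchical_center <- function(state, design, spec) {
  p <- ncol(design$X)
  mu <- state$beta0 + if (p > 0) as.numeric(design$X %*% state$beta) else 0
  state$H <- state$H - mu
  attr(state, "centered") <- TRUE
  state
}

#' @rdname hierarchical_center
#' @export
hierarchical_uncenter <- function(state, design, spec) {
  p <- ncol(design$X)
  mu <- state$beta0 + if (p > 0) as.numeric(design$X %*% state$beta) else 0
  state$H <- state$H + mu
  attr(state, "centered") <- NULL
  state
}

# stable flattened parameter names, matching the compiled sampler's column order
.param_names <- function(spec, S, covariates) {
  nm <- c(paste0("H[", seq_len(S), "]"), "delta_minus",
          paste0("gamma[", 1:5, "]"), "beta0")
  if (length(covariates) > 0) nm <- c(nm, paste0("beta[", covariates, "]"))
  nm <- c(nm, if (spec$month_specific_variance)
    c("sigma_eps[Sep]", "sigma_eps[Oct]") else "sigma_eps")
  nm <- c(nm, switch(spec$metric_cov_structure,
    iid = "sigma_gamma",
    block_diagonal = c("Sigma_pp[1,1]", "Sigma_pp[1,2]", "Sigma_pp[2,2]",
                       "Sigma_mm[1,1]", "Sigma_mm[1,2]", "Sigma_mm[1,3]",
                       "Sigma_mm[2,2]", "Sigma_mm[2,3]", "Sigma_mm[3,3]"),
    unstructured = {
      idx <- which(upper.tri(matrix(0, 5, 5), diag = TRUE), arr.ind = TRUE)
      idx <- idx[order(idx[, 1], idx[, 2]), ]
      paste0("Sigma[", idx[, 1], ",", idx[, 2], "]")
    }))
  if (spec$two_level) {
    nm <- c(nm, "b0", "b1", "sigma_s")
    if (spec$b_bivariate) nm <- c(nm, "rho")
  }
  nm <- c(nm, "deviance_obs")
  if (spec$two_level) nm <- c(nm, "deviance_sal")
  nm
}

.structure_code <- function(spec) {
  match(spec$metric_cov_structure, c("iid", "block_diagonal", "unstructured")) - 1L
}

.state_to_init <- function(state, spec) {
  Sigma <- if (!is.null(state$Sigma)) assemble_sigma(state$Sigma) else
    diag(5) * state$sigma_gamma^2
  list(H = state$H, delta_minus = state$delta_minus, gamma = state$gamma,
       beta0 = state$beta0, beta = as.numeric(state$beta),
       sigma_eps = as.numeric(state$sigma_eps),
       sigma_gamma = state$sigma_gamma, Sigma = Sigma,
       b0 = state$b0, b1 = state$b1, sigma_s = state$sigma_s, rho = state$rho)
}

#' Run multiple MCMC chains for an LHFI model
#'
#' Samples the joint posterior of the LHFI model by a purpose-built
#' Metropolis-within-Gibbs kernel: adaptive random-walk Metropolis for latent
#' health and the group/metric effects (whose conditionals involve the
#' multinomial observation model) and conjugate Gibbs draws for the Gaussian
#' regression layers, variances and covariance blocks.  Chains are
#' independent given distinct sub-seeds derived from `config$seed`; a fixed
#' seed gives bit-reproducible output.
#'
#' @param data a [benthic_dataset()] (may have zero rows, in which case the
#'   sampler targets the prior joined with the latent regressions).
#' @param design a [build_centered_design()] built with the model's
#'   covariates.
#' @param cov the [covariate_table()] the design came from.
#' @param spec a [model_spec()] or preset name for [lhfi_model()].
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @param scheme a [metric_scheme()].
#' @param fixed optional named list clamping blocks of parameters at their
#'   initial values instead of sampling them.  Recognized names: `H`,
#'   `delta_minus`, `gamma`, `beta`, `sigma_eps`, `gamma_var`, `b`.  A
#'   numeric entry supplies the clamped value; `TRUE` clamps at the
#'   default initialization.
#' @param init optional [param_state()] used (after overriding by `fixed`)
#'   as the starting state of every chain; by default each chain gets its own
#'   dispersed [initialize_state()].
#' @return an object of class `posterior_draws`: a list with `chains` (one
#'   iterations x parameters matrix per chain), `param_names`, `burn_in`,
#'   `spec`, `priors`, `config`, `S`, and `meta` (centering constants,
#'   convergence flag, divergence flags, package version).
#' @export
run_chains <- function(data, design, cov, spec, priors = prior_spec(),
                       config = mcmc_config(), scheme = metric_scheme(),
                       fixed = list(), init = NULL) {
  spec <- lhfi_model(spec)
  S <- length(design$centered_dd)
  counts <- if (nrow(data) > 0L) as.matrix(data[paste0("m", 1:5)]) else
    matrix(0, 0, 5)
  if (nrow(data) > 0L && max(data$site) > S)
    stop("counts reference a site missing from the covariate table")

  data_in <- list(
    y = counts,
    total = if (nrow(data) > 0L) as.numeric(data$total) else numeric(0),
    site = if (nrow(data) > 0L) as.integer(data$site) - 1L else integer(0),
    X = design$X,
    month = as.integer(design$month) - 1L,
    s_c = design$centered_salinity,
    d_c = design$centered_dd
  )
  spec_in <- list(two_level = spec$two_level, b_bivariate = spec$b_bivariate,
                  month_specific_variance = spec$month_specific_variance,
                  structure = .structure_code(spec))
  upd <- list(H = TRUE, delta = TRUE, gamma = TRUE, beta = TRUE,
              sigma_eps = TRUE, gamma_var = TRUE, b = TRUE)
  clamp_map <- c(H = "H", delta_minus = "delta", gamma = "gamma",
                 beta = "beta", sigma_eps = "sigma_eps",
                 gamma_var = "gamma_var", b = "b")
  for (nm in names(fixed)) {
    if (!nm %in% names(clamp_map)) stop("unknown fixed-parameter block: ", nm)
    upd[[clamp_map[[nm]]]] <- FALSE
  }

  burn_in <- if (identical(config$burn_in, "auto"))
    config$n_iter %/% 2L else config$burn_in
  pnames <- .param_names(spec, S, spec$health_covariates)

  chains <- vector("list", config$n_chains)
  divergent <- logical(config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    chain_seed <- config$seed + 7901L * (ch - 1L)
    st <- if (is.null(init))
      initialize_state(spec, data, design, chain_seed) else init
    # apply clamped values
    for (nm in names(fixed)) {
      v <- fixed[[nm]]
      if (!isTRUE(v)) {
        if (nm == "b") {
          st$b0 <- v[["b0"]]; st$b1 <- v[["b1"]]
          if ("sigma_s" %in% names(v)) st$sigma_s <- v[["sigma_s"]]
        } else if (nm == "beta" && is.list(v)) {
          st$beta0 <- v$beta0; st$beta <- v$beta
        } else if (nm == "gamma_var") {
          st$sigma_gamma <- v
        } else st[[nm]] <- v
      }
    }
    ctrl <- list(n_iter = config$n_iter, adapt_until = burn_in, update = upd)
    old <- .save_rng_state()
    set.seed(chain_seed)
    res <- .sampler_cpp(data_in, spec_in, priors, .state_to_init(st, spec), ctrl)
    .restore_rng_state(old)
    draws <- res$draws
    colnames(draws) <- pnames
    chains[[ch]] <- draws
    divergent[ch] <- res$divergent
  }

  out <- structure(
    list(chains = chains, param_names = pnames, burn_in = burn_in,
         spec = spec, priors = priors, config = config, S = S,
         meta = list(
           centering_constants = design$centering_constants,
           transform_flags = design$transform_flags,
           covariates = design$covariates,
           divergent = divergent,
           package_version = as.character(packageVersion("lhfi")))),
    class = "posterior_draws")
  if (config$n_chains >= 2L) {
    rhat <- max_bgr(out)
    out$meta$max_bgr <- rhat
    out$meta$converged <- is.finite(rhat) && rhat < 1.1
  }
  out
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]), "iterations,", length(x$param_names),
      "parameters\n")
  cat("  model:", x$spec$name, " burn-in:", x$burn_in, "\n")
  if (!is.null(x$meta$max_bgr))
    cat("  max interval-BGR:", round(x$meta$max_bgr, 4), "\n")
  invisible(x)
}

# pooled post-burn-in draws as one matrix
.pooled_draws <- function(draws) {
  keep <- seq(draws$burn_in + 1L, nrow(draws$chains[[1]]))
  do.call(rbind, lapply(draws$chains, function(m) m[keep, , drop = FALSE]))
}

# reconstruct a param_state from one named draw vector
.row_to_state <- function(v, spec, S) {
  gsel <- function(prefix, n) as.numeric(v[paste0(prefix, "[", seq_len(n), "]")])
  covs <- spec$health_covariates
  Sigma <- NULL
  sigma_gamma <- 1
  if (spec$metric_cov_structure == "iid") {
    sigma_gamma <- as.numeric(v["sigma_gamma"])
  } else if (spec$metric_cov_structure == "block_diagonal") {
    pp <- matrix(0, 2, 2)
    pp[upper.tri(pp, diag = TRUE)] <- v[c("Sigma_pp[1,1]", "Sigma_pp[1,2]", "Sigma_pp[2,2]")]
    pp[lower.tri(pp)] <- t(pp)[lower.tri(pp)]
    mm <- matrix(0, 3, 3)
    mm[1, ] <- v[c("Sigma_mm[1,1]", "Sigma_mm[1,2]", "Sigma_mm[1,3]")]
    mm[2, 2:3] <- v[c("Sigma_mm[2,2]", "Sigma_mm[2,3]")]
    mm[3, 3] <- v["Sigma_mm[3,3]"]
    mm[lower.tri(mm)] <- t(mm)[lower.tri(mm)]
    Sigma <- list(pp = pp, mm = mm, pm = matrix(0, 2, 3))
  } else {
    full <- matrix(0, 5, 5)
    idx <- which(upper.tri(full, diag = TRUE), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), ]
    full[idx] <- v[paste0("Sigma[", idx[, 1], ",", idx[, 2], "]")]
    full[lower.tri(full)] <- t(full)[lower.tri(full)]
    Sigma <- list(pp = full[1:2, 1:2], mm = full[3:5, 3:5], pm = full[1:2, 3:5])
  }
  sigma_eps <- if (spec$month_specific_variance)
    c(Sep = as.numeric(v["sigma_eps[Sep]"]), Oct = as.numeric(v["sigma_eps[Oct]"]))
  else as.numeric(v["sigma_eps"])
  param_state(
    H = gsel("H", S),
    delta_minus = as.numeric(v["delta_minus"]),
    gamma = gsel("gamma", 5),
    beta0 = as.numeric(v["beta0"]),
    beta = if (length(covs) > 0)
      setNames(as.numeric(v[paste0("beta[", covs, "]")]), covs) else numeric(0),
    sigma_eps = sigma_eps, sigma_gamma = sigma_gamma,
    b0 = if (spec$two_level) as.numeric(v["b0"]) else 0,
    b1 = if (spec$two_level) as.numeric(v["b1"]) else 0,
    sigma_s = if (spec$two_level) as.numeric(v["sigma_s"]) else 1,
    Sigma = Sigma,
    rho = if (spec$b_bivariate) as.numeric(v["rho"]) else 0)
}

#' Persist posterior draws as text files
#'
#' Writes one thinned CSV per chain (`iteration` column plus named
#' parameters) and a YAML metadata file (model spec, priors, config,
#' centering constants, burn-in).  [load_draws()] restores the object (with
#' thinned chains).
#'
#' @param draws a `posterior_draws` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_draws <- function(draws, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  thin <- draws$config$thin
  for (ch in seq_along(draws$chains)) {
    m <- draws$chains[[ch]]
    idx <- seq(thin, nrow(m), by = thin)
    df <- data.frame(iteration = idx, m[idx, , drop = FALSE], check.names = FALSE)
    write.csv(df, file.path(dir, sprintf("draws_chain%d.csv", ch)),
              row.names = FALSE)
  }
  meta <- list(
    spec = unclass(draws$spec), priors = unclass(draws$priors),
    config = unclass(draws$config), S = draws$S, burn_in = draws$burn_in,
    param_names = draws$param_names,
    meta = lapply(draws$meta, function(x)
      if (is.numeric(x) && !is.null(names(x))) as.list(x) else x))
  yaml::write_yaml(meta, file.path(dir, "draws_meta.yaml"))
  invisible(dir)
}

#' @rdname save_draws
#' @param dir directory written by [save_draws()].
#' @return a `posterior_draws` object whose chains hold the thinned stored
#'   iterations.
#' @export
load_draws <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "draws_meta.yaml"))
  files <- sort(list.files(dir, pattern = "^draws_chain[0-9]+\\.csv$",
                           full.names = TRUE))
  chains <- lapply(files, function(f) {
    df <- read.csv(f, check.names = FALSE)
    as.matrix(df[, -1, drop = FALSE])
  })
  spec <- do.call(model_spec, meta$spec[c("health_covariates", "two_level",
    "metric_cov_structure", "b_bivariate", "month_specific_variance", "name")])
  cfg <- do.call(mcmc_config, meta$config)
  thin <- cfg$thin
  structure(
    list(chains = chains, param_names = meta$param_names,
         burn_in = meta$burn_in %/% thin, spec = spec,
         priors = do.call(prior_spec, meta$priors[c("normal_variance",
           "ig_shape", "ig_scale", "wishart_df_offset", "wishart_scale")]),
         config = cfg, S = meta$S, meta = meta$meta),
    class = "posterior_draws")
}
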