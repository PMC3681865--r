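## Pipeline commands tying the modules together with config files, manifests
## and reproducible on-disk outputs.  These functions are the programmatic
## interface; inst/cli/lhfi.R is a thin command-line wrapper over them.

.md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(x, f)
  unname(tools::md5sum(f))
}

.write_manifest <- function(out_dir, command, config, inputs, seed, outputs,
                            extra = list()) {
  manifest <- c(list(
    command = command,
    config_hash = .md5_of_object(config),
    input_digests = as.list(if (length(inputs) > 0)
      setNames(unname(tools::md5sum(inputs)), basename(inputs)) else character(0)),
    seed = seed,
    package_version = as.character(packageVersion("lhfi")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs)), extra)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

#' Read a scenario config file
#'
#' @param config a [synthetic_scenario()], or the path of a YAML file whose
#'   keys match the arguments of [synthetic_scenario()] (with `truth` a
#'   nested map matching [synthetic_truth()]; `truth$beta` a named map).
#' @return a `synthetic_scenario`.
#' @export
read_scenario <- function(config) {
  if (inherits(config, "synthetic_scenario")) return(config)
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("scenario config must be a YAML mapping: ", config)
  known <- names(formals(synthetic_scenario))
  bad <- setdiff(names(cfg), known)
  if (length(bad) > 0L)
    stop("unknown key(s) in scenario config: ", paste(bad, collapse = ", "))
  if (!is.null(cfg$truth)) {
    tknown <- names(formals(synthetic_truth))
    tbad <- setdiff(names(cfg$truth), tknown)
    if (length(tbad) > 0L)
      stop("unknown key(s) in scenario config: truth.",
           paste(tbad, collapse = ", truth."))
    if (!is.null(cfg$truth$beta)) cfg$truth$beta <- unlist(cfg$truth$beta)
    if (!is.null(cfg$truth$gamma)) cfg$truth$gamma <- unlist(cfg$truth$gamma)
    cfg$truth <- do.call(synthetic_truth, cfg$truth)
  }
  do.call(synthetic_scenario, cfg)
}

#' Read an MCMC config file
#'
#' @param config an [mcmc_config()] or path of a YAML file with keys
#'   matching its arguments.
#' @return an `mcmc_config`.
#' @export
read_mcmc_config <- function(config) {
  if (inherits(config, "mcmc_config")) return(config)
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("mcmc config must be a YAML mapping: ", config)
  bad <- setdiff(names(cfg), names(formals(mcmc_config)))
  if (length(bad) > 0L)
    stop("unknown key(s) in mcmc config: ", paste(bad, collapse = ", "))
  do.call(mcmc_config, cfg)
}

#' Simulate a dataset to disk
#'
#' Writes `counts.csv`, `covariates.csv`, a `truth.yaml` with the generating
#' parameters, and a run manifest.  Reruns with the same config produce
#' byte-identical data files.
#'
#' @param scenario_config a [synthetic_scenario()] or YAML path
#'   ([read_scenario()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the [simulate_dataset()] result.
#' @export
cmd_simulate <- function(scenario_config, out_dir) {
  scenario <- read_scenario(scenario_config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  sim <- simulate_dataset(scenario)
  counts_f <- file.path(out_dir, "counts.csv")
  cov_f <- file.path(out_dir, "covariates.csv")
  truth_f <- file.path(out_dir, "truth.yaml")
  write_counts_csv(sim$counts, counts_f)
  write_covariates_csv(sim$covariates, cov_f)
  tr <- sim$truth
  yaml::write_yaml(list(beta = as.list(tr$beta), beta0 = tr$beta0,
                        delta_minus = tr$delta_minus, gamma = tr$gamma,
                        b0 = tr$b0, b1 = tr$b1, sigma_eps = tr$sigma_eps,
                        sigma_s = tr$sigma_s, sigma_gamma = tr$sigma_gamma,
                        H = sim$H), truth_f)
  .write_manifest(out_dir, "simulate", unclass(scenario),
                  inputs = character(0), seed = scenario$seed,
                  outputs = basename(c(counts_f, cov_f, truth_f)))
  invisible(sim)
}

#' Fit an LHFI model to counts and covariate files
#'
#' Reads the two CSVs, builds the centered design for the chosen model,
#' runs the MCMC, and writes: `summary.csv` (posterior mean, median, 2.5%
#' and 97.5% quantiles and the credible flag per parameter), `health.csv`
#' (per-site LHFI scores with intervals and ranks), `bgr.csv` (interval-BGR
#' series per parameter), `dic.csv`, thinned per-chain draws, and a
#' manifest.  If the largest BGR is 1.1 or more a warning is raised and the
#' manifest records `converged: no`; outputs are still written.
#'
#' @param counts_csv,covariates_csv input file paths.
#' @param model preset name, model YAML path, or [model_spec()].
#' @param mcmc an [mcmc_config()] or YAML path.
#' @param out_dir output directory.
#' @return invisibly, a list with `draws`, `summary`, `health`, `dic`,
#'   `converged`.
#' @export
cmd_fit <- function(counts_csv, covariates_csv, model,
                    mcmc = mcmc_config(), out_dir) {
  spec <- lhfi_model(model)
  config <- read_mcmc_config(mcmc)
  data <- read_counts_csv(counts_csv)
  cov <- read_covariates_csv(covariates_csv)
  if (max(data$site) != nrow(cov))
    stop("counts and covariates disagree on the number of sites")
  design <- build_centered_design(cov, spec$health_covariates)
  draws <- run_chains(data, design, cov, spec, config = config)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- posterior_summary(draws)
  health <- health_table(draws)
  d <- dic(draws, data, design, cov)
  write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  write.csv(health, file.path(out_dir, "health.csv"), row.names = FALSE)
  write.csv(data.frame(model = spec$name, DIC = d$DIC, Dbar = d$Dbar, pD = d$pD),
            file.path(out_dir, "dic.csv"), row.names = FALSE)

  keep <- setdiff(draws$param_names, c("deviance_obs", "deviance_sal"))
  post <- seq(draws$burn_in + 1L, config$n_iter)
  bgr <- do.call(rbind, lapply(keep, function(p) {
    tr <- lapply(draws$chains, function(m) m[post, p])
    if (all(vapply(tr, function(x) length(unique(x)) == 1L, logical(1))))
      return(NULL)
    s <- bgr_statistic(tr, bins = 10L)
    cbind(parameter = p, s)
  }))
  write.csv(bgr, file.path(out_dir, "bgr.csv"), row.names = FALSE)
  save_draws(draws, out_dir)

  converged <- is.null(draws$meta$max_bgr) || draws$meta$converged
  if (!converged)
    warning("chains did not converge: max BGR = ",
            round(draws$meta$max_bgr, 3))
  .write_manifest(out_dir, "fit",
                  list(model = unclass(spec), mcmc = unclass(config)),
                  inputs = c(counts_csv, covariates_csv), seed = config$seed,
                  outputs = c("summary.csv", "health.csv", "dic.csv", "bgr.csv"),
                  extra = list(converged = if (converged) "yes" else "no",
                               max_bgr = draws$meta$max_bgr))
  invisible(list(draws = draws, summary = summ, health = health, dic = d,
                 converged = converged))
}

#' Compare fitted models by DIC
#'
#' @param fit_dirs two or more directories written by [cmd_fit()] for the
#'   same dataset (checked by the manifests' input digests).
#' @return a data frame with one row per fit (`model`, `DIC`, `Dbar`, `pD`),
#'   sorted ascending by DIC.
#' @export
cmd_compare <- function(fit_dirs) {
  if (length(fit_dirs) < 2L) stop("need at least two fit directories")
  rows <- lapply(fit_dirs, function(d) {
    manifest <- yaml::read_yaml(file.path(d, "manifest.yaml"))
    dic_row <- read.csv(file.path(d, "dic.csv"))
    list(digests = manifest$input_digests, dic = dic_row, dir = d)
  })
  ref <- rows[[1]]$digests
  for (r in rows[-1])
    if (!identical(r$digests, ref))
      stop("fits were run on different datasets (input digests differ): ",
           r$dir)
  out <- do.call(rbind, lapply(rows, function(r) r$dic))
  out$dir <- vapply(rows, function(r) r$dir, character(1))
  out[order(out$DIC), , drop = FALSE]
}

#' Simulation-based parameter recovery study
#'
#' Runs `n_runs` seeded simulate-then-fit cycles and reports, per generating
#' parameter, the fraction of runs whose 95% credible interval covered the
#' truth.  Parameters absent from the fitted model are reported as `NA`.
#' For two-level models the posterior mean of the error-variance ratio is
#' also reported per run (column attached as attribute `"ratio_means"`).
#'
#' @param scenario_config a [synthetic_scenario()] or YAML path.
#' @param model_preset preset name or [model_spec()].
#' @param n_runs number of simulate-fit cycles (>= 1).
#' @param seed master seed; run `k` uses scenario seed `seed + 101*k` and a
#'   matching sampler seed.
#' @param mcmc an [mcmc_config()] for the per-run fits.
#' @param out_csv optional path for the coverage table.
#' @return a data frame with columns `parameter`, `truth`, `coverage`,
#'   `n_runs`.
#' @export
cmd_recover <- function(scenario_config, model_preset, n_runs = 40L,
                        seed = 7L, mcmc = mcmc_config(n_iter = 4000L,
                                                      burn_in = 1500L,
                                                      thin = 10L),
                        out_csv = NULL) {
  if (n_runs < 1L) stop("n_runs must be >= 1")
  scenario <- read_scenario(scenario_config)
  spec <- lhfi_model(model_preset)
  base_cfg <- read_mcmc_config(mcmc)

  watched <- c("delta_minus", "beta0", "sigma_eps", "sigma_gamma",
               paste0("beta[", spec$health_covariates, "]"),
               if (spec$two_level) c("b1", "sigma_s"))
  hits <- matrix(NA, n_runs, length(watched),
                 dimnames = list(NULL, watched))
  ratio_means <- rep(NA_real_, n_runs)

  for (k in seq_len(n_runs)) {
    sc <- scenario
    sc$seed <- scenario$seed + 101L * k
    sim <- simulate_dataset(sc)
    design <- build_centered_design(sim$covariates, spec$health_covariates)
    cfg <- base_cfg
    cfg$seed <- as.integer(seed + 977L * k)
    draws <- run_chains(sim$counts, design, sim$covariates, spec, config = cfg)
    summ <- posterior_summary(draws)
    tr <- sim$truth
    truth_of <- function(p) {
      if (p == "delta_minus") return(tr$delta_minus)
      if (p == "beta0") return(tr$beta0)
      if (p == "sigma_eps") return(tr$sigma_eps)
      if (p == "sigma_gamma") return(tr$sigma_gamma)
      if (p == "b1") return(tr$b1)
      if (p == "sigma_s") return(tr$sigma_s)
      nm <- sub("^beta\\[(.*)\\]$", "\\1", p)
      if (nm %in% names(tr$beta)) return(unname(tr$beta[nm]))
      NA_real_
    }
    for (p in watched) {
      row <- summ[summ$parameter == p, ]
      tv <- truth_of(p)
      if (nrow(row) == 1L && is.finite(tv))
        hits[k, p] <- row$lower <= tv && tv <= row$upper
    }
    if (spec$two_level)
      ratio_means[k] <- variance_ratio_posterior(draws)$mean
  }

  truths <- vapply(watched, function(p) {
    tr <- scenario$truth
    if (p == "sigma_s" && is.null(tr$sigma_s)) {
      dd <- if (scenario$n_sites == 18L) richibucto_dd else
        seq(0, max(richibucto_dd), length.out = scenario$n_sites)
      return(.derive_sigma_s(tr$b1, dd, scenario$target_dd_sal_corr))
    }
    v <- switch(p, delta_minus = tr$delta_minus, beta0 = tr$beta0,
                sigma_eps = tr$sigma_eps, sigma_gamma = tr$sigma_gamma,
                b1 = tr$b1, sigma_s = tr$sigma_s,
                unname(tr$beta[sub("^beta\\[(.*)\\]$", "\\1", p)]))
    if (is.null(v) || length(v) == 0) NA_real_ else v
  }, numeric(1))
  out <- data.frame(parameter = watched, truth = truths,
                    coverage = colMeans(hits), n_runs = n_runs,
                    row.names = NULL)
  attr(out, "ratio_means") <- ratio_means
  if (!is.null(out_csv)) write.csv(out, out_csv, row.names = FALSE)
  out
}
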