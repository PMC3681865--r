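## Covariate transformation, centering, and the distance-downstream construction.

# covariate name -> (source column, transform)
.cov_registry <- list(
  dd           = list(col = "dd_km",        transform = "identity"),
  salinity     = list(col = "salinity_ppt", transform = "identity"),
  depth        = list(col = "depth_m",      transform = "identity"),
  log_depth    = list(col = "depth_m",      transform = "log"),
  sc           = list(col = "silt_clay",    transform = "identity"),
  log_sc       = list(col = "silt_clay",    transform = "log"),
  temp         = list(col = "temp_c",       transform = "identity"),
  median_grain = list(col = "median_grain", transform = "identity"),
  sorting      = list(col = "sorting",      transform = "identity"),
  organic      = list(col = "organic_pct",  transform = "identity"),
  month        = list(col = "month",        transform = "identity")
)

.transformed_column <- function(cov, name) {
  info <- .cov_registry[[name]]
  if (is.null(info)) stop("unknown covariate name: ", name)
  x <- cov[[info$col]]
  if (info$col == "month") x <- as.numeric(cov$month == "Oct")
  if (info$transform == "log") {
    if (any(x <= 0)) stop("log transform of nonpositive values in covariate ", name)
    x <- log(x)
  }
  x
}

#' Build a centered design for the latent health regression
#'
#' Transforms the requested covariates (natural log for `log_depth` and
#' `log_sc`), subtracts a centering constant from each, and forms centered
#' interactions as products of centered parent columns.  Centering constants
#' default to the observed sample means of the transformed columns and are
#' stored so that a fitted model can be applied to new sites with the original
#' constants.
#'
#' Covariate names: `dd`, `salinity`, `depth`, `log_depth`, `sc`, `log_sc`,
#' `temp`, `median_grain`, `sorting`, `organic`, `month`; interactions are
#' written `"a:b"`.  The centered distance downstream and centered salinity
#' are always computed (the two-level salinity-on-DD regression needs them)
#' regardless of whether they appear in `covariates`.
#'
#' @param cov a [covariate_table()].
#' @param covariates character vector of covariate and interaction names, in
#'   the order the design columns are wanted.
#' @param constants optional named numeric vector of centering constants for
#'   the non-interaction covariates (plus `dd` and `salinity`); defaults to
#'   sample means of the transformed columns.
#' @return an object of class `centered_design`: a list with the design matrix
#'   `X` (sites x covariates), `centered_dd`, `centered_salinity`, `month`
#'   (factor per site), `centering_constants`, `transform_flags`, `covariates`.
#' @export
#' @examples
#' cov <- synthetic_covariate_table(seed = 1)
#' d <- build_centered_design(cov, c("log_depth", "log_sc", "log_depth:log_sc"))
#' colMeans(d$X)
build_centered_design <- function(cov, covariates, constants = NULL) {
  stopifnot(inherits(cov, "covariate_table"))
  is_int <- grepl(":", covariates, fixed = TRUE)
  parents <- unique(c(unlist(strsplit(covariates[is_int], ":", fixed = TRUE)),
                      covariates[!is_int]))
  base_needed <- unique(c(parents, "dd", "salinity"))

  centered <- list()
  consts <- numeric(0)
  flags <- character(0)
  for (nm in base_needed) {
    x <- .transformed_column(cov, nm)
    cst <- if (!is.null(constants) && nm %in% names(constants)) constants[[nm]] else mean(x)
    centered[[nm]] <- x - cst
    consts[nm] <- cst
    flags[nm] <- .cov_registry[[nm]]$transform
  }

  cols <- lapply(covariates, function(nm) {
    if (grepl(":", nm, fixed = TRUE)) {
      pq <- strsplit(nm, ":", fixed = TRUE)[[1]]
      if (length(pq) != 2L) stop("interactions must have exactly two parents: ", nm)
      centered[[pq[1]]] * centered[[pq[2]]]
    } else centered[[nm]]
  })
  X <- if (length(cols) > 0L) do.call(cbind, cols) else
    matrix(numeric(0), nrow = nrow(cov), ncol = 0)
  colnames(X) <- covariates

  structure(
    list(
      X = X,
      centered_dd = centered[["dd"]],
      centered_salinity = centered[["salinity"]],
      month = factor(cov$month, levels = c("Sep", "Oct")),
      centering_constants = consts,
      transform_flags = flags,
      covariates = covariates
    ),
    class = "centered_design"
  )
}

#' Distance downstream by straight-line projection
#'
#' Collapses two-dimensional site coordinates into a single spatial covariate:
#' the scalar projection of each site onto the straight line from the most
#' upstream site (the first row) to the most downstream site (the last row).
#' The first site has distance 0 by construction.  Coordinates are planar
#' (projected) kilometres; no geodesy is performed.
#'
#' @param coords numeric matrix (sites x 2) of planar coordinates in km,
#'   ordered so that row 1 is the upstream end of the axis and the last row
#'   the downstream end.
#' @return numeric vector of distances downstream (km), one per site.
#' @export
#' @examples
#' project_distance_downstream(cbind(c(0, 1, 2), c(0, 1, 0)))
project_distance_downstream <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L || ncol(coords) != 2L)
    stop("coords must be a (>= 2) x 2 matrix")
  origin <- coords[1L, ]
  axis <- coords[nrow(coords), ] - origin
  len <- sqrt(sum(axis^2))
  if (len == 0)
    stop("degenerate axis: first and last site share the same location")
  u <- axis / len
  as.numeric((coords[, 1L] - origin[1L]) * u[1L] + (coords[, 2L] - origin[2L]) * u[2L])
}
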