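## Readers/writers and validation for the two study tables:
##   counts CSV:      site,month,replicate,m1..m5,total
##   covariates CSV:  site,month,depth_m,temp_c,salinity_ppt,silt_clay,
##                    median_grain,sorting,organic_pct,dd_km

.count_cols <- c("site", "month", "replicate", paste0("m", 1:5), "total")
.cov_cols <- c("site", "month", "depth_m", "temp_c", "salinity_ppt", "silt_clay",
               "median_grain", "sorting", "organic_pct", "dd_km")

#' Construct a benthic metric-count dataset
#'
#' A replicate-level table of metric counts: one row per grab sample, with the
#' abundance of each of the five AMBI ecological groups and the total number of
#' benthic organisms in the grab.  The metric counts need not exhaust the
#' total; the remainder are organisms not classified into any metric and serve
#' as the baseline category of the multinomial links.
#'
#' @param df data frame with columns `site`, `month`, `replicate`,
#'   `m1`..`m5`, `total`.
#' @return a validated `benthic_dataset` (a data frame).
#' @export
benthic_dataset <- function(df) {
  missing <- setdiff(.count_cols, names(df))
  if (length(missing) > 0L)
    stop("counts table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[.count_cols]
  df$site <- as.integer(df$site)
  df$replicate <- as.integer(df$replicate)
  df$month <- as.character(df$month)
  for (m in paste0("m", 1:5)) df[[m]] <- as.integer(df[[m]])
  df$total <- as.integer(df$total)
  counts <- as.matrix(df[paste0("m", 1:5)])
  if (any(counts < 0) || any(df$total < 0))
    stop("counts and totals must be nonnegative")
  bad <- which(rowSums(counts) > df$total)
  if (length(bad) > 0L)
    stop("metric counts exceed total in row(s) ", paste(bad, collapse = ", "),
         " (site ", paste(df$site[bad], collapse = ", "), ")")
  sites <- sort(unique(df$site))
  if (!identical(sites, seq_along(sites)))
    stop("site ids must be contiguous 1..S; got ", paste(sites, collapse = ", "))
  df <- df[order(df$site, df$replicate), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("benthic_dataset", "data.frame")
  df
}

#' Read a benthic counts CSV
#'
#' @param path path to a CSV with header
#'   `site,month,replicate,m1,m2,m3,m4,m5,total`.
#' @return a [benthic_dataset()].
#' @export
read_counts_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in counts file: ", path)
  benthic_dataset(df)
}

#' Write a benthic counts CSV
#'
#' Round-trip safe: `read_counts_csv(write_counts_csv(x, f))` reproduces `x`.
#'
#' @param data a [benthic_dataset()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Number of unclassified organisms per grab
#'
#' @param data a [benthic_dataset()].
#' @return integer vector, `total` minus the sum of the five metric counts.
#' @export
count_remainder <- function(data) {
  data$total - as.integer(rowSums(as.matrix(data[paste0("m", 1:5)])))
}

#' Construct a per-site abiotic covariate table
#'
#' One row per site with the abiotic measurements used as candidate drivers of
#' latent health: channel depth (m), water temperature (deg C), salinity (ppt),
#' silt-clay fraction, median grain size, sorting, organic content (%), the
#' sampling month, and distance downstream (km).  No unit conversion is
#' performed.
#'
#' @param df data frame with columns `site`, `month`, `depth_m`, `temp_c`,
#'   `salinity_ppt`, `silt_clay`, `median_grain`, `sorting`, `organic_pct`,
#'   `dd_km`.
#' @return a validated `covariate_table` (a data frame ordered by site).
#' @export
covariate_table <- function(df) {
  missing <- setdiff(.cov_cols, names(df))
  if (length(missing) > 0L)
    stop("covariate table is missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop("no sites in covariate table")
  df <- df[.cov_cols]
  df$site <- as.integer(df$site)
  dup <- unique(df$site[duplicated(df$site)])
  if (length(dup) > 0L)
    stop("duplicate site(s) in covariate table: ", paste(dup, collapse = ", "))
  if (any(df$dd_km < 0)) stop("dd_km must be nonnegative")
  if (any(df$silt_clay <= 0 | df$silt_clay > 1))
    stop("silt_clay must lie in (0, 1]")
  df <- df[order(df$site), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("covariate_table", "data.frame")
  df
}

#' Read a per-site covariate CSV
#'
#' @param path path to a CSV with one row per site (see [covariate_table()]
#'   for the column contract).
#' @return a `covariate_table`.
#' @export
read_covariates_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no sites in covariate file: ", path)
  covariate_table(df)
}

#' Write a per-site covariate CSV
#'
#' @param cov a `covariate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_covariates_csv <- function(cov, path) {
  write.csv(as.data.frame(cov), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
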