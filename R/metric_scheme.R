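#' Metric grouping scheme for benthic health indices
#'
#' Defines how the observed metrics (abundance counts of ecological groups) are
#' partitioned into a "plus" group, positively associated with health, and a
#' "minus" group, negatively associated.  The default is the AMBI scheme with
#' five ecological groups: groups 1-2 (sensitive/indifferent taxa) form the
#' plus group and groups 3-5 (tolerant to first-order opportunist taxa) the
#' minus group.
#'
#' @param n_metrics number of metrics (default 5, the AMBI ecological groups).
#' @param plus integer indices of metrics positively associated with health.
#' @param minus integer indices of metrics negatively associated with health.
#'
#' @return an object of class `metric_scheme`: a list with `metric_ids`,
#'   `group_of` (factor "plus"/"minus" per metric) and `sign_of`
#'   (`c(plus = 1, minus = -1)`).
#' @export
#' @examples
#' sc <- metric_scheme()
#' sc$group_of
metric_scheme <- function(n_metrics = 5L, plus = c(1L, 2L), minus = c(3L, 4L, 5L)) {
  n_metrics <- as.integer(n_metrics)
  plus <- as.integer(plus)
  minus <- as.integer(minus)
  if (length(intersect(plus, minus)) > 0L)
    stop("metrics cannot belong to both groups")
  if (!setequal(c(plus, minus), seq_len(n_metrics)))
    stop("every metric must belong to exactly one group")
  group_of <- character(n_metrics)
  group_of[plus] <- "plus"
  group_of[minus] <- "minus"
  structure(
    list(
      metric_ids = seq_len(n_metrics),
      group_of = factor(group_of, levels = c("plus", "minus")),
      sign_of = c(plus = 1, minus = -1),
      plus = sort(plus),
      minus = sort(minus)
    ),
    class = "metric_scheme"
  )
}

#' @export
print.metric_scheme <- function(x, ...) {
  cat("Metric scheme:", length(x$metric_ids), "metrics\n")
  cat("  plus  (+1):", paste(x$plus, collapse = ", "), "\n")
  cat("  minus (-1):", paste(x$minus, collapse = ", "), "\n")
  invisible(x)
}
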