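#' Scan-statistic parameters
#'
#' Bundles every tuning constant of the cylindrical space-time scan.
#' Defaults follow common practice for non-communicable-disease
#' surveillance at small-area resolution: a 30-day maximum temporal window
#' on one-day aggregation, a spatial window capped at half the population
#' at risk, a minimum of 2 cases per reported cluster, 999 Monte-Carlo
#' replications and a 0.05 significance level.
#'
#' @param mode `"retrospective"` scans windows anywhere in the study
#'   period; `"prospective"` scans only windows ending on the final day
#'   ("active" clusters), the mode used for periodic surveillance.
#' @param t_max_days Maximum temporal window height, in days.
#' @param aggregation_days Temporal aggregation unit, in days (1 = daily).
#' @param max_pop_fraction Maximum fraction of the total population a
#'   spatial window may cover, in (0, 1].
#' @param min_cases Minimum observed cases for a cluster to be reported.
#' @param n_replications Monte-Carlo replications for significance testing.
#' @param alpha Significance level for the alarm flag.
#' @param distance_metric `"great_circle"` (haversine, Earth radius
#'   6371 km) or `"euclidean"` (degrees treated as planar; only sensible
#'   for abstract/simulated geometries).
#' @param seed Master seed for Monte-Carlo inference.
#'
#' @return An object of class `scan_params`.
#' @examples
#' scan_params(mode = "prospective", t_max_days = 30)
#' @export
scan_params <- function(mode = c("retrospective", "prospective"),
                        t_max_days = 30L,
                        aggregation_days = 1L,
                        max_pop_fraction = 0.5,
                        min_cases = 2L,
                        n_replications = 999L,
                        alpha = 0.05,
                        distance_metric = c("great_circle", "euclidean"),
                        seed = 1L) {
  mode <- match.arg(mode)
  distance_metric <- match.arg(distance_metric)
  t_max_days <- as.integer(t_max_days)
  aggregation_days <- as.integer(aggregation_days)
  min_cases <- as.integer(min_cases)
  n_replications <- as.integer(n_replications)
  if (aggregation_days < 1L) stop_vld("aggregation_days must be >= 1")
  if (t_max_days < aggregation_days) {
    stop_vld("t_max_days (%d) must be >= aggregation_days (%d)",
             t_max_days, aggregation_days)
  }
  if (!(max_pop_fraction > 0 && max_pop_fraction <= 1)) {
    stop_vld("max_pop_fraction must lie in (0, 1]")
  }
  if (min_cases < 1L) stop_vld("min_cases must be >= 1")
  if (n_replications < 0L) stop_vld("n_replications must be >= 0")
  if (!(alpha > 0 && alpha < 1)) stop_vld("alpha must lie in (0, 1)")
  structure(
    list(mode = mode, t_max_days = t_max_days,
         aggregation_days = aggregation_days,
         max_pop_fraction = max_pop_fraction, min_cases = min_cases,
         n_replications = n_replications, alpha = alpha,
         distance_metric = distance_metric, seed = as.integer(seed)),
    class = "scan_params")
}

#' @export
print.scan_params <- function(x, ...) {
  cat("Space-time scan parameters\n")
  cat(sprintf("  mode:              %s\n", x$mode))
  cat(sprintf("  temporal window:   <= %d days (aggregation %d day%s)\n",
              x$t_max_days, x$aggregation_days,
              if (x$aggregation_days == 1L) "" else "s"))
  cat(sprintf("  spatial window:    <= %.0f%% of population at risk\n",
              100 * x$max_pop_fraction))
  cat(sprintf("  reporting:         min %d cases, high rates only\n", x$min_cases))
  cat(sprintf("  inference:         %d Monte-Carlo replications, alpha = %g, seed = %d\n",
              x$n_replications, x$alpha, x$seed))
  invisible(x)
}

#' Study period
#'
#' The closed date interval over which cases are scanned, plus the temporal
#' aggregation length. Days are grouped into `ceiling(n_days /
#' aggregation_days)` units counted from `start`.
#'
#' @param start,end First and last calendar date (inclusive); anything
#'   `as.Date()` accepts, or `YYYY/MM/DD`.
#' @param aggregation_days Positive integer aggregation unit.
#' @return An object of class `study_period`.
#' @examples
#' study_period("2008-01-01", "2017-12-31")
#' @export
study_period <- function(start, end, aggregation_days = 1L) {
  start <- parse_scan_date(start)
  end <- parse_scan_date(end)
  if (is.na(start) || is.na(end)) stop_vld("unparseable study period date")
  if (start > end) stop_vld("study period start (%s) is after end (%s)", start, end)
  aggregation_days <- as.integer(aggregation_days)
  if (aggregation_days < 1L) stop_vld("aggregation_days must be >= 1")
  n_days <- as.integer(end - start) + 1L
  structure(
    list(start = start, end = end, aggregation_days = aggregation_days,
         n_days = n_days,
         n_units = as.integer(ceiling(n_days / aggregation_days))),
    class = "study_period")
}

#' @export
print.study_period <- function(x, ...) {
  cat(sprintf("Study period %s .. %s (%d days, %d unit%s of %d day%s)\n",
              x$start, x$end, x$n_days, x$n_units,
              if (x$n_units == 1L) "" else "s",
              x$aggregation_days,
              if (x$aggregation_days == 1L) "" else "s"))
  invisible(x)
}

# date -> 1-based aggregated time-unit index within the period
date_to_unit <- function(dates, period) {
  as.integer(as.integer(dates - period$start) %/% period$aggregation_days) + 1L
}

# inclusive date range covered by aggregated units [a, b]
unit_to_dates <- function(a, b, period) {
  t_start <- period$start + (a - 1L) * period$aggregation_days
  t_end <- pmin(period$start + b * period$aggregation_days - 1L, period$end)
  list(t_start = t_start, t_end = t_end)
}
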