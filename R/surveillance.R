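#' Periodic analysis schedule
#'
#' The dates on which a prospective scan is (re-)run during surveillance
#' replay.
#'
#' @param frequency `"daily"`, `"weekly"`, `"monthly"` or `"yearly"`.
#' @param first,last First and last analysis date (inclusive).
#' @return An object of class `analysis_schedule` holding the analysis
#'   dates.
#' @examples
#' analysis_schedule("monthly", "2017-01-31", "2017-12-31")
#' @export
analysis_schedule <- function(frequency = c("daily", "weekly", "monthly", "yearly"),
                              first, last) {
  frequency <- match.arg(frequency)
  first <- parse_scan_date(first)
  last <- parse_scan_date(last)
  if (is.na(first) || is.na(last)) stop_vld("unparseable schedule date")
  if (first > last) stop_vld("schedule first date is after last date")
  by <- switch(frequency, daily = "day", weekly = "week",
               monthly = "month", yearly = "year")
  dates <- seq(first, last, by = by)
  structure(list(frequency = frequency, dates = dates),
            class = "analysis_schedule")
}

#' Replay prospective surveillance over a historical case stream
#'
#' Re-runs the prospective scan at each scheduled analysis date as if the
#' surveillance system had been live: the analysis at date `d` sees only
#' cases dated on or before `d` and scans windows ending exactly at `d`
#' ("active" clusters). An alarm is raised whenever any reported cluster
#' has `p < alpha`. Seeding is per analysis (master seed + analysis
#' index), so the timeline is reproducible and insensitive to schedule
#' truncation.
#'
#' @param dataset A [scan_dataset()].
#' @param params A [scan_params()]; the mode is forced to prospective.
#' @param schedule An [analysis_schedule()] within the dataset period.
#' @return An object of class `alarm_timeline` with `$analyses` (one row
#'   per analysis date: `analysis_date`, `n_cases_seen`, `n_clusters`,
#'   `alarm`, and most-likely-cluster columns `mlc_*`) and `$clusters`
#'   (all reported clusters across analyses, tagged by `analysis_date`).
#' @export
prospective_replay <- function(dataset, params = scan_params(mode = "prospective"),
                               schedule) {
  stopifnot(inherits(dataset, "scan_dataset"),
            inherits(schedule, "analysis_schedule"))
  if (length(schedule$dates) == 0L) stop_vld("empty analysis schedule")
  if (min(schedule$dates) < dataset$period$start ||
      max(schedule$dates) > dataset$period$end) {
    stop_vld("schedule dates fall outside the study period")
  }
  params$mode <- "prospective"
  entries <- vector("list", length(schedule$dates))
  cluster_tabs <- vector("list", length(schedule$dates))
  for (i in seq_along(schedule$dates)) {
    d <- schedule$dates[i]
    cases_d <- dataset$cases[dataset$cases$event_date <= d, , drop = FALSE]
    period_d <- study_period(dataset$period$start, d, params$aggregation_days)
    ds_d <- scan_dataset(cases_d, dataset$locations, period_d)
    params_d <- params
    params_d$seed <- params$seed + i
    res <- run_scan(ds_d, params_d)
    cl <- res$clusters
    alarm <- nrow(cl) > 0L && !is.null(cl$p_value) &&
      any(cl$p_value < params$alpha)
    mlc <- if (nrow(cl)) cl[1L, , drop = FALSE] else NULL
    entries[[i]] <- data.frame(
      analysis_date = d,
      n_cases_seen = nrow(cases_d),
      n_clusters = nrow(cl),
      alarm = alarm,
      mlc_t_start = if (!is.null(mlc)) mlc$t_start else as.Date(NA),
      mlc_observed = if (!is.null(mlc)) mlc$observed else NA_integer_,
      mlc_expected = if (!is.null(mlc)) mlc$expected else NA_real_,
      mlc_llr = if (!is.null(mlc)) mlc$llr else NA_real_,
      mlc_p_value = if (!is.null(mlc) && !is.null(mlc$p_value)) mlc$p_value else NA_real_)
    if (nrow(cl)) {
      cl$analysis_date <- d
      cluster_tabs[[i]] <- cl
    }
  }
  clusters <- do.call(rbind, cluster_tabs[!vapply(cluster_tabs, is.null, logical(1))])
  structure(
    list(analyses = do.call(rbind, entries),
         clusters = clusters,
         schedule = schedule, params = params),
    class = "alarm_timeline")
}

#' @export
print.alarm_timeline <- function(x, ...) {
  a <- x$analyses
  cat(sprintf("Surveillance replay: %d %s analyses, %s .. %s\n",
              nrow(a), x$schedule$frequency,
              min(a$analysis_date), max(a$analysis_date)))
  cat(sprintf("  alarms raised: %d (alpha = %g)\n", sum(a$alarm),
              x$params$alpha))
  invisible(x)
}

#' Chronological cluster timeline records
#'
#' Flattens scan results into plotting/export-ready timeline records,
#' sorted by start date: one row per cluster with its interval, duration
#' (end minus start, in days), observed/expected counts, relative risk
#' and p-value.
#'
#' @param results A `scan_result`, an `alarm_timeline`, or a cluster data
#'   frame from either.
#' @return A data frame with columns `cluster_id`, `start_date`,
#'   `end_date`, `duration_days`, `observed`, `expected`,
#'   `relative_risk`, `p_value`, `significant`.
#' @export
build_cluster_timeline <- function(results) {
  cl <- if (inherits(results, "scan_result")) results$clusters
        else if (inherits(results, "alarm_timeline")) results$clusters
        else results
  if (is.null(cl) || nrow(cl) == 0L) {
    return(data.frame(cluster_id = integer(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      duration_days = integer(0), observed = integer(0),
                      expected = numeric(0), relative_risk = numeric(0),
                      p_value = numeric(0), significant = logical(0)))
  }
  out <- data.frame(
    start_date = cl$t_start,
    end_date = cl$t_end,
    duration_days = as.integer(cl$t_end - cl$t_start),
    observed = cl$observed,
    expected = cl$expected,
    relative_risk = cl$relative_risk,
    p_value = if (!is.null(cl$p_value)) cl$p_value else NA_real_,
    significant = if (!is.null(cl$significant)) cl$significant else NA)
  out <- out[order(out$start_date, out$end_date), , drop = FALSE]
  out <- cbind(cluster_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write a cluster timeline to CSV
#'
#' @param timeline Output of [build_cluster_timeline()].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_timeline_csv <- function(timeline, path) {
  tl <- timeline
  tl$start_date <- format(tl$start_date, "%Y-%m-%d")
  tl$end_date <- format(tl$end_date, "%Y-%m-%d")
  utils::write.csv(tl, path, row.names = FALSE, na = "")
  invisible(path)
}
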