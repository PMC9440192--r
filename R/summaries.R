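#' Demographic breakdown of cases
#'
#' Counts and percentage shares by gender, age group or method of death —
#' the data products behind a surveillance dashboard's pie charts.
#' Percentages are taken over cases with a non-missing value; missing
#' values are reported separately, never silently dropped, so the
#' percentage column always closes to 100 (up to floating point).
#'
#' Age is taken from `age_years` where present, otherwise computed in
#' completed years at the event date from `birth_date`. Age bins are
#' half-open, low-inclusive: `[0, 10), [10, 20), ...` by default, with a
#' terminal `90+`.
#'
#' @param cases Case records (e.g. `dataset$cases`).
#' @param dimension `"gender"`, `"age_group"` or `"method"`.
#' @param age_bins Strictly increasing lower bin edges (with `Inf`
#'   implied above the last edge) used when `dimension = "age_group"`.
#' @return An object of class `breakdown_table`: a list with `dimension`,
#'   `table` (data frame `category`, `count`, `percent`), `n_missing`,
#'   `n_total`.
#' @examples
#' cases <- data.frame(gender = c("male", "male", "male", "female"))
#' demographic_breakdown(cases, "gender")$table
#' @export
demographic_breakdown <- function(cases,
                                  dimension = c("gender", "age_group", "method"),
                                  age_bins = seq(0, 90, by = 10)) {
  dimension <- match.arg(dimension)
  n_total <- nrow(cases)
  values <- switch(
    dimension,
    gender = as.character(cases$gender %||% rep(NA_character_, n_total)),
    method = as.character(cases$method %||% rep(NA_character_, n_total)),
    age_group = {
      if (is.unsorted(age_bins, strictly = TRUE)) {
        stop_vld("age_bins must be strictly increasing")
      }
      age <- cases$age_years %||% rep(NA_real_, n_total)
      if (!is.null(cases$birth_date) && !is.null(cases$event_date)) {
        need <- is.na(age) & !is.na(cases$birth_date)
        if (any(need)) {
          age[need] <- completed_years(cases$birth_date[need],
                                       cases$event_date[need])
        }
      }
      bin_ages(age, age_bins)
    })
  missing <- is.na(values)
  tab <- table(values[!missing])
  counts <- as.integer(tab)
  out <- data.frame(category = as.character(names(tab) %||% character(0)),
                    count = counts,
                    percent = if (sum(counts)) 100 * counts / sum(counts)
                              else numeric(length(counts)),
                    stringsAsFactors = FALSE)
  if (dimension == "age_group") {
    lev <- age_bin_labels(age_bins)
    out <- out[order(match(out$category, lev)), , drop = FALSE]
  } else {
    out <- out[order(-out$count, out$category), , drop = FALSE]
  }
  rownames(out) <- NULL
  structure(list(dimension = dimension, table = out,
                 n_missing = sum(missing), n_total = n_total),
            class = "breakdown_table")
}

completed_years <- function(birth, at) {
  by <- as.integer(format(birth, "%Y")); ay <- as.integer(format(at, "%Y"))
  years <- ay - by
  # subtract one if the birthday has not yet occurred in the event year
  had_birthday <- format(at, "%m%d") >= format(birth, "%m%d")
  years - as.integer(!had_birthday)
}

age_bin_labels <- function(edges) {
  n <- length(edges)
  c(sprintf("%g-%g", edges[-n], edges[-1] - 1), sprintf("%g+", edges[n]))
}

bin_ages <- function(age, edges) {
  labels <- age_bin_labels(edges)
  idx <- findInterval(age, c(edges, Inf))  # half-open [edge_i, edge_{i+1})
  out <- rep(NA_character_, length(age))
  ok <- !is.na(age) & idx >= 1L
  out[ok] <- labels[idx[ok]]
  out
}

#' @export
print.breakdown_table <- function(x, ...) {
  cat(sprintf("Breakdown by %s (%d cases, %d missing)\n",
              x$dimension, x$n_total, x$n_missing))
  tb <- x$table
  tb$percent <- sprintf("%.1f%%", tb$percent)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Write a breakdown table to CSV
#'
#' @param breakdown A [demographic_breakdown()] result.
#' @param path Destination file; a final `missing` row carries the count
#'   of cases without a value.
#' @return Invisibly, `path`.
#' @export
write_breakdown_csv <- function(breakdown, path) {
  tb <- breakdown$table
  tb <- rbind(tb, data.frame(category = "(missing)",
                             count = breakdown$n_missing, percent = NA_real_))
  utils::write.csv(tb, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Export detected clusters as GeoJSON
#'
#' One feature per reported cluster: the scanning circle approximated by
#' a 64-segment geodesic buffer around the centre location (a point
#' feature when the radius is zero), with the cluster's dates, counts,
#' relative risk and p-value as properties. Output follows RFC 7946:
#' WGS84, `[longitude, latitude]` order.
#'
#' @param result A `scan_result` (or its `$clusters` data frame, in which
#'   case `locations` must be supplied).
#' @param locations A [location_table()] resolving centre ids; defaults
#'   to the one stored in `result`.
#' @param path Optional output file; when `NULL` the GeoJSON text is
#'   returned.
#' @param n_segments Segments used to approximate each circle.
#' @return The GeoJSON string (invisibly when written to `path`).
#' @export
export_clusters_geojson <- function(result, locations = NULL, path = NULL,
                                    n_segments = 64L) {
  if (inherits(result, "scan_result")) {
    clusters <- result$clusters
    locations <- locations %||% result$locations
  } else {
    clusters <- result
    if (is.null(locations)) stop_vld("locations required when passing a cluster table")
  }
  features <- vector("list", nrow(clusters))
  for (r in seq_len(nrow(clusters))) {
    cl <- clusters[r, , drop = FALSE]
    i <- match(cl$centre_location_id, locations$location_id)
    if (is.na(i)) stop_vld("unknown centre location '%s'", cl$centre_location_id)
    centre <- c(locations$longitude[i], locations$latitude[i])
    if (cl$radius_km > 0) {
      bearings <- seq(0, 360, length.out = n_segments + 1L)
      ring <- geosphere::destPoint(centre, bearings, cl$radius_km * 1000,
                                   r = 6371000)
      ring[n_segments + 1L, ] <- ring[1L, ]  # close the ring exactly
      geometry <- list(type = "Polygon",
                       coordinates = list(unname(ring)))
    } else {
      geometry <- list(type = "Point", coordinates = centre)
    }
    props <- list(
      cluster = cl$cluster,
      centre_location_id = cl$centre_location_id,
      radius_km = cl$radius_km,
      n_locations = cl$n_locations,
      start_date = format(cl$t_start, "%Y-%m-%d"),
      end_date = format(cl$t_end, "%Y-%m-%d"),
      duration_days = cl$duration_days,
      observed = cl$observed,
      expected = cl$expected,
      relative_risk = if (is.finite(cl$relative_risk)) cl$relative_risk else "Inf",
      llr = cl$llr)
    if (!is.null(clusters$p_value)) {
      props$p_value <- cl$p_value
      props$significant <- cl$significant
    }
    features[[r]] <- list(type = "Feature", geometry = geometry,
                          properties = props)
  }
  doc <- list(type = "FeatureCollection", features = features)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                           null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}
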