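#' Configuration for a synthetic surveillance dataset
#'
#' Describes a seeded synthetic study: small-area centroids placed
#' uniformly in a bounding box, heterogeneous census populations drawn
#' from a log-normal model, a population-proportional Poisson background
#' case process that is homogeneous in time, and optional planted
#' cylindrical clusters with elevated relative risk. The defaults emulate
#' a county-scale decade of suicide mortality surveillance: 100 small
#' areas in a 1 degree x 1 degree box, log-normal populations (median
#' 250), and 388 expected cases over 2008-2017.
#'
#' @param n_locations Number of small areas.
#' @param bbox Named numeric vector `c(lat_min, lat_max, lon_min,
#'   lon_max)` in degrees.
#' @param start,end Study period dates (daily resolution).
#' @param expected_total_cases Expected total case count over the period
#'   (Poisson-total mode); ignored when `n_cases` is given.
#' @param n_cases If non-`NULL`, condition on exactly this many cases
#'   (conditional multinomial mode).
#' @param pop_median,pop_sdlog Log-normal population model: median count
#'   and log-scale standard deviation.
#' @param populations Optional explicit population vector overriding the
#'   log-normal model (length `n_locations`).
#' @param planted_clusters List of planted clusters; each element is a
#'   list with `relative_risk` (>= 1), a window `t_start`/`t_end`
#'   (dates within the period), and a spatial extent given either as
#'   `centre_lat`/`centre_lon` plus `radius_km`, or as `centre_location`
#'   (index) plus `n_locations` (the window is that location and its
#'   `n_locations - 1` nearest neighbours).
#' @param demographics Generate gender / age / method-of-death fields?
#' @param seed Mandatory RNG seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_locations = 100L,
                             bbox = c(lat_min = 51.5, lat_max = 52.5,
                                      lon_min = -9.5, lon_max = -8.5),
                             start = "2008-01-01", end = "2017-12-31",
                             expected_total_cases = 388,
                             n_cases = NULL,
                             pop_median = 250, pop_sdlog = 0.6,
                             populations = NULL,
                             planted_clusters = list(),
                             demographics = TRUE,
                             seed) {
  if (missing(seed)) stop_vld("synthetic_config requires an explicit seed")
  period <- study_period(start, end)
  if (bbox[["lat_max"]] <= bbox[["lat_min"]] ||
      bbox[["lon_max"]] <= bbox[["lon_min"]]) {
    stop_vld("degenerate bounding box")
  }
  if (!is.null(populations) && length(populations) != n_locations) {
    stop_vld("populations must have length n_locations")
  }
  for (pc in planted_clusters) {
    if (is.null(pc$relative_risk) || pc$relative_risk < 1) {
      stop_vld("planted clusters require relative_risk >= 1")
    }
    ts <- parse_scan_date(pc$t_start); te <- parse_scan_date(pc$t_end)
    if (is.na(ts) || is.na(te) || ts > te ||
        ts < period$start || te > period$end) {
      stop_vld("planted cluster window must lie within the study period")
    }
    has_circle <- !is.null(pc$centre_lat) && !is.null(pc$centre_lon) &&
      !is.null(pc$radius_km)
    has_knn <- !is.null(pc$centre_location) && !is.null(pc$n_locations)
    if (!has_circle && !has_knn) {
      stop_vld("planted cluster needs centre_lat/centre_lon/radius_km or centre_location/n_locations")
    }
  }
  structure(
    list(n_locations = as.integer(n_locations), bbox = bbox,
         period = period,
         expected_total_cases = expected_total_cases,
         n_cases = if (is.null(n_cases)) NULL else as.integer(n_cases),
         pop_median = pop_median, pop_sdlog = pop_sdlog,
         populations = populations,
         planted_clusters = planted_clusters,
         demographics = isTRUE(demographics), seed = as.integer(seed)),
    class = "synthetic_config")
}

#' Generate a synthetic dataset
#'
#' Draws a full [scan_dataset()] from a [synthetic_config()]:
#' per-(location, day) Poisson rates proportional to population and
#' uniform over days, multiplied by the planted relative risk inside any
#' planted cylinder; the total is Poisson (or fixed via `n_cases`) and
#' cases are placed by a conditional multinomial draw. Fully reproducible
#' from the seed. The realised planted clusters (member locations and
#' windows) are attached as `attr(, "truth")` for power evaluation.
#'
#' @param config A [synthetic_config()].
#' @return A [scan_dataset()] with attributes `truth` (list of realised
#'   planted clusters) and `config`.
#' @export
generate_synthetic <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_rng_seed(config$seed, {
    L <- config$n_locations
    bb <- config$bbox
    lat <- stats::runif(L, bb[["lat_min"]], bb[["lat_max"]])
    lon <- stats::runif(L, bb[["lon_min"]], bb[["lon_max"]])
    pop <- config$populations %||%
      pmax(1, round(stats::rlnorm(L, meanlog = log(config$pop_median),
                                  sdlog = config$pop_sdlog)))
    locations <- location_table(sprintf("SA%04d", seq_len(L)), lat, lon, pop)
    period <- config$period
    Tn <- period$n_units
    base <- config$expected_total_cases *
      (locations$population / sum(locations$population)) / Tn
    rate <- matrix(base, nrow = L, ncol = Tn)  # recycled down columns
    truth <- list()
    for (pc in config$planted_clusters) {
      if (!is.null(pc$centre_location)) {
        ci <- as.integer(pc$centre_location)
        d <- great_circle_km(locations$latitude, locations$longitude,
                             locations$latitude[ci], locations$longitude[ci])
        o <- order(d, locations$location_id)
        members <- o[seq_len(min(as.integer(pc$n_locations), L))]
        radius <- max(d[members])
      } else {
        d <- great_circle_km(locations$latitude, locations$longitude,
                             pc$centre_lat, pc$centre_lon)
        members <- which(d <= pc$radius_km)
        radius <- pc$radius_km
      }
      a <- date_to_unit(parse_scan_date(pc$t_start), period)
      b <- date_to_unit(parse_scan_date(pc$t_end), period)
      if (length(members)) {
        rate[members, a:b] <- rate[members, a:b] * pc$relative_risk
        truth[[length(truth) + 1L]] <- list(
          member_location_ids = locations$location_id[members],
          t_start = parse_scan_date(pc$t_start),
          t_end = parse_scan_date(pc$t_end),
          relative_risk = pc$relative_risk,
          radius_km = radius,
          expected_excess = (pc$relative_risk - 1) *
            sum(base[members]) * (b - a + 1L))
      }
    }
    N <- if (!is.null(config$n_cases)) config$n_cases
         else stats::rpois(1L, sum(rate))
    cases <- empty_cases()
    if (N > 0L) {
      cell <- stats::rmultinom(1L, N, as.vector(rate))[, 1L]
      nz <- which(cell > 0L)
      loc_idx <- rep.int((nz - 1L) %% L + 1L, cell[nz])
      unit <- rep.int((nz - 1L) %/% L + 1L, cell[nz])
      ord <- order(unit, loc_idx)
      loc_idx <- loc_idx[ord]; unit <- unit[ord]
      cases <- data.frame(
        case_id = sprintf("C%06d", seq_len(N)),
        location_id = locations$location_id[loc_idx],
        event_date = period$start + (unit - 1L),
        stringsAsFactors = FALSE)
      if (config$demographics) {
        cases$gender <- sample(c("male", "female"), N, replace = TRUE,
                               prob = c(0.78, 0.22))
        age <- round(stats::rnorm(N, mean = 44, sd = 16))
        cases$age_years <- pmin(95, pmax(12, age))
        cases$birth_date <- as.Date(rep(NA_character_, N))
        cases$method <- sample(c("hanging", "drowning", "poisoning", "other"),
                               N, replace = TRUE, prob = c(0.6, 0.15, 0.15, 0.1))
      } else {
        cases$gender <- NA_character_
        cases$age_years <- NA_real_
        cases$birth_date <- as.Date(rep(NA_character_, N))
        cases$method <- NA_character_
      }
    }
    ds <- scan_dataset(cases, locations, period)
    attr(ds, "truth") <- truth
    attr(ds, "config") <- config
    ds
  })
}

#' Overlap between a detected cluster and a planted truth cluster
#'
#' Spatial agreement is the Jaccard index of the member-location sets;
#' temporal agreement is the Jaccard overlap of the day intervals
#' (intersection length / union length, in days).
#'
#' @param detected A one-row slice of `scan_result$clusters`, or a list
#'   with `members` (or `member_location_ids`), `t_start`, `t_end`.
#' @param truth An element of `attr(dataset, "truth")`.
#' @return A list with `spatial_jaccard` and `temporal_overlap`, both in
#'   \[0, 1\].
#' @export
plant_truth_overlap <- function(detected, truth) {
  det_members <- if (is.data.frame(detected)) detected$members[[1L]]
                 else detected$members %||% detected$member_location_ids
  det_start <- if (is.data.frame(detected)) detected$t_start else detected$t_start
  det_end <- if (is.data.frame(detected)) detected$t_end else detected$t_end
  tru_members <- truth$member_location_ids %||% truth$members
  spatial <- jaccard(det_members, tru_members)
  inter <- max(0, as.integer(min(det_end, truth$t_end) -
                               max(det_start, truth$t_start)) + 1L)
  uni <- as.integer(max(det_end, truth$t_end) -
                      min(det_start, truth$t_start)) + 1L
  list(spatial_jaccard = spatial,
       temporal_overlap = if (uni > 0) inter / uni else 0)
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}
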