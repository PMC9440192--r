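#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km, the conventional
#' mean Earth radius. Vectorised over all arguments.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in km.
#' @examples
#' great_circle_km(51.8985, -8.4756, 53.3498, -6.2603) # Cork - Dublin
#' @export
great_circle_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) stop_vld("latitude out of range")
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) stop_vld("longitude out of range")
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = 6371)
}

location_distance <- function(locations, metric = "great_circle") {
  L <- nrow(locations)
  D <- matrix(0, L, L)
  if (metric == "great_circle") {
    for (i in seq_len(L)) {
      D[, i] <- great_circle_km(locations$latitude, locations$longitude,
                                locations$latitude[i], locations$longitude[i])
    }
  } else {
    D <- as.matrix(stats::dist(cbind(locations$latitude, locations$longitude)))
  }
  D
}

#' Null expected counts per location-time cell
#'
#' Under the discrete Poisson model, conditional on the observed total
#' `N`, the expected count in cell (location, time unit) is proportional
#' to the location's census population, spread uniformly over time units:
#' `mu = N * pop / pop_total / n_units`. Expectations sum to `N` exactly.
#'
#' @param locations A [location_table()].
#' @param period A [study_period()].
#' @param N Total observed case count.
#' @return An object of class `expected_surface` (factorised form); use
#'   `as.matrix()` for the dense location x time-unit matrix.
#' @examples
#' loc <- location_table(c("A", "B"), c(52, 52.1), c(-8.5, -8.4), c(100, 300))
#' s <- expected_counts(loc, study_period("2020-01-01", "2020-01-10"), 8)
#' as.matrix(s)[1, 1] # 8 * (100/400) * (1/10) = 0.2
#' @export
expected_counts <- function(locations, period, N) {
  stopifnot(inherits(period, "study_period"), N >= 0)
  pop_total <- sum(locations$population)
  if (pop_total <= 0) stop_vld("total population must be > 0")
  structure(
    list(location_id = locations$location_id,
         pop_frac = locations$population / pop_total,
         n_units = period$n_units, N = N),
    class = "expected_surface")
}

#' @export
as.matrix.expected_surface <- function(x, ...) {
  m <- x$N * outer(x$pop_frac, rep(1 / x$n_units, x$n_units))
  rownames(m) <- x$location_id
  m
}

#' Poisson scan log-likelihood ratio
#'
#' The test statistic of the discrete-Poisson scan, conditional on the
#' total count `N`: for a window with observed `O` and null expectation
#' `E`, `LLR = O log(O/E) + (N - O) log((N - O)/(N - E))` when `O > E`,
#' and 0 otherwise (high-rate, one-sided). The convention `0 log 0 = 0`
#' makes `O = N` finite.
#'
#' @param O Observed count(s) in the window, `0 <= O <= N`.
#' @param E Expected count(s), `0 < E < N`.
#' @param N Total case count.
#' @return Log-likelihood ratio(s), `>= 0`.
#' @examples
#' poisson_llr(3, 0.103, 388)
#' @export
poisson_llr <- function(O, E, N) {
  if (any(O < 0 | O > N)) stop_vld("O must satisfy 0 <= O <= N")
  if (any(E <= 0 | E >= N)) stop_vld("E must satisfy 0 < E < N")
  t1 <- ifelse(O > 0, O * log(O / E), 0)
  t2 <- ifelse(N - O > 0, (N - O) * log((N - O) / (N - E)), 0)
  ifelse(O > E, t1 + t2, 0)
}

#' Relative risk of a scan window
#'
#' Estimated rate ratio inside versus outside the window:
#' `RR = (O/E) / ((N - O)/(N - E))`; `Inf` when all cases fall inside.
#'
#' @inheritParams poisson_llr
#' @return Relative risk(s).
#' @export
relative_risk <- function(O, E, N) {
  if (any(O < 0 | O > N)) stop_vld("O must satisfy 0 <= O <= N")
  if (any(E <= 0 | E >= N)) stop_vld("E must satisfy 0 < E < N")
  ifelse(O == N, Inf, (O / E) / ((N - O) / (N - E)))
}

# --- scan geometry -----------------------------------------------------

# For every centre location, the candidate spatial windows are the nested
# sets obtained by absorbing locations in order of distance (ties broken
# by location id); the window stops growing when its population would
# exceed max_pop_fraction of the total. The degenerate centre-only window
# is always scanned, so purely temporal scanning remains possible even
# when a single location dominates the population.
build_scan_geometry <- function(locations, params) {
  L <- nrow(locations)
  if (L == 0L) stop_vld("location table is empty")
  D <- location_distance(locations, params$distance_metric)
  pop <- locations$population
  pop_total <- sum(pop)
  cap <- params$max_pop_fraction * pop_total
  ord <- vector("list", L)
  K <- integer(L)
  radii <- vector("list", L)
  pf <- vector("list", L)
  for (i in seq_len(L)) {
    o <- order(D[, i], locations$location_id)
    cum <- cumsum(pop[o])
    k <- sum(cum <= cap + 1e-9)
    k <- max(1L, k)
    ord[[i]] <- o[seq_len(k)]
    K[i] <- k
    radii[[i]] <- D[o[seq_len(k)], i]
    pf[[i]] <- cum[seq_len(k)] / pop_total
  }
  list(L = L, ord = ord, K = K, radii = radii, pop_frac = pf,
       loc_pop_frac = pop / pop_total,
       location_id = locations$location_id, pop_total = pop_total)
}

max_temporal_units <- function(params) {
  max(1L, params$t_max_days %/% params$aggregation_days)
}

# Best interval for one spatial zone, searching only windows whose ends
# are anchored on case time-units: for fixed O, shrinking a window
# strictly decreases E and so strictly increases the LLR, hence an
# optimal window spans from one case unit to another (or, prospectively,
# from a case unit to the final unit).
zone_best_interval <- function(ts, pf, N, n_units, maxu, prospective,
                               min_O = 1L) {
  if (length(ts) == 0L) return(NULL)
  r <- rle(sort.int(ts, method = "radix"))
  us <- r$values
  cnt <- r$lengths
  cum <- cumsum(cnt)
  m <- length(us)
  if (prospective) {
    low <- n_units - maxu + 1L
    sel <- which(us >= low)
    if (length(sel) == 0L) return(NULL)
    O <- cum[m] - cum[sel] + cnt[sel]
    a <- us[sel]
    b <- rep.int(n_units, length(sel))
  } else {
    jm <- findInterval(us + maxu - 1L, us)
    lens <- jm - seq_len(m) + 1L
    i <- rep.int(seq_len(m), lens)
    j <- sequence(lens, from = seq_len(m))
    O <- cum[j] - cum[i] + cnt[i]
    a <- us[i]
    b <- us[j]
  }
  len <- b - a + 1L
  E <- N * pf * len / n_units
  keep <- O >= min_O & (O > E | (E == 0 & O > 0))
  if (!any(keep)) return(NULL)
  O <- O[keep]; E <- E[keep]; a <- a[keep]; b <- b[keep]
  llr <- ifelse(E > 0,
                ifelse(O > 0, O * log(O / E), 0) +
                  ifelse(N - O > 0, (N - O) * log((N - O) / (N - E)), 0),
                Inf)
  best <- order(-llr, a, b)[1L]
  list(llr = llr[best], O = O[best], E = E[best], a = a[best], b = b[best])
}

# Scan every zone; either return the maximum LLR over all cylinders
# (report = FALSE, used for Monte-Carlo replicates) or a table of the
# best window per zone subject to the min-case rule (report = TRUE).
scan_zones <- function(geom, case_loc, case_unit, n_units, N, params,
                       report = FALSE) {
  maxu <- min(max_temporal_units(params), n_units)
  prospective <- params$mode == "prospective"
  min_O <- if (report) params$min_cases else 1L
  loc_units <- split(case_unit, factor(case_loc, levels = seq_len(geom$L)))
  max_llr <- 0
  rows <- if (report) vector("list", sum(geom$K)) else NULL
  nrow_out <- 0L
  for (i in seq_len(geom$L)) {
    o <- geom$ord[[i]]
    ts <- NULL
    n_cases_zone <- 0L
    for (k in seq_len(geom$K[i])) {
      new <- loc_units[[o[k]]]
      if (length(new)) {
        ts <- c(ts, new)
        n_cases_zone <- n_cases_zone + length(new)
      }
      if (n_cases_zone < min_O) next
      best <- zone_best_interval(ts, geom$pop_frac[[i]][k], N, n_units,
                                 maxu, prospective, min_O)
      if (is.null(best)) next
      if (report) {
        nrow_out <- nrow_out + 1L
        rows[[nrow_out]] <- c(centre = i, k = k, O = best$O, E = best$E,
                              llr = best$llr, a = best$a, b = best$b)
      } else if (best$llr > max_llr) {
        max_llr <- best$llr
      }
    }
  }
  if (!report) return(max_llr)
  if (nrow_out == 0L) {
    return(data.frame(centre = integer(0), k = integer(0), O = integer(0),
                      E = numeric(0), llr = numeric(0), a = integer(0),
                      b = integer(0)))
  }
  as.data.frame(do.call(rbind, rows[seq_len(nrow_out)]))
}

#' Enumerate candidate space-time cylinders
#'
#' Materialises the full set of cylindrical windows the scan searches:
#' for each centre, nested spatial windows grown over nearest neighbours
#' up to the population cap, crossed with every temporal interval of at
#' most `t_max_days` (retrospective) or only intervals ending on the last
#' day (prospective). Intended for small problems and for verifying the
#' scan against direct enumeration; [scan_clusters()] never materialises
#' this set.
#'
#' @param locations A [location_table()].
#' @param period A [study_period()].
#' @param params A [scan_params()].
#' @return A data frame with one row per cylinder: `centre_location_id`,
#'   `radius_km`, `n_locations`, `members` (list column of location ids),
#'   `t_start`, `t_end`.
#' @export
enumerate_cylinders <- function(locations, period, params) {
  geom <- build_scan_geometry(locations, params)
  n_units <- period$n_units
  maxu <- min(max_temporal_units(params), n_units)
  if (params$mode == "prospective") {
    a <- (n_units - maxu + 1L):n_units
    b <- rep.int(n_units, length(a))
  } else {
    a <- integer(0); b <- integer(0)
    for (len in seq_len(maxu)) {
      a <- c(a, seq_len(n_units - len + 1L))
      b <- c(b, seq_len(n_units - len + 1L) + len - 1L)
    }
  }
  zones <- data.frame(
    centre = rep.int(seq_len(geom$L), geom$K),
    k = sequence(geom$K))
  idx_z <- rep(seq_len(nrow(zones)), each = length(a))
  idx_t <- rep(seq_along(a), times = nrow(zones))
  dates <- unit_to_dates(a[idx_t], b[idx_t], period)
  out <- data.frame(
    centre_location_id = geom$location_id[zones$centre[idx_z]],
    radius_km = mapply(function(c0, k) geom$radii[[c0]][k],
                       zones$centre[idx_z], zones$k[idx_z]),
    n_locations = zones$k[idx_z],
    t_start = dates$t_start,
    t_end = dates$t_end,
    stringsAsFactors = FALSE)
  out$members <- mapply(function(c0, k) geom$location_id[geom$ord[[c0]][seq_len(k)]],
                        zones$centre[idx_z], zones$k[idx_z], SIMPLIFY = FALSE)
  out
}

#' Run the space-time scan (no significance testing)
#'
#' Computes observed and expected counts and the Poisson log-likelihood
#' ratio over every candidate cylinder and reports the most likely
#' cluster plus geographically non-overlapping secondary clusters in
#' decreasing LLR order. Only windows with at least `min_cases` observed
#' cases and LLR > 0 are reported. Ties on LLR are broken by smaller
#' radius, earlier start, then centre id, so output is deterministic.
#'
#' Use [run_scan()] for the full pipeline including Monte-Carlo p-values.
#'
#' @param dataset A [scan_dataset()].
#' @param params A [scan_params()].
#' @return An object of class `scan_result`; its `$clusters` data frame
#'   has one row per reported cluster with columns `cluster`,
#'   `centre_location_id`, `radius_km`, `n_locations`, `t_start`,
#'   `t_end`, `duration_days`, `observed`, `expected`, `llr`,
#'   `relative_risk`, and a `members` list column.
#' @export
scan_clusters <- function(dataset, params = scan_params()) {
  stopifnot(inherits(dataset, "scan_dataset"), inherits(params, "scan_params"))
  period <- dataset$period
  if (period$aggregation_days != params$aggregation_days) {
    period <- study_period(period$start, period$end, params$aggregation_days)
  }
  geom <- build_scan_geometry(dataset$locations, params)
  N <- dataset$n_cases
  empty <- data.frame(
    cluster = integer(0), centre_location_id = character(0),
    radius_km = numeric(0), n_locations = integer(0),
    t_start = as.Date(character(0)), t_end = as.Date(character(0)),
    duration_days = integer(0), observed = integer(0), expected = numeric(0),
    llr = numeric(0), relative_risk = numeric(0), stringsAsFactors = FALSE)
  result <- structure(
    list(clusters = empty, params = params, period = period,
         n_cases = N, locations = dataset$locations,
         replicate_maxima = NULL),
    class = "scan_result")
  if (N == 0L) return(result)
  case_loc <- match(dataset$cases$location_id, dataset$locations$location_id)
  case_unit <- date_to_unit(dataset$cases$event_date, period)
  zb <- scan_zones(geom, case_loc, case_unit, period$n_units, N, params,
                   report = TRUE)
  if (nrow(zb) == 0L) return(result)
  zb$radius <- mapply(function(c0, k) geom$radii[[c0]][k], zb$centre, zb$k)
  zb$centre_id <- geom$location_id[zb$centre]
  zb <- zb[order(-zb$llr, zb$radius, zb$a, zb$centre_id), , drop = FALSE]
  taken <- rep(FALSE, geom$L)
  keep <- integer(0)
  members <- list()
  for (r in seq_len(nrow(zb))) {
    mem <- geom$ord[[zb$centre[r]]][seq_len(zb$k[r])]
    if (any(taken[mem])) next
    taken[mem] <- TRUE
    keep <- c(keep, r)
    members[[length(members) + 1L]] <- geom$location_id[mem]
  }
  zb <- zb[keep, , drop = FALSE]
  dates <- unit_to_dates(zb$a, zb$b, period)
  clusters <- data.frame(
    cluster = seq_len(nrow(zb)),
    centre_location_id = zb$centre_id,
    radius_km = zb$radius,
    n_locations = zb$k,
    t_start = dates$t_start,
    t_end = dates$t_end,
    duration_days = as.integer(dates$t_end - dates$t_start),
    observed = as.integer(zb$O),
    expected = zb$E,
    llr = zb$llr,
    relative_risk = ifelse(zb$O == N, Inf,
                           ifelse(zb$E > 0,
                                  (zb$O / zb$E) / ((N - zb$O) / (N - zb$E)),
                                  Inf)),
    stringsAsFactors = FALSE)
  clusters$members <- members
  result$clusters <- clusters
  result
}

#' @export
print.scan_result <- function(x, ...) {
  mode_lbl <- paste0(toupper(substr(x$params$mode, 1, 1)),
                     substring(x$params$mode, 2))
  cat(sprintf("%s space-time scan: %d cases, %d location(s), %s .. %s\n",
              mode_lbl, x$n_cases,
              nrow(x$locations), x$period$start, x$period$end))
  cl <- x$clusters
  if (nrow(cl) == 0L) {
    cat("No clusters reported.\n")
    return(invisible(x))
  }
  cat(sprintf("%d cluster(s) reported:\n", nrow(cl)))
  show <- data.frame(
    cluster = cl$cluster,
    start = fmt_date_slash(cl$t_start),
    end = fmt_date_slash(cl$t_end),
    duration = cl$duration_days,
    expected = round(cl$expected, 3),
    observed = cl$observed,
    llr = round(cl$llr, 3))
  if (!is.null(cl$p_value)) show$p_value = round(cl$p_value, 3)
  print(show, row.names = FALSE)
  invisible(x)
}
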