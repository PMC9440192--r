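# Shared fixtures and an independent brute-force oracle for the scan.

# Small deterministic location table: points strung along a line of
# longitude near Cork, explicit populations.
make_locations <- function(pops, lat0 = 51.9, lon0 = -8.5, step_deg = 0.05) {
  n <- length(pops)
  location_table(sprintf("SA%03d", seq_len(n)),
                 latitude = rep(lat0, n),
                 longitude = lon0 + step_deg * (seq_len(n) - 1),
                 population = pops)
}

make_cases <- function(location_id, dates) {
  n <- length(location_id)
  data.frame(case_id = sprintf("case%04d", seq_len(n)),
             location_id = location_id,
             event_date = as.Date(dates),
             gender = rep(NA_character_, n), age_years = rep(NA_real_, n),
             birth_date = as.Date(rep(NA_character_, n)),
             method = rep(NA_character_, n), stringsAsFactors = FALSE)
}

# Independent haversine (own closed form, not the package's path).
oracle_haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

oracle_llr <- function(O, E, N) {
  if (O <= E) return(0)
  t1 <- if (O > 0) O * log(O / E) else 0
  t2 <- if (N - O > 0) (N - O) * log((N - O) / (N - E)) else 0
  t1 + t2
}

# Brute-force scan oracle: enumerates every cylinder explicitly and
# recounts cases per cylinder directly. Returns the best cylinder under
# the same tie-break (LLR desc, radius, start, centre id) and the full
# cylinder table.
brute_scan <- function(dataset, params) {
  loc <- dataset$locations
  L <- nrow(loc)
  pop <- loc$population
  pop_total <- sum(pop)
  cap <- params$max_pop_fraction * pop_total
  start <- dataset$period$start
  n_units <- as.integer(dataset$period$end - start) + 1L
  maxu <- min(params$t_max_days, n_units)
  N <- dataset$n_cases
  case_loc <- dataset$cases$location_id
  case_unit <- as.integer(dataset$cases$event_date - start) + 1L
  rows <- list()
  for (ci in seq_len(L)) {
    d <- oracle_haversine_km(loc$latitude, loc$longitude,
                             loc$latitude[ci], loc$longitude[ci])
    o <- order(d, loc$location_id)
    cum <- cumsum(pop[o])
    K <- max(1L, sum(cum <= cap + 1e-9))
    for (k in seq_len(K)) {
      members <- loc$location_id[o[seq_len(k)]]
      pf <- cum[k] / pop_total
      in_zone <- case_loc %in% members
      ab <- if (params$mode == "prospective") {
        cbind(a = (n_units - maxu + 1L):n_units, b = n_units)
      } else {
        do.call(rbind, lapply(seq_len(n_units), function(a) {
          cbind(a = a, b = a:min(n_units, a + maxu - 1L))
        }))
      }
      for (r in seq_len(nrow(ab))) {
        a <- ab[r, "a"]; b <- ab[r, "b"]
        O <- sum(in_zone & case_unit >= a & case_unit <= b)
        E <- N * pf * (b - a + 1L) / n_units
        if (E <= 0 || E >= N) next
        llr <- oracle_llr(O, E, N)
        rows[[length(rows) + 1L]] <- data.frame(
          centre = loc$location_id[ci], radius = d[o[k]], k = k,
          a = a, b = b, O = O, E = E, llr = llr,
          stringsAsFactors = FALSE)
      }
    }
  }
  all <- do.call(rbind, rows)
  if (is.null(all)) {
    all <- data.frame(centre = character(0), radius = numeric(0),
                      k = integer(0), a = integer(0), b = integer(0),
                      O = integer(0), E = numeric(0), llr = numeric(0))
  }
  cand <- all[all$llr > 0 & all$O >= params$min_cases, , drop = FALSE]
  best <- if (nrow(cand)) {
    cand[order(-cand$llr, cand$radius, cand$a, cand$centre), , drop = FALSE][1L, ]
  } else {
    NULL
  }
  list(best = best, all = all)
}

# Random small instance for oracle-equivalence sweeps.
random_instance <- function(seed) {
  set.seed(seed)
  n_loc <- sample(2:6, 1)
  n_days <- sample(5:12, 1)
  locs <- location_table(
    sprintf("SA%03d", seq_len(n_loc)),
    latitude = round(runif(n_loc, 51.5, 52.5), 4),
    longitude = round(runif(n_loc, -9.5, -8.5), 4),
    population = sample(50:500, n_loc, replace = TRUE))
  period <- study_period("2021-03-01", as.Date("2021-03-01") + n_days - 1)
  n_cases <- sample(0:15, 1)
  cases <- make_cases(sample(locs$location_id, n_cases, replace = TRUE),
                      period$start + sample.int(n_days, n_cases, replace = TRUE) - 1L)
  scan_dataset(cases, locs, period)
}
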