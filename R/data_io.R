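#' Read a case file
#'
#' Two dialects are supported. The SaTScan-style dialect is
#' whitespace/comma delimited, headerless: `<location_id> <count> <date>`;
#' a row with count `k` expands to `k` individual case records. The CSV
#' dialect is headered and carries one case per row with optional
#' demographics; recognised columns are `case_id`, `location_id` (or
#' `location`), `event_date` (or `date`), `gender`, `age_years`,
#' `birth_date` and `method` — any further columns are kept as extra
#' attributes.
#'
#' @param path Path to the case file.
#' @param dialect `"satscan"` or `"csv"`.
#' @return A data frame of case records (one row per case) with at least
#'   `case_id`, `location_id`, `event_date` columns.
#' @examples
#' f <- tempfile()
#' writeLines(c("SA001 2 2011-09-15", "SA002 1 2011/10/01"), f)
#' read_case_file(f, "satscan")
#' @export
read_case_file <- function(path, dialect = c("satscan", "csv")) {
  if (!file.exists(path)) stop_vld("case file not found: %s", path)
  dialect <- match.arg(dialect)
  if (dialect == "satscan") {
    read_cases_satscan(path)
  } else {
    read_cases_csv(path)
  }
}

read_cases_satscan <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0L) {
    return(empty_cases())
  }
  parts <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  nf <- lengths(parts)
  bad <- keep[nf != 3L]
  if (length(bad)) {
    stop_vld("malformed case row (need <location_id> <count> <date>) at line %s of %s",
             paste(bad, collapse = ", "), path)
  }
  m <- do.call(rbind, parts)
  counts <- suppressWarnings(as.numeric(m[, 2L]))
  bad <- keep[is.na(counts) | counts != floor(counts)]
  if (length(bad)) {
    stop_vld("non-integer case count at line %s of %s",
             paste(bad, collapse = ", "), path)
  }
  bad <- keep[counts < 0]
  if (length(bad)) {
    stop_vld("negative case count at line %s of %s",
             paste(bad, collapse = ", "), path)
  }
  dates <- parse_scan_date(m[, 3L])
  bad <- keep[is.na(dates)]
  if (length(bad)) {
    stop_vld("unparseable date at line %s of %s",
             paste(bad, collapse = ", "), path)
  }
  idx <- rep.int(seq_along(keep), as.integer(counts))
  n <- length(idx)
  data.frame(
    case_id = if (n) sprintf("case%06d", seq_len(n)) else character(0),
    location_id = m[idx, 1L],
    event_date = dates[idx],
    gender = rep(NA_character_, n),
    age_years = rep(NA_real_, n),
    birth_date = as.Date(rep(NA_character_, n)),
    method = rep(NA_character_, n),
    stringsAsFactors = FALSE)
}

read_cases_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  names(df) <- tolower(names(df))
  loc_col <- intersect(c("location_id", "location", "loc"), names(df))[1]
  date_col <- intersect(c("event_date", "date"), names(df))[1]
  if (is.na(loc_col) || is.na(date_col)) {
    stop_vld("csv case file %s must name location and date columns in its header", path)
  }
  n <- nrow(df)
  if (n == 0L) return(empty_cases())
  dates <- parse_scan_date(df[[date_col]])
  if (anyNA(dates)) {
    stop_vld("unparseable date at line %s of %s (line 1 = header)",
             paste(which(is.na(dates)) + 1L, collapse = ", "), path)
  }
  ids <- if ("case_id" %in% names(df)) df$case_id else sprintf("case%06d", seq_len(n))
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))
    stop_vld("duplicate case_id '%s' at line %s of %s",
             ids[dup[1]], paste(dup + 1L, collapse = ", "), path)
  }
  age <- if ("age_years" %in% names(df)) suppressWarnings(as.numeric(df$age_years)) else rep(NA_real_, n)
  if (any(!is.na(age) & age < 0)) {
    stop_vld("negative age_years at line %s of %s",
             paste(which(!is.na(age) & age < 0) + 1L, collapse = ", "), path)
  }
  out <- data.frame(
    case_id = ids,
    location_id = df[[loc_col]],
    event_date = dates,
    gender = if ("gender" %in% names(df)) na_if_empty(df$gender) else rep(NA_character_, n),
    age_years = age,
    birth_date = if ("birth_date" %in% names(df)) parse_scan_date(df$birth_date) else as.Date(rep(NA_character_, n)),
    method = if ("method" %in% names(df)) na_if_empty(df$method) else rep(NA_character_, n),
    stringsAsFactors = FALSE)
  extra <- setdiff(names(df), c("case_id", loc_col, date_col, "gender",
                                "age_years", "birth_date", "method"))
  for (col in extra) out[[col]] <- df[[col]]
  out
}

na_if_empty <- function(x) {
  x <- as.character(x)
  x[!nzchar(trimws(x))] <- NA_character_
  x
}

empty_cases <- function() {
  data.frame(case_id = character(0), location_id = character(0),
             event_date = as.Date(character(0)), gender = character(0),
             age_years = numeric(0), birth_date = as.Date(character(0)),
             method = character(0), stringsAsFactors = FALSE)
}

#' Read and join the coordinates and population files
#'
#' The coordinates file gives one small-area centroid per row
#' (`<location_id> <lat> <lon>`), the population file the census count
#' (`<location_id> <year> <population>`; the year column is validated but
#' otherwise ignored — the count is treated as a single snapshot applied
#' uniformly over the study period). Headered CSV files with columns
#' `location_id`, `latitude`/`lat`, `longitude`/`lon` and `location_id`,
#' `population` are also accepted.
#'
#' @param geo_path Path to the coordinates file.
#' @param pop_path Path to the population file.
#' @param dialect `"satscan"` (headerless, whitespace/comma delimited) or
#'   `"csv"` (headered).
#' @return A `location_table` data frame with columns `location_id`,
#'   `latitude`, `longitude`, `population`.
#' @export
read_location_table <- function(geo_path, pop_path,
                                dialect = c("satscan", "csv")) {
  dialect <- match.arg(dialect)
  for (p in c(geo_path, pop_path)) {
    if (!file.exists(p)) stop_vld("file not found: %s", p)
  }
  if (dialect == "satscan") {
    geo <- read_delim_cols(geo_path, 3L, c("location_id", "latitude", "longitude"))
    pop <- read_delim_cols(pop_path, 3L, c("location_id", "year", "population"))
  } else {
    geo <- utils::read.csv(geo_path, stringsAsFactors = FALSE)
    names(geo) <- tolower(names(geo))
    names(geo)[names(geo) == "lat"] <- "latitude"
    names(geo)[names(geo) == "lon"] <- "longitude"
    pop <- utils::read.csv(pop_path, stringsAsFactors = FALSE)
    names(pop) <- tolower(names(pop))
  }
  location_table(geo$location_id, as.numeric(geo$latitude),
                 as.numeric(geo$longitude),
                 population = pop$population[match(geo$location_id, pop$location_id)],
                 pop_ids = pop$location_id)
}

read_delim_cols <- function(path, ncol, nms) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  parts <- strsplit(trimws(lines[keep]), "[,[:space:]]+")
  bad <- keep[lengths(parts) != ncol]
  if (length(bad)) {
    stop_vld("malformed row (need %d fields) at line %s of %s",
             ncol, paste(bad, collapse = ", "), path)
  }
  m <- do.call(rbind, parts)
  if (is.null(m)) m <- matrix(character(0), 0, ncol)
  stats::setNames(as.data.frame(m, stringsAsFactors = FALSE), nms)
}

#' Construct a validated location table
#'
#' @param location_id Unique small-area identifiers.
#' @param latitude,longitude WGS84 centroid coordinates in degrees.
#' @param population Non-negative census population counts.
#' @param pop_ids Internal: ids seen in the population file, for
#'   key-mismatch diagnostics.
#' @return A data frame of class `location_table`.
#' @export
location_table <- function(location_id, latitude, longitude, population,
                           pop_ids = NULL) {
  location_id <- as.character(location_id)
  if (anyDuplicated(location_id)) {
    stop_vld("duplicate location_id: %s",
             paste(unique(location_id[duplicated(location_id)]), collapse = ", "))
  }
  if (!is.null(pop_ids)) {
    pop_ids <- as.character(pop_ids)
    miss <- setdiff(location_id, pop_ids)
    if (length(miss)) {
      stop_vld("location(s) in coordinates file missing from population file: %s",
               paste(miss, collapse = ", "))
    }
    extra <- setdiff(pop_ids, location_id)
    if (length(extra)) {
      stop_vld("location(s) in population file missing from coordinates file: %s",
               paste(extra, collapse = ", "))
    }
  }
  latitude <- as.numeric(latitude)
  longitude <- as.numeric(longitude)
  if (any(is.na(latitude)) || any(abs(latitude) > 90)) {
    stop_vld("latitude out of range [-90, 90] for location(s): %s",
             paste(location_id[is.na(latitude) | abs(latitude) > 90], collapse = ", "))
  }
  if (any(is.na(longitude)) || any(abs(longitude) > 180)) {
    stop_vld("longitude out of range [-180, 180] for location(s): %s",
             paste(location_id[is.na(longitude) | abs(longitude) > 180], collapse = ", "))
  }
  population <- suppressWarnings(as.numeric(population))
  if (any(is.na(population) | population < 0)) {
    stop_vld("missing or negative population for location(s): %s",
             paste(location_id[is.na(population) | population < 0], collapse = ", "))
  }
  population <- as.integer(round(population))
  if (length(population) && sum(population) <= 0) {
    stop_vld("total population must be > 0")
  }
  structure(
    data.frame(location_id = location_id, latitude = latitude,
               longitude = longitude, population = population,
               stringsAsFactors = FALSE),
    class = c("location_table", "data.frame"))
}

#' Assemble a study dataset
#'
#' Binds case records, the location table and the study period into the
#' unit every scan operation consumes, after cross-validating them: every
#' case must reference a known location and fall inside the period.
#'
#' @param cases Case records as returned by [read_case_file()].
#' @param locations A [location_table()].
#' @param period A [study_period()].
#' @return An object of class `scan_dataset` with elements `cases`,
#'   `locations`, `period` and `n_cases`.
#' @export
scan_dataset <- function(cases, locations, period) {
  stopifnot(inherits(period, "study_period"))
  if (!inherits(locations, "location_table")) {
    locations <- location_table(locations$location_id, locations$latitude,
                                locations$longitude, locations$population)
  }
  unknown <- setdiff(unique(cases$location_id), locations$location_id)
  if (length(unknown)) {
    stop_vld("case location(s) not in location table: %s",
             paste(unknown, collapse = ", "))
  }
  if (nrow(cases)) {
    out_of_period <- cases$event_date < period$start | cases$event_date > period$end
    if (any(out_of_period)) {
      stop_vld("case(s) dated outside the study period: %s",
               paste(cases$case_id[out_of_period], collapse = ", "))
    }
    if (any(!is.na(cases$age_years) & cases$age_years < 0)) {
      stop_vld("negative age_years")
    }
  }
  structure(list(cases = cases, locations = locations, period = period,
                 n_cases = nrow(cases)),
            class = "scan_dataset")
}

#' @export
print.scan_dataset <- function(x, ...) {
  cat(sprintf("Space-time scan dataset: %d cases, %d locations (total population %s)\n",
              x$n_cases, nrow(x$locations),
              format(sum(x$locations$population), big.mark = ",")))
  print(x$period)
  invisible(x)
}

#' Write a dataset to disk
#'
#' Emits a case file, a coordinates file and a population file in the
#' chosen dialect, such that reading them back reproduces the dataset
#' (exactly for the CSV dialect; the SaTScan dialect aggregates cases to
#' per-location/day counts, so case ids and demographics are not carried).
#'
#' @param dataset A [scan_dataset()].
#' @param out_dir Output directory, created if needed.
#' @param dialect `"satscan"` or `"csv"`.
#' @return Invisibly, a named character vector of the paths written
#'   (`cases`, `geo`, `pop`).
#' @export
write_dataset <- function(dataset, out_dir, dialect = c("satscan", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(dataset, "scan_dataset"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  census_year <- format(dataset$period$start, "%Y")
  if (dialect == "satscan") {
    paths <- c(cases = file.path(out_dir, "cases.cas"),
               geo = file.path(out_dir, "locations.geo"),
               pop = file.path(out_dir, "population.pop"))
    cs <- dataset$cases
    if (nrow(cs)) {
      agg <- stats::aggregate(list(count = rep(1L, nrow(cs))),
                              by = list(location_id = cs$location_id,
                                        event_date = cs$event_date),
                              FUN = sum)
      agg <- agg[order(agg$location_id, agg$event_date), , drop = FALSE]
      writeLines(sprintf("%s %d %s", agg$location_id, agg$count,
                         format(agg$event_date, "%Y-%m-%d")), paths[["cases"]])
    } else {
      writeLines(character(0), paths[["cases"]])
    }
    loc <- dataset$locations
    # 17 significant digits: doubles round-trip exactly through the file
    writeLines(sprintf("%s %.17g %.17g", loc$location_id, loc$latitude,
                       loc$longitude), paths[["geo"]])
    writeLines(sprintf("%s %s %d", loc$location_id, census_year,
                       loc$population), paths[["pop"]])
  } else {
    paths <- c(cases = file.path(out_dir, "cases.csv"),
               geo = file.path(out_dir, "locations.csv"),
               pop = file.path(out_dir, "population.csv"))
    cs <- dataset$cases
    cs$event_date <- format(cs$event_date, "%Y-%m-%d")
    if ("birth_date" %in% names(cs)) {
      cs$birth_date <- ifelse(is.na(cs$birth_date), "",
                              format(cs$birth_date, "%Y-%m-%d"))
    }
    utils::write.csv(cs, paths[["cases"]], row.names = FALSE, na = "")
    loc <- as.data.frame(dataset$locations)
    geo <- data.frame(location_id = loc$location_id,
                      latitude = sprintf("%.17g", loc$latitude),
                      longitude = sprintf("%.17g", loc$longitude))
    utils::write.csv(geo, paths[["geo"]], row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(location_id = loc$location_id,
                                population = loc$population),
                     paths[["pop"]], row.names = FALSE)
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing the files.
#' @param period A [study_period()]; if `NULL`, the span of the case dates
#'   is used.
#' @param dialect `"satscan"` or `"csv"`.
#' @return A [scan_dataset()].
#' @export
read_dataset <- function(dir, period = NULL, dialect = c("satscan", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "satscan") {
    cases <- read_case_file(file.path(dir, "cases.cas"), "satscan")
    locations <- read_location_table(file.path(dir, "locations.geo"),
                                     file.path(dir, "population.pop"), "satscan")
  } else {
    cases <- read_case_file(file.path(dir, "cases.csv"), "csv")
    locations <- read_location_table(file.path(dir, "locations.csv"),
                                     file.path(dir, "population.csv"), "csv")
  }
  if (is.null(period)) {
    if (nrow(cases) == 0L) stop_vld("period must be given for an empty case file")
    period <- study_period(min(cases$event_date), max(cases$event_date))
  }
  scan_dataset(cases, locations, period)
}
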