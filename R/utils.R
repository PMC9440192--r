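# Internal helpers shared across modules.

#' @importFrom stats rpois rmultinom setNames
#' @importFrom utils read.csv write.csv read.table write.table
NULL

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library calls never perturb user simulations.
with_rng_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Strict date parser: accepts ISO-8601 (2011-09-15) and the slashed form
# used in SaTScan-era tables (2011/09/15). Returns Date, NA where invalid.
parse_scan_date <- function(x) {
  x <- trimws(as.character(x))
  out <- as.Date(rep(NA_character_, length(x)))
  iso <- grepl("^\\d{4}-\\d{1,2}-\\d{1,2}$", x)
  sla <- grepl("^\\d{4}/\\d{1,2}/\\d{1,2}$", x)
  out[iso] <- as.Date(x[iso], format = "%Y-%m-%d")
  out[sla] <- as.Date(x[sla], format = "%Y/%m/%d")
  # as.Date with a format silently rolls some impossible dates to NA but
  # accepts e.g. "2017-2-30" -> NA already; double-check round-trip so that
  # nothing like "2017-13-01" slips through on exotic platforms.
  ok <- !is.na(out)
  if (any(ok)) {
    rt <- format(out[ok], "%Y-%m-%d")
    norm <- gsub("/", "-", x[ok])
    norm <- vapply(strsplit(norm, "-"), function(p) {
      sprintf("%04d-%02d-%02d", as.integer(p[1]), as.integer(p[2]), as.integer(p[3]))
    }, character(1))
    out[ok][rt != norm] <- as.Date(NA)
  }
  out
}

fmt_date_slash <- function(d) format(d, "%Y/%m/%d")

stop_vld <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
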