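#' Simulate null replicate maxima
#'
#' Conditional Monte-Carlo null: the `N` observed cases are redistributed
#' over all location x time-unit cells by a single multinomial draw with
#' probabilities proportional to the null expectations (population share
#' x uniform time), then the same cylinder set is scanned and the maximum
#' LLR recorded. Repeated `n_replications` times under one RNG stream
#' seeded from `seed`, so results are fully reproducible.
#'
#' @param dataset A [scan_dataset()].
#' @param params A [scan_params()]; `mode`, windows and the cylinder set
#'   match the observed scan.
#' @param n_replications Number of replicates (defaults to
#'   `params$n_replications`).
#' @param seed Master seed (defaults to `params$seed`).
#' @return Numeric vector of replicate maximum LLRs, length
#'   `n_replications`.
#' @export
simulate_null_maxima <- function(dataset, params = scan_params(),
                                 n_replications = params$n_replications,
                                 seed = params$seed) {
  stopifnot(inherits(dataset, "scan_dataset"))
  period <- dataset$period
  if (period$aggregation_days != params$aggregation_days) {
    period <- study_period(period$start, period$end, params$aggregation_days)
  }
  geom <- build_scan_geometry(dataset$locations, params)
  null_maxima(geom, period, dataset$n_cases, params, n_replications, seed)
}

# Shared worker: draws all replicates under one RNG stream and scans each
# with the same cylinder set as the observed data. Replicates are batched:
# zone-by-time count matrices for a whole chunk are formed with one matrix
# product, cumulated over time, and differenced into every temporal
# interval at once, so the per-replicate cost is a few dense vector ops.
null_maxima <- function(geom, period, N, params, R, seed) {
  R <- as.integer(R)
  if (R == 0L) return(numeric(0))
  n_units <- period$n_units
  maxima <- numeric(R)
  if (N == 0L) return(maxima)
  # cell probabilities: population share x uniform over time units;
  # cells are laid out location-fastest (column-major L x n_units)
  prob <- rep(geom$loc_pop_frac / n_units, times = n_units)
  maxu <- min(max_temporal_units(params), n_units)

  # zone membership matrix (n_zones x L) and per-zone population shares
  n_zones <- sum(geom$K)
  Z <- matrix(0, n_zones, geom$L)
  pf <- numeric(n_zones)
  z <- 0L
  for (i in seq_len(geom$L)) {
    for (k in seq_len(geom$K[i])) {
      z <- z + 1L
      Z[z, geom$ord[[i]][seq_len(k)]] <- 1
      pf[z] <- geom$pop_frac[[i]][k]
    }
  }
  # For the replicate MAXIMUM only the largest window count per (zone,
  # window length) matters: E is fixed given zone and length, and the
  # one-sided LLR is non-decreasing in O. So per chunk we keep a sliding
  # window-sum matrix and reduce it to per-length row maxima.
  E_len <- outer(pf, seq_len(maxu) / n_units) * N   # n_zones x maxu
  chunk <- max(1L, min(R, as.integer(4e6 %/% max(1L, n_zones * n_units))))
  done <- 0L
  row_max <- function(m) {
    if (ncol(m) == 1L) return(m[, 1L])
    j <- max.col(m, ties.method = "first")
    m[cbind(seq_len(nrow(m)), j)]
  }
  with_rng_seed(seed, {
    while (done < R) {
      nrep <- min(chunk, R - done)
      draws <- stats::rmultinom(nrep, N, prob)       # (L*n_units) x nrep
      flat <- matrix(as.vector(draws), nrow = geom$L) # L x (n_units*nrep)
      zc <- Z %*% flat                               # zone-time counts
      # reorder to (zone, rep) rows x time-unit columns
      arr <- aperm(array(zc, c(n_zones, n_units, nrep)), c(1, 3, 2))
      M <- matrix(arr, n_zones * nrep, n_units)
      nr <- nrow(M)
      mxO <- matrix(0, nr, maxu)
      if (params$mode == "prospective") {
        # windows anchored at the final unit: O(len) = sum of last len units
        acc <- numeric(nr)
        for (len in seq_len(maxu)) {
          acc <- acc + M[, n_units - len + 1L]
          mxO[, len] <- acc
        }
      } else {
        O_cur <- M
        mxO[, 1L] <- row_max(O_cur)
        for (len in seq.int(2L, length.out = maxu - 1L)) {
          nc <- n_units - len + 1L
          O_cur <- O_cur[, seq_len(nc), drop = FALSE] +
            M[, len:n_units, drop = FALSE]
          mxO[, len] <- row_max(O_cur)
        }
      }
      Ebig <- E_len[rep.int(seq_len(n_zones), nrep), , drop = FALSE]
      llr <- matrix(0, nr, maxu)
      W <- which(mxO > Ebig)
      if (length(W)) {
        Ow <- mxO[W]; Ew <- Ebig[W]; nn <- N - Ow
        v <- Ow * log(Ow / Ew)
        pos <- nn > 0
        v[pos] <- v[pos] + nn[pos] * log(nn[pos] / (N - Ew[pos]))
        llr[W] <- v
      }
      maxima[done + seq_len(nrep)] <-
        apply(matrix(row_max(llr), n_zones, nrep), 2, max)
      done <- done + nrep
    }
  })
  maxima
}

#' Monte-Carlo rank p-value
#'
#' `p = rank / (R + 1)` where `rank = 1 + #\{replicate maxima >=
#' observed\}`. With `R = 999` the attainable p-values are `0.001, 0.002,
#' ..., 1.000`.
#'
#' @param observed_llr Observed test statistic(s).
#' @param replicate_maxima Vector of `R` null replicate maximum LLRs.
#' @return p-value(s) on the grid `k/(R+1)`.
#' @examples
#' monte_carlo_p(10, rep(1, 999)) # 0.001
#' @export
monte_carlo_p <- function(observed_llr, replicate_maxima) {
  R <- length(replicate_maxima)
  if (R == 0L) stop_vld("p-value undefined with 0 Monte-Carlo replications")
  vapply(observed_llr,
         function(l) (1 + sum(replicate_maxima >= l)) / (R + 1),
         numeric(1))
}

#' Attach Monte-Carlo p-values to scan results
#'
#' Every reported cluster (most likely and secondaries) is referenced
#' against the same distribution of replicate maxima — the standard
#' most-likely-cluster reference, conservative for secondary clusters.
#' Adds `p_value`, `significant` (`p < alpha`) and `recurrence` (`1/p`,
#' in analysis periods) columns.
#'
#' @param result A `scan_result` from [scan_clusters()].
#' @param replicate_maxima From [simulate_null_maxima()].
#' @param alpha Significance level (defaults to the scan's).
#' @return The `scan_result`, with p-value columns and the replicate
#'   maxima stored in `$replicate_maxima`.
#' @export
attach_pvalues <- function(result, replicate_maxima,
                           alpha = result$params$alpha) {
  stopifnot(inherits(result, "scan_result"))
  cl <- result$clusters
  if (nrow(cl)) {
    cl$p_value <- monte_carlo_p(cl$llr, replicate_maxima)
    cl$significant <- cl$p_value < alpha
    cl$recurrence <- 1 / cl$p_value
  } else {
    cl$p_value <- numeric(0)
    cl$significant <- logical(0)
    cl$recurrence <- numeric(0)
  }
  result$clusters <- cl
  result$replicate_maxima <- replicate_maxima
  result
}

#' Full scan pipeline: detection plus significance
#'
#' Runs [scan_clusters()] and, when `params$n_replications > 0`,
#' [simulate_null_maxima()] and [attach_pvalues()].
#'
#' @inheritParams scan_clusters
#' @return A `scan_result` with p-values attached.
#' @export
run_scan <- function(dataset, params = scan_params()) {
  result <- scan_clusters(dataset, params)
  if (params$n_replications > 0L && nrow(result$clusters)) {
    maxima <- simulate_null_maxima(dataset, params)
    result <- attach_pvalues(result, maxima)
  }
  result
}
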