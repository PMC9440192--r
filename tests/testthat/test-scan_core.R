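test_that("great-circle distance is a haversine on a 6371 km sphere", {
  expect_equal(great_circle_km(51.9, -8.5, 51.9, -8.5), 0)
  d1 <- great_circle_km(51.8985, -8.4756, 53.3498, -6.2603)
  d2 <- great_circle_km(53.3498, -6.2603, 51.8985, -8.4756)
  expect_equal(d1, d2)                       # symmetry
  expect_equal(d1, oracle_haversine_km(51.8985, -8.4756, 53.3498, -6.2603),
               tolerance = 1e-9)
  expect_equal(d1, 220, tolerance = 0.01)    # Cork - Dublin, ~220 km
  expect_error(great_circle_km(91, 0, 0, 0), "latitude")
})

test_that("expected counts are population-proportional and conserve N", {
  locs <- make_locations(c(100, 300))
  period <- study_period("2020-01-01", "2020-01-10")
  surf <- expected_counts(locs, period, 8)
  m <- as.matrix(surf)
  expect_equal(unname(m["SA001", 1]), 8 * (100 / 400) * (1 / 10))
  expect_equal(sum(m), 8)
  locs0 <- make_locations(c(0, 300))
  m0 <- as.matrix(expected_counts(locs0, period, 8))
  expect_true(all(m0["SA001", ] == 0))
  # conservation across random shapes
  for (seed in 1:5) {
    set.seed(seed)
    locs_r <- make_locations(sample(0:500, 4))
    n_units <- sample(3:40, 1)
    N <- sample(0:300, 1)
    s <- expected_counts(locs_r, study_period("2020-01-01",
                                              as.Date("2020-01-01") + n_units - 1), N)
    expect_equal(sum(as.matrix(s)), N)
  }
})

test_that("Poisson LLR matches direct evaluation and its boundary rules", {
  expect_equal(poisson_llr(10, 2, 10), 10 * log(5))  # 0 log 0 := 0 at O = N
  expect_equal(poisson_llr(5, 5, 100), 0)            # null boundary O = E
  expect_equal(poisson_llr(2, 4, 100), 0)            # one-sided: low rate -> 0
  O <- 7; E <- 1.3; N <- 50
  expect_equal(poisson_llr(O, E, N), oracle_llr(O, E, N))
  expect_error(poisson_llr(3, 0, 388), "E must")
  expect_error(poisson_llr(3, 388, 388), "E must")
  expect_error(poisson_llr(400, 1, 388), "O must")
})

test_that("relative risk is the inside/outside rate ratio", {
  expect_equal(relative_risk(3, 0.103, 388), (3 / 0.103) / (385 / 387.897))
  expect_equal(relative_risk(5, 5, 100), 1)
  expect_equal(relative_risk(10, 2, 10), Inf)
})

test_that("cylinder enumeration: temporal windows, modes, population cap", {
  locs1 <- make_locations(100)
  period3 <- study_period("2020-01-01", "2020-01-03")
  retro <- enumerate_cylinders(locs1, period3, scan_params(t_max_days = 30))
  expect_equal(nrow(retro), 6L)  # [1,1],[2,2],[3,3],[1,2],[2,3],[1,3]
  prosp <- enumerate_cylinders(locs1, period3,
                               scan_params(mode = "prospective", t_max_days = 30))
  expect_equal(nrow(prosp), 3L)
  expect_true(all(prosp$t_end == period3$end))

  # equal-population pair, cap 0.5: no window contains both locations
  locs2 <- make_locations(c(200, 200))
  cyl <- enumerate_cylinders(locs2, period3, scan_params(max_pop_fraction = 0.5))
  expect_true(all(vapply(cyl$members, length, integer(1)) == 1L))

  # every member lies within the stated radius of the centre
  locs5 <- make_locations(c(50, 80, 120, 60, 90))
  cyl5 <- enumerate_cylinders(locs5, study_period("2020-01-01", "2020-01-05"),
                              scan_params())
  for (r in sample(nrow(cyl5), 20)) {
    ci <- match(cyl5$centre_location_id[r], locs5$location_id)
    mi <- match(cyl5$members[[r]], locs5$location_id)
    d <- great_circle_km(locs5$latitude[mi], locs5$longitude[mi],
                         locs5$latitude[ci], locs5$longitude[ci])
    expect_true(all(d <= cyl5$radius_km[r] + 1e-9))
  }
})

test_that("scan recovers a planted excess on a flat background", {
  locs <- make_locations(c(100, 100, 100, 100))
  period <- study_period("2020-01-01", "2020-03-31")
  # sparse background plus 6 cases at SA002 in one week
  bg <- make_cases(c("SA001", "SA003", "SA004", "SA001"),
                   c("2020-01-10", "2020-02-05", "2020-03-20", "2020-02-25"))
  burst <- make_cases(rep("SA002", 6),
                      as.Date("2020-02-10") + c(0, 1, 2, 4, 5, 6))
  burst$case_id <- paste0("b", seq_len(6))
  ds <- scan_dataset(rbind(bg, burst), locs, period)
  res <- scan_clusters(ds, scan_params(t_max_days = 30))
  top <- res$clusters[1, ]
  expect_true("SA002" %in% top$members[[1]])
  expect_true(top$t_start <= as.Date("2020-02-10") &&
                top$t_end >= as.Date("2020-02-16"))
  expect_equal(top$observed, 6L)
})

test_that("a single case is never reported under the min-case rule", {
  locs <- make_locations(c(100, 100))
  ds <- scan_dataset(make_cases("SA001", "2020-01-05"), locs,
                     study_period("2020-01-01", "2020-01-31"))
  res <- scan_clusters(ds, scan_params(min_cases = 2))
  expect_equal(nrow(res$clusters), 0L)
  # and an empty dataset scans to an empty result, not an error
  ds0 <- scan_dataset(make_cases(character(0), character(0)), locs,
                      study_period("2020-01-01", "2020-01-31"))
  expect_equal(nrow(scan_clusters(ds0, scan_params())$clusters), 0L)
})

test_that("most-likely cluster equals the brute-force oracle on random instances", {
  for (seed in 1:50) {
    ds <- random_instance(seed)
    params <- scan_params(mode = if (seed %% 2) "retrospective" else "prospective",
                          t_max_days = sample(c(3, 7, 30), 1),
                          min_cases = sample(1:2, 1),
                          n_replications = 0)
    res <- scan_clusters(ds, params)
    oracle <- brute_scan(ds, params)
    if (is.null(oracle$best)) {
      expect_equal(nrow(res$clusters), 0L, info = paste("seed", seed))
    } else {
      expect_gt(nrow(res$clusters), 0)
      top <- res$clusters[1, ]
      expect_equal(top$observed, oracle$best$O, info = paste("seed", seed))
      expect_equal(top$expected, oracle$best$E, tolerance = 1e-12,
                   info = paste("seed", seed))
      expect_equal(top$llr, oracle$best$llr, tolerance = 1e-12,
                   info = paste("seed", seed))
      expect_equal(top$centre_location_id, oracle$best$centre,
                   info = paste("seed", seed))
    }
  }
})

test_that("reported secondary clusters are pairwise location-disjoint", {
  for (seed in c(3, 8, 21)) {
    cfg <- synthetic_config(n_locations = 10, start = "2020-01-01",
                            end = "2020-04-30", expected_total_cases = 40,
                            seed = seed)
    res <- scan_clusters(generate_synthetic(cfg),
                         scan_params(t_max_days = 14, min_cases = 2))
    cl <- res$clusters
    if (nrow(cl) > 1) {
      for (i in seq_len(nrow(cl) - 1)) {
        for (j in (i + 1):nrow(cl)) {
          expect_length(intersect(cl$members[[i]], cl$members[[j]]), 0)
        }
      }
    }
    expect_true(all(cl$observed > cl$expected))  # high-rate windows only
    expect_true(all(diff(cl$llr) <= 1e-12))      # decreasing LLR order
  }
})

test_that("adding a case inside the most-likely cylinder never lowers its LLR", {
  for (seed in c(2, 5, 9)) {
    ds <- random_instance(seed)
    if (ds$n_cases < 2) next
    res <- scan_clusters(ds, scan_params(min_cases = 2, t_max_days = 7))
    if (nrow(res$clusters) == 0) next
    top <- res$clusters[1, ]
    extra <- make_cases(top$members[[1]][1], top$t_start)
    extra$case_id <- "extra1"
    ds2 <- scan_dataset(rbind(ds$cases, extra), ds$locations, ds$period)
    res2 <- scan_clusters(ds2, scan_params(min_cases = 2, t_max_days = 7))
    expect_gte(res2$clusters$llr[1], top$llr - 1e-12)
  }
})

test_that("prospective results are the retrospective cylinders ending on the final day", {
  for (seed in c(4, 13)) {
    ds <- random_instance(seed)
    pr <- scan_params(mode = "prospective", t_max_days = 7, min_cases = 1)
    res_p <- scan_clusters(ds, pr)
    oracle <- brute_scan(ds, scan_params(t_max_days = 7, min_cases = 1))
    n_units <- as.integer(ds$period$end - ds$period$start) + 1L
    act <- oracle$all[oracle$all$b == n_units & oracle$all$llr > 0 &
                        oracle$all$O >= 1, , drop = FALSE]
    if (nrow(res_p$clusters)) {
      expect_true(all(res_p$clusters$t_end == ds$period$end))
      best <- act[order(-act$llr, act$radius, act$a, act$centre), ][1, ]
      expect_equal(res_p$clusters$llr[1], best$llr, tolerance = 1e-12)
    } else {
      expect_true(nrow(act) == 0)
    }
  }
})
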