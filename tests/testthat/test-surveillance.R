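test_that("a one-date schedule reproduces a single prospective scan", {
  ds <- generate_synthetic(synthetic_config(
    n_locations = 6, start = "2020-01-01", end = "2020-02-29",
    expected_total_cases = 20, seed = 8))
  params <- scan_params(mode = "prospective", t_max_days = 14,
                        n_replications = 99, seed = 10)
  sched <- analysis_schedule("daily", "2020-02-29", "2020-02-29")
  tl <- prospective_replay(ds, params, sched)
  expect_equal(nrow(tl$analyses), 1L)
  params1 <- params
  params1$seed <- params$seed + 1L  # replay seeds per analysis index
  direct <- run_scan(ds, params1)
  expect_equal(tl$analyses$n_clusters, nrow(direct$clusters))
  if (nrow(direct$clusters)) {
    expect_equal(tl$clusters$llr, direct$clusters$llr)
    expect_equal(tl$clusters$p_value, direct$clusters$p_value)
  }
})

test_that("replay is causal and clusters stay active on their analysis date", {
  ds <- generate_synthetic(synthetic_config(
    n_locations = 6, start = "2020-01-01", end = "2020-03-31",
    expected_total_cases = 30, seed = 21))
  params <- scan_params(mode = "prospective", t_max_days = 14,
                        n_replications = 49, seed = 4)
  sched <- analysis_schedule("weekly", "2020-02-01", "2020-03-28")
  tl <- prospective_replay(ds, params, sched)
  for (i in seq_len(nrow(tl$analyses))) {
    d <- tl$analyses$analysis_date[i]
    expect_equal(tl$analyses$n_cases_seen[i], sum(ds$cases$event_date <= d))
  }
  if (!is.null(tl$clusters)) {
    expect_true(all(tl$clusters$t_end == tl$clusters$analysis_date))
  }
  expect_true(all(tl$analyses$alarm %in% c(TRUE, FALSE)))
})

test_that("a strong planted cluster ending at an analysis date raises an alarm", {
  locs <- make_locations(c(150, 150, 150, 150, 150, 150))
  period <- study_period("2020-01-01", "2020-03-31")
  bg <- make_cases(c("SA003", "SA005", "SA006"),
                   c("2020-01-15", "2020-02-01", "2020-02-20"))
  burst <- make_cases(rep("SA001", 8), as.Date("2020-03-10") + c(0, 0, 1, 2, 2, 3, 4, 5))
  burst$case_id <- paste0("b", 1:8)
  ds <- scan_dataset(rbind(bg, burst), locs, period)
  params <- scan_params(mode = "prospective", t_max_days = 14,
                        n_replications = 999, seed = 2)
  sched <- analysis_schedule("daily", "2020-03-08", "2020-03-20")
  tl <- prospective_replay(ds, params, sched)
  a <- tl$analyses
  # no alarm before the burst has 2 cases; alarm soon after it builds
  expect_false(any(a$alarm[a$analysis_date < as.Date("2020-03-10")]))
  expect_true(any(a$alarm[a$analysis_date >= as.Date("2020-03-12")]))
  first_alarm <- min(a$analysis_date[a$alarm])
  seen <- sum(ds$cases$location_id == "SA001" &
                ds$cases$event_date <= first_alarm)
  expect_gte(seen, params$min_cases)
})

test_that("the timeline flattens clusters chronologically with day durations", {
  fixture <- system.file("extdata", "cork_clusters_2008_2017.csv",
                         package = "stscan")
  tab <- read.csv(fixture)
  cl <- data.frame(
    t_start = as.Date(tab$start_date, format = "%Y/%m/%d"),
    t_end = as.Date(tab$end_date, format = "%Y/%m/%d"),
    observed = tab$observed, expected = tab$expected,
    relative_risk = NA_real_, p_value = tab$p_value,
    significant = tab$p_value < 0.05)
  tl <- build_cluster_timeline(cl)
  expect_equal(nrow(tl), 12L)
  expect_equal(min(tl$start_date), as.Date("2008-09-25"))
  expect_equal(max(tl$end_date), as.Date("2015-11-02"))
  expect_true(!is.unsorted(tl$start_date))
  # duration = end - start in days, including the same-day record
  expect_equal(tl$duration_days, as.integer(tl$end_date - tl$start_date))
  expect_true(any(tl$duration_days == 0))
  # csv export round-trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_timeline_csv(tl, f)
  back <- read.csv(f)
  expect_equal(back$duration_days, tl$duration_days)
  expect_equal(nrow(build_cluster_timeline(NULL)), 0L)
})

test_that("time to detection shrinks as the planted relative risk grows", {
  detect_day <- function(rr, seed) {
    cfg <- synthetic_config(
      n_locations = 8, start = "2020-01-01", end = "2020-03-31",
      expected_total_cases = 20,
      planted_clusters = list(list(centre_location = 1, n_locations = 3,
                                   t_start = "2020-03-01", t_end = "2020-03-14",
                                   relative_risk = rr)),
      seed = seed)
    ds <- generate_synthetic(cfg)
    sched <- analysis_schedule("daily", "2020-03-02", "2020-03-21")
    tl <- prospective_replay(ds, scan_params(mode = "prospective",
                                             t_max_days = 21,
                                             n_replications = 199, seed = seed),
                             sched)
    alarms <- tl$analyses$analysis_date[tl$analyses$alarm]
    if (length(alarms)) as.integer(min(alarms) - as.Date("2020-03-01")) else 99L
  }
  seeds <- 1:6
  weak <- vapply(seeds, function(s) detect_day(5, s), integer(1))
  strong <- vapply(seeds, function(s) detect_day(40, s), integer(1))
  expect_lte(mean(strong), mean(weak))
})
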