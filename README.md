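# stscan — space-time scan statistics for suicide cluster surveillance

`stscan` detects space-time clusters of point-referenced health events.
It was built for real-time surveillance of suspected suicide at
small-area resolution, where the operational question is: *is there a
community, right now or in the recent past, with more deaths close
together in space and time than its population share can explain?*

The engine is the cylindrical space-time scan statistic under a
discrete Poisson model. Candidate clusters are cylinders: a circular
spatial window centred on a small-area centroid (grown over nearest
neighbours up to a population cap), extruded over a time interval of at
most `t_max_days`. For a window with observed count *O* and
population-proportional null expectation *E*, conditional on the total
case count *N*, the one-sided test statistic is the Poisson
log-likelihood ratio

```
LLR = O log(O/E) + (N − O) log((N − O)/(N − E))   if O > E, else 0
```

and the reported effect size is the relative risk
`RR = (O/E) / ((N−O)/(N−E))`. The most likely cluster is the
LLR-maximising cylinder; secondary clusters follow in decreasing LLR
with no geographic overlap. Significance comes from conditional Monte
Carlo: the N cases are redistributed proportional to population
(uniform in time), the same cylinder family rescanned, and
`p = rank/(R+1)` computed from the replicate maxima (smallest attainable
p with the default R = 999 is 0.001).

Two modes: **retrospective** (all windows anywhere in the study period)
and **prospective** (only windows ending on the final day — "active"
clusters), plus a **surveillance replay** that re-runs the prospective
scan on a daily/weekly/monthly/yearly schedule over a historical case
stream and emits an alarm timeline. A seeded synthetic-data generator
(heterogeneous small-area populations, population-proportional Poisson
background, planted cylindrical clusters with chosen relative risk)
supports calibration and power studies when real case data are
restricted. Dashboard-ready outputs: Table-style cluster listings,
chronological timelines, GeoJSON cluster maps, and gender / age-group /
method-of-death breakdown tables.

## Worked example

Simulate six months of county-scale surveillance data with a planted
cluster (relative risk 15 over 3 small areas for two weeks), scan it
retrospectively, and compare the top cluster against the planted truth:

```r
library(stscan)

cfg <- synthetic_config(
  n_locations = 20, start = "2017-01-01", end = "2017-06-30",
  expected_total_cases = 25,
  planted_clusters = list(list(centre_location = 7, n_locations = 3,
                               t_start = "2017-05-20", t_end = "2017-06-02",
                               relative_risk = 15)),
  seed = 2026)
ds <- generate_synthetic(cfg)

res <- run_scan(ds, scan_params(t_max_days = 30, n_replications = 999, seed = 1))
print(res)

ov <- plant_truth_overlap(res$clusters[1, ], attr(ds, "truth")[[1]])
cat(sprintf("spatial Jaccard vs planted truth: %.2f\n", ov$spatial_jaccard))
```

```
Retrospective space-time scan: 23 cases, 20 location(s), 2017-01-01 .. 2017-06-30
4 cluster(s) reported:
 cluster      start        end duration expected observed    llr p_value
       1 2017/05/20 2017/06/07       18    0.411        7 14.331   0.003
       2 2017/06/09 2017/06/10        1    0.032        2  6.360   0.830
       3 2017/06/25 2017/06/30        5    0.184        2  3.033   1.000
       4 2017/04/26 2017/05/23       27    0.307        2  2.123   1.000
spatial Jaccard vs planted truth: 1.00
```

Reading the top row: between 2017/05/20 and 2017/06/07 (duration 18
days) the window observed 7 cases where the null expected 0.411; the
test statistic 14.331 exceeded the maximum of 997 of the 999 null
replicates, so p = 3/1000 = 0.003 — a significant active cluster, and
exactly the planted member areas (Jaccard 1.00). The remaining rows are
routine non-significant pairs of nearby cases, which is what a
well-calibrated scan reports on mostly-null data.

The same pipeline is scriptable from a shell via the installed `stscan`
executable (`stscan simulate | scan | surveil | summarize`); every run
writes a `manifest.json` echoing all effective parameters and the seed.

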