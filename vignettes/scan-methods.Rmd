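---
title: "Space-time scan statistics for suicide cluster surveillance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Space-time scan statistics for suicide cluster surveillance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stscan)
```

## The problem

Suicide clusters — unusual aggregations of deaths close together in both
space and time — are rare, small, and consequential: detecting one early
can trigger a community-level postvention response. A real-time
surveillance system therefore needs a statistic that (i) scans all
locations and all recent time windows without pre-specifying where or
when a cluster might occur, (ii) adjusts for the fact that more people
live in some small areas than others, and (iii) controls the multiple
testing implied by evaluating millions of candidate windows. The
space-time scan statistic under a discrete Poisson model is the standard
tool for exactly this situation, and `stscan` implements it natively in
R for both retrospective analysis of a historical case series and
prospective, periodically repeated surveillance.

## The model and the statistic

Cases are point events with a small-area location id and an event date.
Each small area has a census population count, treated as a single
snapshot applied uniformly over the study period — intercensal drift in
the spatial distribution of the population is a known, accepted
approximation at this scale. Under the null hypothesis the count in cell
$(i, t)$ (location $i$, time unit $t$) is Poisson with mean proportional
to the population of $i$ and constant over time. Conditioning on the
observed total $N$, the null expectation of a cell is

$$\mu_{it} = N \cdot \frac{\mathrm{pop}_i}{\mathrm{pop}_+} \cdot \frac{1}{T},$$

with $T$ the number of aggregated time units; expectations sum to $N$
exactly (`expected_counts()`).

Candidate clusters are *cylinders*: a circular spatial base centred on a
location, extruded over a time interval. For a window with observed
count $O$ and expectation $E$, the one-sided (high-rate) Poisson
log-likelihood ratio is

$$\Lambda = O \log\frac{O}{E} + (N - O)\log\frac{N - O}{N - E}
\quad \text{if } O > E, \text{ else } 0,$$

with the convention $0 \log 0 = 0$ so a window containing every case is
finite (`poisson_llr()`). The reported effect size is the relative risk
$RR = (O/E) \,/\, ((N-O)/(N-E))$, the estimated rate ratio inside versus
outside the window, $\infty$ when all cases fall inside.

The *most likely cluster* is the cylinder maximising $\Lambda$.
Secondary clusters are reported in decreasing $\Lambda$ subject to no
geographic overlap (no shared member location) with any better-ranked
cluster; temporal overlap is allowed, since two waves in different
communities may well overlap in time. Exact ties are broken by smaller
radius, then earlier start, then centre id, making output fully
deterministic.

## The window family

Spatial windows at each centre are the nested sets obtained by absorbing
locations in order of centroid distance (haversine on a 6371 km sphere;
ties by location id), stopping when the window would exceed a fraction
$\rho_{\max}$ (default 0.5) of the total population at risk. For
point-referenced data this finite family realises a circle of
continuously varying radius exactly. One deliberate exception to the
population cap: the degenerate centre-only window is always scanned, so
that purely temporal scanning remains possible even when a single
location holds most of the population (and a one-location geometry still
has a well-defined scan).

Temporal windows are every aggregated interval of length 1 to
$T_{\max}$ (default 30 days on one-day aggregation — the windowing used
for non-communicable-event surveillance of this kind) in retrospective
mode; in prospective mode only intervals ending on the final day are
scanned, which is what makes a cluster "active" and the mode suitable
for repeated surveillance. Reported clusters must contain at least
`min_cases` cases (default 2). The duration of a reported cluster is
`end - start` in days, so a same-day cluster has duration 0.

## Inference

Significance is assessed by conditional Monte Carlo
(`simulate_null_maxima()`): the $N$ cases are redistributed over all
location-time cells by a single multinomial draw with probabilities
$\mu_{it}/N$ (a Poisson process conditioned on its total), the identical
cylinder family is rescanned, and the replicate's maximum $\Lambda$
recorded. With $R$ replicates (default 999) the Monte-Carlo rank p-value
is $p = \mathrm{rank}/(R+1)$, so the attainable p-values are
$\{0.001, \ldots, 1.000\}$ and the smallest is 0.001. Every reported
cluster — most likely and secondary — is referenced against the same
replicate-maximum distribution, the standard convention; this is
conservative for secondary clusters. A recurrence-interval column
($1/p$, in analysis periods) is emitted for surveillance users; no
multiplicity adjustment is applied across repeated prospective analyses,
matching the plain $p < \alpha$ alarm rule the tool is designed to
emulate.

All replicates are drawn from one RNG stream seeded by `seed`, in a
single deterministic sequence of multinomial draws; the computation is
single-threaded, so no per-replicate seed offsets are needed for
reproducibility. In surveillance replay each analysis date $d$ gets seed
`seed + analysis index`, so truncating or extending a schedule never
changes the results of the analyses it shares with another run.

### Implementation notes

The observed scan never materialises the full cylinder-by-interval
table. For a fixed window and count $O$, shrinking the interval strictly
decreases $E$ and so strictly increases $\Lambda$; an optimal window
therefore spans from one case date to another (or ends on the final day,
prospectively), and the per-zone search enumerates only case-anchored
intervals. The Monte-Carlo engine exploits a second monotonicity: for a
fixed zone and window *length*, $E$ is constant, so only the maximum
window count over start positions matters; replicates are processed in
batches with dense matrix products (zone membership times cell counts)
and sliding-window maxima. Both paths are verified in the test suite
against a brute-force oracle that enumerates every cylinder and recounts
cases directly.

Numerical edge cases: a zone with zero population has $E = 0$; any case
observed there yields $\Lambda = \infty$ (and $RR = \infty$), which
simply ranks it first. Windows with $O \le E$ score 0 and are never
reported. An empty case file scans to an empty result, not an error.

## The synthetic-data generator

Real case data of this kind are restricted, so the package ships a
seeded generator (`generate_synthetic()`) whose defaults emulate the
study conditions the scan is designed for: 100 small areas placed
uniformly in a 1° x 1° box (a county-scale extent at Irish latitudes),
log-normal census populations (median 250, log-sd 0.6, the right order
for small-area census geographies), and 388 expected cases over the
ten-year period 2008–2017 — a realistic volume for county-level suicide
surveillance. The background process is exactly the model's null:
Poisson cells proportional to population, homogeneous in time (a
seasonality hook is deliberately absent from the defaults; uniform time
mirrors the null). Planted clusters multiply cell rates by a relative
risk $\ge 1$ inside a chosen cylinder, and the realised truth (member
locations, window, expected excess) is attached for power evaluation
via Jaccard overlap in space and time (`plant_truth_overlap()`).
Optional demographics (gender roughly 78% male, ages centred in the
forties, a method mix dominated by hanging) are plausible for this
application but are decorative for the scan itself.

What the generator does *not* emulate: settlement geography and road
networks (locations are uniform, not village-clustered), seasonality and
weekday effects, intercensal population drift, and demographic risk
gradients. Passing tests on synthetic data therefore validate the
statistical machinery — calibration, power, determinism — not the
sociology of any real region.

## Problem sizes used in the validation suite

The test suite validates statistical properties at sizes chosen to keep
a full run comfortably interactive while leaving the conclusions
meaningful: type-I error calibration uses 200 null datasets of 6
locations over 30 days with $R = 999$ (rejection counts compared to the
central 99% binomial band around 0.05); power/recovery uses 50 seeded
datasets of 15 locations over 90 days with a planted 4-area, 14-day
cylinder at $RR = 20$ (about 24 expected excess cases, far above the
5-case floor at which detection is demanded); oracle equivalence sweeps
50 random instances of up to 6 locations and 12 days against brute-force
enumeration. Scaling any of these up is a matter of changing the
constants in the tests; the engine itself has no hard-coded sizes.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `t_max_days` | 30 | maximum temporal window height (days) |
| `aggregation_days` | 1 | temporal aggregation unit (days) |
| `max_pop_fraction` | 0.5 | spatial window cap as a share of total population |
| `min_cases` | 2 | minimum observed cases for a reported cluster |
| `n_replications` | 999 | Monte-Carlo replicates |
| `alpha` | 0.05 | significance level for the alarm flag |
| `distance_metric` | great_circle | haversine (6371 km) or planar degrees |

`max_pop_fraction = 0.5` is the de-facto standard for this scan family
rather than a value with an application-specific justification, and it
is exposed precisely because of that. `min_cases = 2` reflects that a
single death is never a "cluster" in this application. Low-rate
(protective) windows are not scanned: the surveillance question is
one-sided by design.

## Design choices that were genuinely open

- **Centroid assignment.** Cases carry a small-area location id rather
  than exact residential coordinates; pre-geocoded point data are
  ingested by synthesising one location per unique coordinate pair.
  Centroid assignment is the documented default because population
  denominators exist only at small-area level, and a centred-but-wrong
  denominator is worse than a rounded location.
- **Secondary-cluster rule.** No geographic overlap, temporal overlap
  allowed (see above). The alternative — no overlap in space *or* time —
  suppresses genuinely distinct simultaneous clusters.
- **Reference distribution for secondaries.** The replicate-maximum
  distribution for every reported cluster. Cluster-specific reference
  distributions are not implemented; the conservative direction is the
  safe one for an alarm system.
- **Calibration test uses `min_cases = 1`.** With the reporting floor at
  2, the observed statistic (max over windows with $O \ge 2$) is a
  different functional from the replicate maximum (unrestricted), which
  makes the test conservative by construction; setting `min_cases = 1`
  restores exchangeability and tests the Monte-Carlo machinery sharply.
- **Exports.** GeoJSON (RFC 7946) replaces an ESRI shapefile as the
  cluster-map format: open, single-file, and readable by every modern
  mapping stack. Circles are 64-segment geodesic buffers; a zero-radius
  (single-location) cluster is a point feature.

## Known limitations

- Circular windows only: elongated clusters (a river valley, a
  commuter corridor) can be fragmented or missed. Elliptic or
  irregularly-shaped windows are out of scope.
- One census snapshot: population change within the study period is not
  modelled.
- No covariate adjustment (age/sex-standardised expected counts are not
  computed); the expectation is purely population-proportional.
- The space-time permutation variant (which needs no population file)
  is not implemented; the discrete Poisson model is the method here.
- Pure-R engine: a decade of daily data over a few hundred small areas
  scans in seconds, but Monte-Carlo inference with $R = 999$ on much
  larger geographies is compute-hungry; batching keeps it tractable at
  county scale, which is the intended deployment.
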