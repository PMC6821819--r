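# trophnet

Spatiotemporal analysis of trophallactic (mouth-to-mouth food exchange)
networks in ant colonies.

When a starved colony regains access to food, a small caste of foragers
collects it and the rest of the colony receives it through chains of
trophallactic exchanges. Scan-sampling such a colony — recording once per
minute every ongoing exchange with donor, receiver and nest position —
yields a spatiotemporal contact table. `trophnet` turns that table (or a
synthetic colony with known ground truth) into the full set of analyses
this kind of study needs. It is aimed at behavioural ecologists working on
social insect networks and at anyone needing temporal-network randomization
tests on scan-sampled contact data.

## What it computes

* **Events and castes** — maximal runs of the same directed pair on
  consecutive scans become single events with duration and position; an
  ant is a forager iff a single feeding visit lasted ≥ 5 consecutive
  seconds; per-ant activity profiles (given/received counts, balance,
  first-event times, partners).
* **Network structure** — directed weighted aggregate network; weighted
  degree, betweenness, harmonic closeness, eigenvector centrality,
  weighted clustering; global efficiency
  *E* = mean over ordered pairs of 1/*d*(*i*,*j*); caste pair-type shares
  against the caste-blind expectation; pair/event ratio.
* **Inequality** — Lorenz curves and the Gini coefficient
  *G* = 1 − 2∫*L*(*p*)d*p* of per-ant activity, over all ants or active
  ants, per caste and role.
* **Reference models** — Full Random (FR) rewiring (every event reassigned
  to a uniform random ordered pair) and Randomly Permuted times (RP;
  event times shuffled, network conserved exactly), with seeded,
  reproducible ensembles and Z-tests
  *Z* = (obs − mean₀)/sd₀ plus empirical rank p-values.
* **Temporal dynamics** — naive-ant survival curves, log-linear
  exponential latency fits (τ = −1/slope), T₅₀/T₇₅/T₉₅ spreading
  quantiles, observed T₅₀ vs the RP ensemble, count-rate regressions, and
  Poisson-GLM overdispersion tests (Pearson χ²/df with exposure offsets).
* **Space** — per-ant gravity centres and mean event–centroid distances
  (cm), a 6 × 5 occupancy grid with conservation-checked half-open
  binning, occupancy–event rank correlation, per-caste foreground
  (entrance-half) donation shares with a 2 × 2 χ², entrance-distance
  drift over 10-min windows, and a uniformity test of event locations.
* **Synthetic colonies** — a generator with exponential onsets (mean
  35 min), per-ant gamma-distributed exchange rates (Poisson-homogeneous
  at shape ∞, overdispersed otherwise), caste-structured partner choice,
  forager entrance bias decaying in time, and full ground-truth exposure
  for calibration and recovery tests.

## A worked example

```r
library(trophnet)

cfg <- run_config(simulate = simulation_config(seed = 5),
                  n_replicates = 1000, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> trophallactic-network analysis report
#>   colony: 53 ants, 112 events
#>   gini (active ants) = 0.459 vs FR null 0.253 +/- 0.024 (Z = 8.58, one-sided p = 4.952e-18)
#>   onset: tau = 23.4 min (R2 = 0.948); T50 vs RP: Z = -0.83, p = 0.2022
#>   efficiency = 0.108; pair ratio = 0.857
```

Reading this: the simulated colony of 53 ants produced 112 exchanges whose
concentration among active ants (Gini 0.459) far exceeds what uniformly
random exchanges give (null mean 0.253) — individual heterogeneity, not
chance. Half the colony had joined the network by minute 31 versus 37.8
expected under time permutation (Z = −0.83): spreading is faster than its
temporally randomized reference, here not significantly so in a single
colony. The caste table shows the forager/non-forager asymmetry:

```r
report$caste_summary
#>   caste n_ants n_active events_given events_received mean_given mean_received
#> 1     F     12       12           85              41  7.08          3.42
#> 2    NF     41       28           27              71  0.66          1.73
```

Twelve foragers performed 76% of the donations while non-foragers were net
receivers (mean balance −1.07), and foragers ranged wider around their
gravity centres (1.14 cm vs 0.84 cm):

```r
gv <- report$spatial$gravity
tapply(gv$mean_dist_cm, gv$caste, mean)
#>    F   NF
#> 1.14 0.84
```

The same pipeline runs on recorded CSVs (`scan_path`, `visit_path`,
`roster_path` in `run_config()`, or a YAML file via `read_run_config()`),
and `multi_colony_summary()` pools several reports with a Kruskal–Wallis
homogeneity check.

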