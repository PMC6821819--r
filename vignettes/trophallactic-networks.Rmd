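---
title: "Analysing trophallactic networks: models, null references, and the synthetic colony"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing trophallactic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trophnet)
```

## The problem

When a starved ant colony regains access to food, a small caste of foragers
collects it and the colony redistributes it internally through mouth-to-mouth
exchanges (trophallaxis). Scan sampling such a colony — recording, once per
minute, every ongoing exchange with the donor's and receiver's identities and
the position of the contact — produces a spatiotemporal contact table from
which three families of questions can be asked:

* **Who does the work?** Are exchanges spread evenly, or concentrated in a
  few individuals beyond what chance alone produces?
* **How fast does food spread?** How quickly do naive ants (those that have
  not yet exchanged) join the network, and is the spreading faster than a
  temporally randomized reference?
* **Where does it happen?** Do foragers and non-foragers exchange in
  different parts of the nest, and does the spatial pattern drift as the
  colony fills?

`trophnet` implements this full analysis: event construction from scans,
operational caste classification, directed weighted network metrics,
Lorenz/Gini inequality, two randomization reference models with Z-tests,
spreading dynamics, overdispersion tests of individual heterogeneity, and
nest-grid spatial analyses — plus a synthetic colony generator whose ground
truth is exposed so every estimator can be checked by parameter recovery.

## From scans to events

A trophallactic *event* is a maximal run of scans of the same ordered
(donor, receiver) pair at strictly consecutive minutes; its duration is the
run length and its position is the first scan's position. Three conventions
matter and are fixed here:

* runs are defined on the **ordered** pair — a role swap between consecutive
  minutes starts a new event, because merging across swaps would corrupt the
  per-role tallies;
* a gap of one or more missed minutes breaks a run;
* the event position is the first scan's position (reproducible, order
  independent), not a run average.

Castes are operational: an ant is a forager (`F`) if any single feeding
visit lasted at least 5 consecutive seconds, a non-forager (`NF`) otherwise.
Summed shorter visits never qualify, so classification is monotone in the
threshold. Ants with no events remain in the roster; every analysis states
whether it uses the whole colony or only active ants.

## Inequality of participation

Per-ant activity counts (total, given, or received) are summarised by the
ascending Lorenz curve and the Gini coefficient computed as one minus twice
the trapezoidal area under it: 0 for perfect equality, $(n-1)/n$ when one
ant does everything. A widely quoted verbal definition — the ratio of the
area below the Lorenz curve to the area below the diagonal — contradicts
that range (it equals 1 at perfect equality); this package implements the
standard coefficient, which matches the stated 0 = equality / 1 =
inequality convention, and documents the discrepancy rather than
reproducing it.

## Network metrics

The aggregate network is directed and weighted: weight($u \to v$) = number
of events $u$ donated to $v$. Choices that the raw definition leaves open:

* **Weight-to-distance.** Shortest-path metrics (betweenness, closeness,
  efficiency) use edge length $1/w$: stronger exchange, shorter distance —
  the standard convention for interaction-count networks.
* **Closeness on disconnected graphs.** The default is harmonic closeness
  (mean of inverse distances, unreachable = 0), so partially connected
  colonies remain comparable; classical within-component closeness is
  available as an option.
* **Eigenvector centrality.** Computed by power iteration (tolerance
  1e-10) on the symmetrised adjacency by default, so one caste-comparable
  score is reported; the right (receive-side) and left (give-side)
  eigenvectors are returned alongside. Degenerate graphs give a flagged
  zero result, never a silent one.
* **Degree** is the raw in+out event count (an activity measure);
  clustering is the weighted (Barrat) local coefficient on the underlying
  undirected graph.

Global efficiency is the mean over ordered pairs of $1/d(i,j)$ with
$1/\infty = 0$; a complete unit-weight digraph scores 1, an edgeless one 0.
All shortest-path metrics are tested against exhaustive path enumeration on
small graphs.

## Reference models and Z-tests

Two null models bracket the observed structure:

* **FR (Full Random)** redraws every event's (donor, receiver) as a
  uniformly random ordered pair of distinct colony members — independently
  per event, so repeated pairs can arise and the pair-ratio null is well
  defined. Times, durations and positions are conserved; all network
  structure is destroyed. The FR roster is the whole colony by default
  (configurable to active-only).
* **RP (Randomly Permuted times)** permutes the multiset of start times
  among events, conserving the aggregate network, every per-ant count, and
  every static statistic *exactly* — which the test suite verifies
  bit-for-bit — while destroying temporal correlation.

An observed statistic is compared to its null ensemble (default 1000
replicates) by a Z-test; an empirical rank-based p-value is reported
alongside the normal-tail one. Replicate $r$ of an ensemble runs on its own
RNG stream seeded `seed + r`, so ensembles are reproducible and order
independent. Sidedness defaults follow the direction each comparison is
about (observed Gini *above* the null, spreading *faster* than the null)
and every result records the choice; reported one-sided p-values of the
form p = 0.028 for Z = 1.91 are consistent with this default.

## Temporal dynamics

The naive survival curve $S(t)$ is the proportion of a reference population
whose first qualifying event is later than $t$. The latency scale is
estimated by regressing $\ln S$ on $t$ (deterministic, matches a
regression-style $R^2$); the mean latency is $-1/\mathrm{slope}$. On a
noiseless exponential the fit is exact to machine precision. Two caveats
are deliberate:

* with an **active-only** reference the curve is a truncated exponential
  and the log-linear fit is biased low (about $-40\%$ at a 35-min mean in a
  90-min window) — recovery tests therefore use the whole-colony curve of a
  fully participating population, and the bias is a reason to prefer the
  whole-colony scope when a latency scale is the target;
* the curve needs at least three positive points; non-decaying input gives
  a flagged, not fabricated, result.

$T_{50}/T_{75}/T_{95}$ are the earliest first-event times at which the
cumulative count reaches the ceiling of $q \cdot N$ for a stated reference
$N$; quantiles never reached are reported absent. `spreading_vs_rp`
compares the observed $T_{50}$ to its RP distribution. Its default
reference is the **whole colony**: "half the ants have joined" then probes
the tail of the joining process when a sizeable fraction never joins, which
is where front-loaded (exponential) onsets beat time-permuted references
most clearly. The active-only variant (the median joiner) is available and
is the one used for calibration checks, because its null is finer-grained;
the whole-colony variant's z is conservative (the null of a minute-resolution
tail statistic is lumpy and skewed), which the calibration suite documents
rather than hides.

Individual heterogeneity is tested with an intercept-only Poisson GLM with
a log-exposure offset — exposure being the remaining observation time after
the first event, which operationalizes "individuals starting at the same
time" for ants that start at different times. The dispersion statistic is
the Pearson chi-square over its degrees of freedom, with the chi-square
upper tail as p-value. Its type-I error is calibrated by simulation (within
[3%, 7.5%] at $n = 100$) and its power against counts with variance three
times the mean exceeds 80%. Slopes of count-on-covariate regressions
(events vs first-event time; events vs feeding visits) are compared across
groups with a Wald z on the slope difference; Spearman statistics are
reported alongside every linear fit.

## Spatial organisation

The nest (56 × 41 mm, entrance on the boundary, position configurable) is
divided into a 6 × 5 grid of equal cells (about two ant lengths per side).
Binning is half-open with the far edges closed, so every in-bounds point
maps to exactly one cell and totals are conserved. Per-ant *gravity
centres* are centroids of all event positions the ant took part in (donor
or receiver, with role-filtered subgroups available); the mean distance of
its events to that centroid — reported in cm — measures how far the ant
ranges while exchanging, and is translation and rotation invariant. The
*foreground* is the nest half nearer the entrance, split perpendicular to
the wall the entrance sits on; per-caste foreground donation shares are
compared by a 2 × 2 chi-square. Spatial heterogeneity of event locations is
tested by comparing the per-cell Pearson chi-square against uniform random
placement of the same number of events (a reconstruction of a
Z-test-against-uniformity described only summarily in the source
literature). Occupancy and event grids are compared by Spearman rank
correlation over cells.

## The synthetic colony generator

`simulate_colony()` produces scan tables, feeding visits and snapshot
positions with the statistical structure the analyses assume, and exposes
all generating parameters. Its defaults are the study conditions the
pipeline targets: 53 ants, 23% foragers, 90 minutes at 1-min scans,
exponential onset latency with mean 35 min, and on the order of a hundred
events per trial.

The generative model, and what each piece encodes:

* **Joining.** Each ant joins the exchange network with probability
  `p_active` (defaults F 0.95, NF 0.55 — roughly half the colony, mostly
  non-foragers, never exchanges) after an exponential latency; its first
  event is a donation or a receipt with caste-dependent probability, the
  partner drawn among earlier joiners (weighted toward forager donors for
  joining receivers). Drawing partners among earlier joiners is a
  deliberately minimal stand-in for crop-load bookkeeping: ants that have
  already received or foraged are the ones able to give.
* **Repeat activity.** After joining, each ant initiates donations as a
  Poisson process with a personal gamma-distributed rate (`shape_give`
  finite gives negative-binomial, overdispersed, counts; `Inf` is the
  Poisson-homogeneous null). Expected counts are proportional to remaining
  observation time, which is what makes the count-on-first-time regression
  linear with slope equal to the negated mean rate.
* **Phase structure.** Repeat-donation times are skewed toward the end of
  each ant's window (`redistribution_ramp`, default 2): primary
  dissemination dominates early, secondary redistribution builds up as
  crops fill — consistent with exchanges moving away from the entrance
  after the first half hour. This late secondary phase is also what makes
  observed spreading faster than the RP reference: first events are
  front-loaded relative to the pooled time distribution.
* **Receivers** are drawn among current participants with personal
  gamma-distributed attractiveness weights (`shape_receive`).
* **Space.** Non-foragers share a tight home cluster away from the
  entrance; forager homes are dispersed. Event positions scatter
  isotropically (truncated to the nest by resampling) around a point
  anchored toward the receiver's home — the receiver is the more
  stationary partner — and forager donations are pulled toward the
  entrance early, a pull decaying linearly with time. The spread
  parameters are set so that per-ant gravity-centre dispersions sit near
  the observed scale (around 1.1 cm for foragers vs 0.8 cm for
  non-foragers, ratio about 1.4) and foragers reliably range wider.
* **Null world.** `partner_choice = "uniform"` keeps the event times but
  reassigns every event to a uniformly random ordered pair — exactly the
  world the FR model describes. With homogeneous rates this is the
  configuration against which the FR-Gini Z-test is shown to be
  calibrated.

The emitted scan table is canonical: the generator's event list is, by
construction, what `merge_consecutive_scans()` recovers from its own scans,
so simulated data round-trip the parsers exactly. Feeding visits make the
true castes recoverable by `assign_castes()` (forager visits always exceed
the 5-s threshold; non-foragers never visit).

What the generator does **not** emulate: crop volumes and satiation
feedback, queen or brood effects, pair memory (partnerships are
pair-anonymous given the weights), within-minute timing, or ant
trajectories between events. Tests that pass on synthetic colonies
therefore validate the estimators under the stated statistical structure —
they do not certify any particular biological mechanism in real colonies.

## Problem sizes and numerical choices

Simulation-based checks in the test suite use 100–200 seeded colonies with
reference ensembles of 120–300 replicates, and 300–1000 draws for
type-I/power checks — sizes at which the binomial noise of a rejection rate
is well below the width of the asserted bands. Reported analyses default to
1000-replicate ensembles. Other numerical conventions: ties in Lorenz
sorting are broken by ant id (the Gini is tie-invariant); T-quantiles use
the ceiling-count rule; degenerate cases (zero-variance ensembles,
constant grids, all-zero activity, non-decaying survival) yield flagged
results or errors, never silent zeros.

## Known limitations

* Centrality values are convention-dependent (weight-to-distance mapping,
  normalization); comparisons across castes within one convention are
  meaningful, absolute values are not comparable across conventions.
* The whole-colony $T_{50}$ Z-test is conservative at 1-min resolution;
  significance claims based on it understate evidence, and the empirical
  rank p-value is reported for exactly this reason.
* The exposure-offset dispersion test conditions on observed first-event
  times; it tests heterogeneity of post-onset rates, not of joining.
* The generator's ladenness proxy (participation) slightly inflates
  donation counts of early joiners relative to the configured personal
  rates; the rate-recovery tests bound this by checking CI coverage rather
  than exact equality.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(simulate = simulation_config(seed = 7),
                  n_replicates = 1000, seed = 42)
report <- run_pipeline(cfg)
print(report)
report$inequality$vs_fr     # observed Gini vs the FR ensemble
report$temporal$t50_vs_rp   # spreading vs the RP ensemble
report$spatial$foreground   # per-caste foreground donation shares
```
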