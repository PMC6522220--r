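---
title: "Modeling C. elegans aggregation and swarming with wormswarm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling C. elegans aggregation and swarming with wormswarm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`wormswarm` simulates collective feeding of *C. elegans* as `N` worm-like
chain agents in a periodic square arena.  Each worm is a chain of `M`
nodes (default 18) connected by stiff springs that keep the total length
at `L` (1 mm) to within 5%.  The head node performs a persistent random
walk: each time step its heading receives a Gaussian rotational-diffusion
increment with variance `2 * D_theta * dt`, and the remaining nodes
follow the node ahead of them, so the body traces the head's path.
Worms may overlap freely: hyper-social worms crawl over one another in
dense clusters, and the model deliberately omits volume exclusion.

Three density-dependent behaviors drive aggregation.  Local density
`rho` around a worm is sensed as the k-nearest-neighbor density of all
worms' head-region centroids, `rho = k / (pi * d_k^2)` with `k = 6` —
the same estimator the analysis side applies to tracked pharynx
positions, chosen for internal consistency between model and
measurement.

1. **Cluster-edge reversals.**  Each worm registers contact within
   `r_contact` (0.1 mm) at the first and last 10% of its nodes.  Contact
   at exactly one end is the signature of leaving a cluster, and then a
   reversal starts as a Poisson event with rate `r' * rho`.  The rate is
   zero at zero density: spontaneous reversals off clusters are rare
   experimentally and are ignored.  A reversal swaps the propulsion
   direction (the tail leads, continuing backwards along the body) and
   ends after an exponential duration with mean 2 s.
2. **Speed switching.**  Worms switch stochastically between fast
   crawling (`v_fast` = 0.35 mm/s) and slow crawling (`v_slow` =
   0.035 mm/s) with rates `k_slow = k_s0 + k_s' * rho` and
   `k_fast = k_f0 * exp(-k_f' * rho)`; the exponential form keeps the
   speeding rate positive at any density.  The zero-density rates default
   to `k_s0 = 1/240` and `k_f0 = 1/60` per second, giving lone worms a
   stationary fast fraction of 80%.  These two values are
   package defaults standing in for single-worm literature calibration,
   and are configurable.
3. **Neighbor taxis.**  A worm's heading is biased towards its neighbors:
   the taxis vector is `f_t * sum_j u_j / r_j` over neighbor head
   centroids within one worm length, where `u_j` is the unit vector
   towards neighbor `j`.  The heading update adds this vector to the unit
   persistence vector and takes the direction of the sum, before applying
   rotational noise.

With food enabled, a periodic grid of relative concentration (cell size
0.2 mm, initialized at 1) is depleted under each worm's head cell at
`feed_rate` per second per occupant.  Where the concentration has fallen
below `food_threshold` (0.05), slowing is suppressed (`k_slow = 0`), so
worms on depleted patches speed up, leave, and re-aggregate on nearby
food — the mechanism that turns static aggregation into swarming.

## Time stepping and numerics

The engine advances all worms with a fixed step `dt = 0.05` s, chosen so
that a fast worm moves well under one node spacing per step and the
spring relaxation (three Gauss–Seidel sweeps per step in the engine)
keeps chain lengths within the 5% tolerance; the exported single-worm
`advance_body()` uses ten sweeps so that arbitrarily distorted test
configurations also relax.  Random draws consume a single seeded RNG
stream in a fixed order (per step: headings, reversals, speed switches,
each over worms in index order), so every run is exactly reproducible
from its seed.  Coordinates are wrapped into `[0, arena_side)` and all
distances use the minimum-image convention.

The default arena is 8 mm for 40 worms: with a nominal worm width of
0.08 mm this gives an occupied-area fraction of 5%, matching the 4–6%
of the experiments the model emulates.

## Reference parameter sets

The four interaction parameters for the aggregating (*npr-1*-like) and
solitary (N2-like) phenotypes are package reference sets, chosen once
during model exploration so that the full aggregating set forms dense
clusters while removing any one mechanism degrades them; they are not
measured constants.  The aggregating set is `r' = 0.5 mm^2/s`,
`k_s' = 0.03 mm^2/s`, `k_f' = 1 mm^2`, `f_t = 0.01`.  Two scales inform
these choices.  First, background density in the default arena is about
1 mm^-2 while in-cluster densities reach 10–40 mm^-2, so the slopes must
leave lone worms mostly fast (`k_s' * 1` comparable to `k_s0`) yet trap
clustered worms (`k_slow` of order 1/s, `k_fast` negligible).  Second,
because the heading update re-aims every step, the effective taxis
turning rate is about `f_t / (r * dt)`; for `f_t` above roughly
`v_fast * dt` even fast worms orbit a neighbor and lock into pairs,
so the reference `f_t = 0.01` sits below that threshold — taxis can hold
slowed, clustered worms together but cannot by itself bind fast ones.
This makes the mechanisms genuinely cooperative: speed switching
recruits worms into clusters, taxis and reversals tighten and retain
them.

## What the statistics compute

* **S1, pair correlation**: per distance bin, observed pair counts
  divided by the expectation for the same number of uniform points in
  the same domain, averaged over frames.  On the periodic arena the
  expectation is the exact minimum-image disc-area formula on the torus;
  on bounded domains it is a seeded Monte-Carlo uniform reference.
* **S2, branch lengths**: the `n - 1` single-linkage merge distances per
  frame (computed with `hclust`), pooled and histogrammed to relative
  frequency; the histogram is normalized over the configured bins.
* **S3/S4**: per-axis standard deviation and Pearson kurtosis
  (Gaussian = 3, per-axis uniform = 1.8) of positions, axis-averaged then
  frame-averaged.  The kurtosis convention is a package choice.
* Statistics use head-region centroids only — the simulation analogue of
  pharynx-only tracking — even when full skeletons were recorded.
* Simulated runs are summarized over frames sampled from the final 10%
  of the run (the quasi-steady state); fixtures and imports over the
  whole recording, one frame per 30 s.

## Trajectory analyses

Signed speed takes its sign from the dot product of the skeleton
(head-direction) vector with the centroid velocity and is smoothed over
half a second.  Reversal events are positive-to-negative sign changes,
kept when the backward path (displacements opposing the pre-event
direction, within a one-second-extended window) is at least 50 µm and
the track moved at least half a pixel per frame (10 µm/px calibration by
default) in the second before and after.  Reversal rates per density bin
are events divided by forward time, with a 100-sample worm-frame
bootstrap.

Cluster tracking rasterizes worm positions every 30 s to a 0.1 mm
occupancy grid (all skeleton nodes when available, otherwise head
centroids; the default blob-area threshold of three worms' footprint
adapts accordingly), labels 8-connected blobs (periodic-aware), links
blob centroids across samples by globally nearest pairs within 1 mm per
elapsed sample, and tolerates up to 4 missed samples before closing a
track, because simulated clusters transiently disperse and re-form.
Centroid positions are unwrapped, smoothed over 10 min, and differenced
to speeds in µm/min.

## Inference

Rejection ABC samples the four interaction parameters from independent
uniform priors (`r'` in [0, 1], `k_s'` in [0, 1], `k_f'` in [0, 2],
`f_t` in [0, 2]), restricted by a feasibility cap on the reversal rate
at a reference in-cluster density (10 per second at 20 worms/mm^2),
which excludes unrealistically reversal-dominated dynamics.  The
distance between summary statistic sets weights the four statistics
equally: Euclidean distances between the binned S1 and S2 curves and
absolute differences of S3 and S4, each divided by a per-statistic scale.
The scales are self-normalizing — the root-mean-square component
distance to the pooled mean across the prior-predictive set — because
"equal weighting" needs the four statistics on a common scale.  The
default acceptance fraction is 1%, a package choice.

## Problem sizes used by the test and acceptance suites

The suites run the model at sizes a laptop handles in minutes, stated
here as the package's own study conditions: closed-form oracles use
10^4–10^5 Monte-Carlo draws; ablation and phase-portrait runs use the
default 40-worm arena for 90 minutes of simulated time; the swarming
analysis sweeps four feeding rates with five seeded 90-minute runs each;
and parameter recovery uses 500 prior simulations of a 12-worm, 4.5 mm
arena (the same 5% area fraction) for 10 simulated minutes, repeated
three times.  The full-scale inference campaign of the original study
(tens of thousands of hour-long simulations) is out of desk scope, and
nothing in the package depends on it.

## What the synthetic fixtures do and do not emulate

`generate_fixtures()` produces seeded datasets with known ground truth:
uniform and clustered point patterns for the spatial statistics, a
scripted track with backward excursions of known lengths for reversal
detection, a rigidly translating disc of worms for cluster tracking, and
a two-population speed field for the density-binned speed profiles.
They emulate the statistical structure each analysis assumes — not real
tracking imperfections such as identity swaps, segmentation loss inside
dense clusters, or intensity-dependent detection.  Passing tests
therefore validate the estimators' arithmetic and conventions, not
robustness to tracker artifacts.

## Known limitations

* No volume exclusion; clusters are denser than physically possible.
* The taxis cue is phenomenological (1/r weighting towards pharynx
  positions); no oxygen or pheromone field is modeled.
* Food does not diffuse or regrow, and lawns are uniform.
* Undulations are omitted; body posture beyond the chain backbone is not
  modeled.
* The reference strain parameter sets reproduce phenotypes, not fitted
  posterior values.
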