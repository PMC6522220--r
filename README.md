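# wormswarm

Agent-based simulation and analysis of *C. elegans* collective feeding:
aggregation of hyper-social worms into dense clusters, and the dynamic
swarming that emerges when those clusters locally deplete their food.

Hyper-social *C. elegans* (such as *npr-1* loss-of-function mutants)
aggregate on bacterial lawns, while the solitary laboratory strain N2
does not; over hours, the aggregates of social worms start sweeping
across the lawn as a coherent moving cluster.  `wormswarm` is for
quantitative behavioral scientists and modelers who want to (i) simulate
these phenomena from individual-level behavioral rules, (ii) compute the
spatial and trajectory statistics used to quantify them in multi-worm
tracking data, and (iii) infer behavioral parameters from those
statistics by likelihood-free (rejection ABC) inference.

## The model

Each of N worms is a chain of M nodes of total length L (springs enforce
non-extensibility) whose head performs a persistent random walk with
rotational diffusion coefficient D<sub>θ</sub>, in a periodic square
arena.  Local density ρ around a worm is the k-nearest-neighbor density
k/(π d<sub>k</sub>²), k = 6.  Three density-dependent behaviors couple
the worms:

* **Cluster-edge reversals** — contact sensed at one body end but not
  the other triggers a reversal with Poisson rate r′ρ (zero at zero
  density);
* **Speed switching** — stochastic switching between fast and slow
  crawling with rates k<sub>slow</sub> = k<sub>s0</sub> + k′<sub>s</sub>ρ
  and k<sub>fast</sub> = k<sub>f0</sub> exp(−k′<sub>f</sub>ρ);
* **Neighbor taxis** — a heading bias f<sub>t</sub> Σ û<sub>j</sub>/r<sub>j</sub>
  towards neighbors within one worm length.

With food enabled, worm heads deplete a relative-concentration grid;
absence of food suppresses slowing (k<sub>slow</sub> = 0), which makes
clusters disperse off depleted patches and re-form on food — emergent
swarming.

Analysis tools mirror the tracking-side quantification: pair correlation
(S1), single-linkage branch-length distribution (S2), positional
dispersion (S3) and kurtosis (S4); signed speed and reversal detection
with density-binned bootstrap rates; blob-based cluster tracking with
10-min-smoothed centroid speeds; and rejection ABC over
(r′, k′<sub>s</sub>, k′<sub>f</sub>, f<sub>t</sub>) with equal weighting
of the four summary statistics.

## Worked example

```r
library(wormswarm)
p <- worm_params(strain = "npr1", seed = 7)   # aggregating reference set
p
#> Worm aggregation model parameters
#>   40 worms x 18 nodes, L = 1 mm, arena 8 mm (periodic)
#>   speeds: v_fast = 0.35, v_slow = 0.035 mm/s; dt = 0.05 s; D_theta = 0.1 rad^2/s
#>   reversals: r' = 0.5 mm^2/s, mean duration 2 s
#>   switching: k_s0 = 0.004167, k_f0 = 0.01667 1/s; k_s' = 0.03 mm^2/s, k_f' = 1 mm^2
#>   taxis: f_t = 0.01, cutoff 1 mm; contact radius 0.1 mm; k-NN k = 6

d <- run_simulation(p, duration = 1800, record_every = 10)
d
#> worm_tracks: 181 frames x 40 worms (simulated), 1800.0 s at 10 s/frame
#>   periodic arena 8 mm

summarize_dataset(d, sample_every = 30)
#> Spatial summary statistics
#>   S1 (pair correlation): mean 26.58 at r < 0.5 mm
#>   S2 (branch lengths):   mass 0.88 below 1 mm
#>   S3 (dispersion):       2.073 mm
#>   S4 (kurtosis):         1.732
#>   computed from 7 sampled frames
```

After 30 simulated minutes the aggregating parameter set shows strong
small-scale clustering: worms have on average ~27× more neighbors within
0.5 mm than a uniform population would (S1), and 88% of single-linkage
merge distances fall below 1 mm (S2).  The same run with the default
non-interacting parameters (`worm_params()`) gives S1 ≈ 1 at all
distances.  With `food_enabled = TRUE` the same parameter set produces
moving clusters whose 10-min-smoothed centroid speed is computed by
`cluster_tracks()`.

A thin CLI wraps the same functions
(`inst/exec/wormswarm simulate|swarm|stats|reversals|clusters|infer|sweep|fixtures`),
with YAML configs mirroring `worm_params()` field names.

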