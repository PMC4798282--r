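---
title: "Models and methods: T-cell motility statistics and search-efficiency simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: T-cell motility statistics and search-efficiency simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the models it implements,
the parameters that matter, and the places where a design decision had
to be made. The companion `analysis/` scripts run everything described
here on synthetic reference data; nothing below states a number that
those scripts or the test suite do not themselves compute.

## The scientific problem

Naive T cells percolate through the lymph-node paracortex looking for
dendritic cells (DCs) that display their cognate antigen. The rate at
which a T cell encounters *new* DCs (search extent) and *re-encounters*
nearby DCs (search thoroughness) both matter immunologically, and
different random-walk models trade these off differently. Given 3D cell
tracks — an ordered sequence of positions every 13–21 s for up to 10
minutes per cell — the analysis asks three questions:

1. Which statistical motion model do the tracks actually follow?
2. What search efficiency would each candidate model deliver against
   realistically clustered DC targets?
3. Do cells move differently in specific locations ("hotspots") than a
   motion-matched null model predicts?

## Track model and filtering

A `track` is a time-ordered position sequence with a nominal frame
interval; consecutive intervals must agree with it within 10% (real
acquisitions jitter; larger gaps indicate broken tracks). A `field` is
a set of tracks sharing a bounding box and frame interval — the unit at
which null models and simulations are matched to observation, because
correlation analyses depend on the frame rate.

Non-motile cells are removed by three Imaris-style track statistics:
total path length ≥ 17 μm (three cell diameters), net start-to-end
squared displacement ≥ 300 μm² (= 17 μm × 17 μm), and at least 3 time
steps. "Displacement²" is read as the *net* (first-to-last) squared
displacement, matching the Imaris track statistic of that name; a
maximal-over-time reading exists but is not used.

## Steps and the step-length distribution

Per-frame speeds (displacement ÷ frame interval) are one kinematic
scale; the other is the *step*: the resultant of a maximal run of
velocity vectors that stays within 15° of the run's **first** vector.
Measuring deviation against the first vector bounds total within-step
curvature; comparing against the immediately preceding vector is
available as `reference = "previous"`. Zero-length velocity vectors
(pauses) carry no direction and are absorbed into the current step. At
a 180° threshold every track collapses to one step, and the step count
is non-increasing in the threshold — both properties are tested.

## Distribution competition

Candidate families for speeds and step lengths are fitted by maximum
likelihood — closed forms for lognormal, Gaussian, Maxwell (the 3D
Brownian speed law, a² = Σx²/3n) and exponential; profile-likelihood
optimization for gamma; the Hill estimator with x_min at the sample
minimum for the power law. Fits are compared primarily by negative
log-likelihood; AICc (2k − 2lnL + 2k(k+1)/(n−k−1)) and BIC confirm the
ranking is not a parameter-count artifact; KS and Anderson–Darling are
computed against the fitted CDF without binning (binning biases
random-walk inference); χ² uses ⌈√n⌉ equal-probability bins, the one
place a binning choice is unavoidable. Gaussian fits to positive data
are deliberately untruncated: the Gaussian is the Brownian reference
model and truncation would change the likelihood comparison.

The Lévy-walk diagnostic is Clauset-style tail estimation: for each
candidate cutoff x_min (unique values, thinned to ≤1000 quantile-spaced
candidates; exhaustive search is quadratic), the tail exponent is
μ̂ = 1 + m/Σln(xᵢ/x_min) and the candidate minimizing the KS distance
between the tail's empirical CDF and the fitted power law wins. The
*fraction of data retained in the tail* is the interpretable output: a
true Lévy walk keeps most of the data; a lognormal body forces the
cutoff high and the fraction low.

## Diffusivity

MSD uses the displacement-from-origin convention — squared distance
from each track's first position, averaged per lag over tracks still
alive at that lag — because the decaying per-lag sample count is itself
informative; a time-averaged variant is deliberately not the default.
Only the first 10 minutes are used. α is the slope of a degree-1 least
squares fit to (log lag, log MSD), with the fit r² reported; tracks are
classed subdiffusive (α<1), in the Lévy window (1≤α≤2), or accelerating
(α>2), and r² filters {0, 0.25, 0.5, 0.75, 0.8, 0.9} are supported. The
motility coefficient is the slope of a plain linear fit to the first
25% of the MSD curve divided by 6 (3D), reported in μm²/min; the
population value is the unweighted mean over tracks with fit r² > 0.8.

One behaviour of this convention is worth knowing: on
displacement-filtered, variable-duration tracks, survivorship can pull
the ensemble α below the per-track typical value (short tracks must be
strongly displaced to pass the filter, and only longer, relatively less
displaced tracks contribute at long lags). The per-track α census is
the more robust summary under heavy filtering.

## Persistence and drift

Directional persistence is the ensemble mean of unit-velocity dot
products at a given delay, C(τ) = ⟨û(t)·û(t+τ)⟩, pooled over tracks and
start times; C(0) = 1 and an isotropic walker gives C(τ) ≈ 0 beyond
τ = 0. The between-track cross-correlation ⟨û_k(t)·û_m(t)⟩ at matched
*absolute* times (drift is a wall-clock phenomenon, so pairs are not
matched on track age) is the field-drift check; a drift-free field lies
within sampling error of zero.

## The search-efficiency simulator

Targets are placed at density 3.17×10⁻⁵ targets/μm³ — in the default
6.3×10⁶ μm³ field, 200 targets — in clusters of 10, each cluster
uniform within a sphere whose radius (10/20/40 μm, or uniform) sets the
aggregation measured by a 3D Hopkins statistic: per repetition, m
uniform probes (nearest-data distances u) and m sampled data points
(nearest-other-data distances w) give Σw/(Σu+Σw), so uniform → 0.5 and
clustered → 0. Raw (first-power) distances are the default; the
third-power variant is a flag.

The box default is a 355 × 355 × 50 μm slab, not a cube: two-photon
fields image 40–60 μm of depth, and slab confinement materially changes
how much a diffusive searcher re-covers its own ground. A cube (or any
box) can be passed explicitly; model-intrinsic checks such as the MSD
slopes of the walkers are run in a large cube so reflections do not
confound them.

Six searcher models are parameterized from the field's own pooled
speeds, turning angles, and step lengths:

| model | direction | displacement |
|---|---|---|
| brownian | uniform per frame | Maxwell-fit speed per frame |
| lognormal | uniform per frame | lognormal-fit speed per frame |
| crw | gamma-fit turning angle per frame | Gaussian-fit speed, clamped at 0 |
| logmcrw | gamma angle per *step* | lognormal fit to *step lengths*, at pooled mean speed |
| powerlaw | uniform per *step* | full-sample power-law fit to step lengths, at pooled mean speed |
| bootstrap | empirical (speed, angle) pair per frame | the paired empirical speed |

Three decisions here were genuinely open and are worth recording:

- **Per-frame vs per-step semantics.** The lognormal searcher draws a
  fresh speed each frame (its ensemble MSD slope is ≈1, the diffusive
  behaviour that model is meant to exhibit), while the LogMCRW is "a
  CRW with a lognormal distribution of *step lengths*": straight runs
  with lognormal lengths, a gamma turning angle between runs, traversed
  at the pooled mean speed. The per-frame kinematic reading of the
  LogMCRW (speed per frame, angle per frame) is kept as
  `semantics = "frame"` and is what the synthetic-data generator uses,
  because generated per-frame speeds must follow the lognormal speed
  law that defines the study conditions.
- **The Lévy searcher's exponent.** The power-law walker uses the
  full-sample power-law MLE (exponent ≈1.2–1.4 on lognormal-shaped step
  data), not the Clauset tail fit: the tail fit's exponent ≈3.4 with a
  high cutoff describes a tame walk, and a Lévy searcher is by
  definition in the heavy-tailed 1<μ<3 regime. The tail fit remains the
  *analysis* tool; both parameterizations are carried in the fitted
  parameter object.
- **Gaussian truncation.** Negative Gaussian speed draws become pauses
  (clamped to zero) rather than being resampled: resampling on skewed
  speed data inflates the walker's realized mean speed ~40% above its
  own fitted value, which breaks "parameterized by the estimated
  speeds".

Searchers start at the observed tracks' start positions with the
observed durations, and each searcher's path length is budgeted by its
observed track's path length, so the summed simulated distance never
exceeds the summed observed distance. A searcher that exhausts its
budget *idles in place* while its clock keeps running: this keeps the
searcher population's average velocity pinned to the observed value —
stopping the clock instead would reward fast models with a smaller
time denominator.

Contact uses the exact point-to-segment distance against a 10 μm
radius (5 μm each for T cell and DC), so detection is frame-rate
robust. Unique contacts count each (searcher, target) pair once; total
contacts by default count re-entry events (a contiguous run of
in-contact segments is one event), with a per-frame "presence" variant
as an option. Efficiencies divide by summed searcher time in minutes.
Model comparisons report percent change in median efficiency vs the
reference tracks, a t-based 95% CI over independent repetitions, and
Mann–Whitney p-values both on per-repetition medians and on pooled raw
values (efficiency distributions are far from Gaussian).

## Hotspots

Fields are discretized into 20 μm cubes (≈2 cell diameters) anchored at
the bounding-box minimum corner, and each cube records its number of
*unique* visiting tracks. The null model is the LogMCRW simulation
matched to the field — same starts, frame interval, durations — run 10
times; the threshold is the pooled mean + 2 SD of per-location visit
counts across all visited locations and repetitions (a single threshold
per field, not per-location). Cubes strictly above threshold are
hotspots; ties are not. Tracks intersecting any hotspot are *hot*, the
rest *cold*; the comparison reports median speeds with a Mann–Whitney
p-value, step-length skew/kurtosis per group, and dwell times (maximal
runs of consecutive frames in one cube, in time steps) for hot tracks
split by cube type.

Because counts are small integers, the mean + 2 SD threshold of a
sparse field can sit very near 2.0, and the detector's self-rate on an
independent null replicate then flips between "count ≥ 2" (~15% of
cubes) and "count ≥ 3" (~2%) regimes depending on the field. At the
synthetic study conditions used here (~100 tracks per field) this
bimodality is real and the across-field average self-rate is higher
than either branch; richer fields (more tracks, clustered entries)
push the threshold well above 2 and stabilize the rate. The analysis
scripts print the per-field threshold so this regime is visible.

## Heterogeneity

Shape statistics are method-of-moments: skew m₃/m₂^1.5 and non-excess
kurtosis m₄/m₂² (a Gaussian scores 3; the non-excess convention is used
throughout). The sliding window runs over track mean speed with width
0.125 μm/s in 0.1 μm/s increments, pooling member tracks' per-frame
speeds; windows with fewer than 10 pooled values are omitted. The
subpopulation competition pools speeds of tracks with mean speed
< 5 μm/min (slow) and > 15 μm/min (fast) and runs the full distribution
ranking in each class; the heterogeneity signature is a lognormal
winner with high skew in the slow class and a Gaussian/Maxwell winner
with near-zero skew in the fast class.

## Synthetic data: what it does and does not emulate

The generators are the stand-in for the study's unreleased imaging
data. Defaults define the study conditions and are not tuned:
speeds lognormal(μ = −2.5027, σ = 0.9329) in ln-μm/s and step lengths
lognormal(0.4818, 0.9192) in μm (the maximum-likelihood values
estimated from observed cells); frame interval 15 s (observed range
13–20.7 s); track durations uniform on [120 s, 600 s], which reproduces
decaying per-lag MSD counts; field volume 6.3×10⁶ μm³ as a
355 × 355 × 50 μm slab; turning angles gamma(shape 2, scale 30°) —
the printed record of the observed angle fit does not include its
parameters, so these were chosen once to put the angle mode below 90°
(the observed persistence signature) and are config-exposed.

Hotspot fields embed spherical regions with alternate (slower, less
persistent) parameters, a dwell bias (moves that would exit the region
are rejected with the given probability), and an *attraction*: walkers
passing within an attraction radius are steered toward the region core.
Attraction is what makes regions detectable — the detector counts
unique visitors, and a null model matched to the same start positions
inherits any start clustering, so extra dwell alone changes no
unique-visit count. With zero biases and identical parameters the
hotspot generator is statistically indistinguishable from the plain
one, which is the detector's false-positive control.

What passing tests on this synthetic world do **not** show: real
lymph-node tracks have empirical speed distributions that are only
approximately lognormal (their Gaussian-fit coefficient of variation is
smaller than the pure law's), start positions clustered at entry
portals, imaging artifacts (z-drift, track splitting), and anatomical
structure. Conclusions about relative model behaviour transfer;
absolute rates and thresholds need not.

## Numerical choices and degenerate inputs

- Angles are reported in degrees, computed in radians; cosines are
  clamped to [−1, 1] before `acos`.
- Gamma MLE brackets the profile-likelihood shape within a factor 50 of
  the moment estimate.
- Power-law tail cutoffs need ≥10 tail samples; identical-valued
  samples are a degenerate-tail error.
- Walkers reflect specularly at box faces; a frame-quantized walk
  realizes step lengths as whole-frame multiples, and 10-minute tracks
  truncate heavy tails — so tail-exponent recovery from generated
  *fields* is validated against an oracle that applies the same
  quantization and truncation to direct Pareto draws, not against the
  raw generating exponent.
- Hotspot grids use half-open cube intervals; the grid origin is the
  bounding-box minimum corner.
- All stochastic stages consume the caller-seeded RNG; generators take
  an explicit seed and are bit-reproducible given it.

## Problem sizes

The test suite and acceptance checks run at desk scale, chosen as the
smallest sizes at which the tested property is stable: Hopkins
calibration at 20 placements × 100 statistic repetitions; MSD slopes at
500 tracks × 40 frames; the null hotspot rate over 20 fields of 100
tracks; parameter recovery at 10⁴–10⁵ samples; the search-efficiency
ordering at 60 tracks × 100 replicates × 2 repetitions. The analysis
scripts use comparable sizes and print what they used.

## Known limitations

- The efficiency ordering between closely matched models (LogMCRW vs
  CRW, ~5% median difference under these conditions) is directionally
  stable but not always significant at desk-scale replicate counts.
- The Hopkins statistic of clustered placements depends on target
  count at fixed density and geometry; its printed calibration points
  are reproduced qualitatively (monotone in cluster radius, uniform
  limit at 0.5) rather than numerically at 200 targets.
- The total-contact ("thoroughness") advantage of Brownian search over
  Lévy search emerges only for searchers substantially slower than the
  budget allows; under a dimensionally consistent Maxwell
  parameterization the Brownian searcher spends its budget early and
  idles, capping its re-contact count.
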