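---
title: "Quantifying sway-pattern variability with self-organizing maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying sway-pattern variability with self-organizing maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swaysom)
```

## The problem

Repeated lateral weight shifting — swaying the trunk from the outermost
left to the outermost right stance limit and back — is a demanding balance
task, and lateral instability is one of the better predictors of falls in
older adults. When such a task is recorded with a markerless skeleton
tracker, each frame yields the 3D positions of 15 body segments at an
irregular rate of roughly 30 Hz. The question this package addresses is
how to turn those multivariate recordings into a quantity that captures
*how consistently a person repeats their coordination pattern*, and
whether that quantity separates young from older movers.

The pipeline has five stages, each its own module:

1. **Synthetic data** — a generator that emulates the study design, so the
   entire pipeline is testable without access to human recordings.
2. **Preprocessing** — resampling, landmark reduction, sway-cycle
   segmentation, amplitude/frequency summary, time normalization.
3. **Normalization** — per-trial centering and amplitude equalization.
4. **SOM** — a from-scratch Kohonen map projecting posture vectors onto a
   25 × 25 lattice; each trial becomes a trajectory of best-matching units
   (BMUs).
5. **Variability & classification** — the TTvar statistic, phase-resolved
   variability ellipses, Mann–Whitney group tests, and a second-SOM +
   kNN classifier of whole-trial trajectories.

## The synthetic cohort generator

The generator is not a fixture factory but a model of the study
conditions. Each subject receives a base sway amplitude (lower-back
medio-lateral half-excursion, default population mean 0.12 m, SD 0.02), a
base frequency (0.45 ± 0.07 Hz), a cycle-to-cycle variability level
(0.08 ± 0.02, expressed as the SD of per-cycle amplitude and period
perturbations relative to their means), a stature multiplier, and a
coordination trait: the phase lead of the upper body over the pelvis
(young 0.28 ± 0.07 rad, old 0.16 ± 0.07 rad). Each of five task
conditions scales amplitude and frequency (e.g. condition 3, "maximum
sway frequency", multiplies frequency by 1.8; condition 5, "maximum sway
amplitude", multiplies amplitude by 1.6) and condition 4 adds a
contralateral leg lift.

Trials are built from a single lower-back oscillator,
`-A a(t) cos(2*pi*u(t))`, where `u` is the within-cycle phase — every cycle
therefore starts and ends at the outermost *left* position, matching the
cycle definition used downstream — and `a(t)` interpolates per-cycle
amplitude perturbations linearly so the signal stays continuous across
cycle boundaries. All 15 segments are gain-scaled, phase-lagged copies of
this oscillator on a planar chain, with a pendulum-like vertical coupling:
the vertical dip of a landmark is proportional to `1 - cos` of its lateral
lean angle. Timestamps sit on a 1/30 s grid jittered uniformly by ±5 ms,
and Gaussian sensor noise (SD 3 mm) is added to every coordinate.

Three design choices deserve justification:

* **Age effects live at the performance limits.** Both groups share the
  same baseline distributions; for an `old` subject under a *complex*
  condition (3 or 5) the effective amplitude and frequency are multiplied
  by 0.8 and the variability level by 1.5. This mirrors the empirical
  pattern that group differences in sway amplitude, frequency and pattern
  variability emerge when the task pushes towards maximum frequency or
  amplitude, and it gives parameter-recovery tests a known answer: TTvar
  should separate the groups in conditions 3 and 5 and not in condition 1.
* **Age also changes coordination style, in every condition.** The
  amplitude normalization deliberately removes amplitude differences and
  the time normalization removes frequency differences, so if the
  archetypes differed *only* in those, the trajectory classifier would
  face pure noise. Older adults are stiffer and sway more en bloc, with
  less trunk-on-pelvis phase lead; the generator encodes this as the
  group-dependent `phase_lag` trait. The distributions overlap
  substantially (0.12 rad apart, SD 0.07), so the groups form a continuum
  on the second map rather than two clean clusters — classification is
  intentionally imperfect.
* **Corrupted trials are generated, not simulated away.** A configurable
  number of trials per group is generated with too few sway cycles; the
  preprocessing discard rule must catch exactly these. The default
  acceptance cohort forces 8 young and 14 old trials short, so 400
  recorded trials yield 378 for analysis.

What the generator does *not* model: physiologically validated balance
dynamics, depth-camera noise structure (occlusion, per-segment tracking
quality), postural strategies beyond a single kinematic chain, or
fatigue/learning across trials. Tests passing on this generator therefore
demonstrate that the *pipeline* measures what it claims on data with known
structure — not that real Kinect recordings would produce the same
numbers.

## Preprocessing

* **Resampling.** Cubic-spline interpolation (`stats::spline`, no
  extrapolation) of every coordinate onto an exact 30 Hz grid. Splines
  reproduce cubics exactly and track a 1 Hz sinusoid sampled at ~30 Hz to
  well under 0.1 mm, which is far below the injected sensor noise.
* **Landmark reduction.** Hands, elbows and feet are poorly tracked and
  not needed for the sway task; they and the sagittal axis are dropped,
  by column label, leaving the 18-dimensional posture vector (9 x's then
  9 y's).
* **Cycle segmentation.** A sway cycle runs between successive outermost-
  left positions of the shoulders. Boundaries are local minima of the
  mean shoulder medio-lateral coordinate with topographic prominence of at
  least 25% of the signal's interquartile range — the landmark is fixed by
  the cycle definition, the algorithm (prominence-filtered extrema) is
  ours, and the threshold is expressed relative to the signal so it needs
  no units. The first cycle is discarded (task onset), the next ten are
  kept; trials with fewer than ten remaining cycles are flagged
  `discarded`, a reported outcome rather than an error.
* **Sway amplitude** is the mean per-cycle peak-to-peak medio-lateral
  excursion of the lower back. "Distance covered" could also be read as
  path length; peak-to-peak excursion is the quantity actually manipulated
  by the maximum-amplitude condition, so it is the default and only
  implementation.
* **Sway frequency** is the argmax of the periodogram (Hann window, linear
  detrend, DC bin excluded) of the lower-back medio-lateral signal over
  the whole trial. The estimator resolution is one spectral bin
  (rate/N ≈ 0.017 Hz on a one-minute trial).
* **Time normalization.** Each selected cycle is interpolated onto 30
  phase points at 0, 1/30, …, 29/30 of the cycle (right-open, so
  consecutive cycles do not duplicate their shared boundary frame). All
  18 signals share one time base per cycle, which preserves inter-segment
  phase lags — verified by a cross-correlation test. Ten cycles × 30
  frames give the fixed 300 × 18 trial block.

## Amplitude normalization

Per trial, the mean posture is subtracted from every frame. The
"amplitude" of coordinate k in trial i is the mean absolute centered
excursion `m_ik`; the grand mean over trials, `m̄_k`, defines scaling
factors `f_ik = m̄_k / m_ik`, and the normalized values are
`psi_ijk = c_ijk * f_ik`. After this step every trial has mean absolute
amplitude exactly `m̄_k` in every coordinate (an algebraic identity,
asserted to 1e-9 relative), while the *relative* amplitudes between
coordinates — e.g. shoulder sway versus knee sway — are preserved. A
whole-posture-vector amplitude (mean Euclidean norm) is available as a
variant, but only the per-coordinate reading yields a per-coordinate
scaling factor, so it is the default. A coordinate with zero amplitude
raises an error naming trial and coordinate; silent division by zero is
never performed.

The fitted model (per-trial amplitudes, grand means, scale factors) is a
first-class object, persistable as JSON. Held-out trials are normalized
against *frozen* grand means (`normalize_with_model()`); this is also what
makes the normalization scale-invariant per trial — rescaling a trial's
raw coordinates by any positive constant cancels exactly.

## The self-organizing map

The map is a `rows × cols` square lattice (default 25 × 25 = 625 nodes) of
weight vectors with the input dimensionality (18 for postures, 600 for
trajectory vectors). Weights initialize uniformly within the
per-coordinate data range. Training is sequential: one iteration presents
every input vector once, in a freshly shuffled seeded order; each
presentation moves the BMU and its neighbors towards the input,

`w(t+1) = w(t) + h(t) * eta(t) * (psi - w(t))`,

with a Gaussian neighborhood `h = exp(-d^2 / (2 sigma(t)^2))` over
Euclidean lattice distance. The original analysis toolbox's exact schedule
defaults are not recoverable, so the schedules are explicit parameters:
sigma decays linearly from `max(rows, cols)/4` to 1 and eta from 0.5 to
0.01 over the iterations. BMU ties break to the smallest row-major node
index, making training fully deterministic given a seed. Updates with
neighborhood weight below 1e-7 are skipped; at the default schedules this
is numerically invisible but keeps the inner loop (written in C++, as SOM
implementations generally are) linear in practice.

Quality is tracked as quantization error (mean input-to-BMU distance) and
checked in tests via three properties: training never increases the
quantization error on its own data across seeds, a single repeated vector
is a fixed point (its BMU converges to it), and on 2-D inputs the
Spearman correlation between input distances and BMU lattice distances of
sampled pairs exceeds 0.5 (weak topology preservation).

Problem sizes: the package's defaults reproduce the reference geometry
(25 × 25, 1000 iterations over the full 113400 × 18 matrix). The test
suite and the acceptance script train the same geometry with 120
iterations on an 8000-row subsample — our chosen desk-scale working point,
at which the map is well organized (quantization error plateaus) and every
downstream group effect is stable across seeds. Both controls are ordinary
function arguments (`iterations`, `subsample`).

## TTvar and phase-resolved variability

A trial's 300 BMUs split into 10 cycles × 30 phases. For frame j (cycle c,
phase b), the per-frame variability entry is the mean Euclidean *lattice*
distance between the frame's BMU and the BMUs of the other 9 cycles at
phase b; TTvar is the sum of the 300 entries. Summing per-frame entries is
one of two readings of "summing all 300 entries" (the alternative sums 30
per-phase means); the two differ by a constant factor of 10, which cannot
affect group comparisons or monotonicity, and the per-frame reading is the
one that actually yields 300 entries. Distances are measured in lattice
coordinates because the trajectories, and the published variability
ellipses, live on the map; a weight-space variant is available behind
`ttvar(space = "weight")`. TTvar is non-negative, zero exactly when all
ten cycles retrace one lattice path, and invariant under relabeling of
the cycles.

Phases are classed as sway *endpoint* (the 7 phases centered on each
turning point — the left turn at the cycle boundary, phase 1, with its
window wrapping, and the right turn at mid-cycle, phase 16: 14 phases
total) or *traveling* (the remaining 16). Per phase, the variability
ellipse has horizontal and vertical radii equal to the SEM of the 10
cycles' BMU x and y coordinates and area `pi * h * v`; per-phase ellipses
are averaged within each sway phase.

Group differences in TTvar are tested with a two-sided Mann–Whitney U
test using midranks; for pooled samples of at most 12 the p-value is exact
by full enumeration, otherwise a tie-corrected normal approximation with
continuity correction is used (both paths are cross-checked against
independent oracles in the tests).

## Classification

Trajectory vectors stack each trial's 300 BMU x-coordinates then the 300
y-coordinates (length 600). Trials from the conditions in which the groups
differ in TTvar (3 and 5 by default) feed a second SOM with 600-d weights;
each trial's BMU on that map is its 2-D coordination signature. A kNN
classifier (k = 5) is evaluated over 100 stratified 70/30 splits;
stratification keeps both groups represented in every training set (the
splits would otherwise occasionally degenerate at small n). Vote ties —
possible through distance ties, or with even k — resolve to the single
nearest neighbor's label. The classifier can also run directly on the
600-d vectors (`features = "vectors"`); the 2-D map features are the
default because the second map, not the raw vectors, is the stated basis
for identifying group clusters. Accuracy is reported per run and as the
mean over runs.

On the default synthetic study the mean accuracy lands in the low 0.8s —
above chance, well below perfect — reflecting the overlapping
coordination-trait distributions described above. The permutation baseline
(labels shuffled) sits at 0.5 within sampling error, and perfectly
separated synthetic groups reach 1.0; both extremes are asserted in the
tests.

## Degenerate inputs and numerical conventions

* Frames and lattice coordinates are 0-based on the lattice (nodes at
  integer (x, y), x along columns), 1-based in R indices; phases are
  1-based.
* Coordinate convention: x is medio-lateral (positive to the subject's
  right), y vertical (up), z sagittal; meters. Fixed here for the whole
  package, since skeleton-capture exports vary.
* Monotone drift without oscillation is a `no_cycles` error; too few
  cycles is a `discarded` flag, not an error. Empty samples, dimension
  mismatches and out-of-range phases raise classed `invalid_argument`
  errors; structurally broken inputs (missing landmarks, non-monotone
  timestamps) raise `malformed_input`.
* Centering is verified before amplitude computation (a non-centered
  input triggers a classed warning); normalization's equal-amplitude
  post-condition is re-checked after application.

## Known limitations

* TTvar magnitudes depend on how much of the lattice a cohort's
  trajectories occupy, and therefore on map size, training length and
  cohort composition; only within-pipeline comparisons (between groups or
  conditions mapped on the same trained SOM) are meaningful.
* The generator's realism is a stand-in: no published quantitative
  description of the raw segment kinematics exists, so absolute TTvar
  values here are not comparable to values computed on human recordings.
* Sequential SOM training is order-dependent by construction;
  reproducibility is guaranteed only through the seed.
* The Mann–Whitney normal approximation is used above pooled n = 12;
  near that boundary its p-values can differ from exact ones by up to a
  couple of percent (bounded in tests at 0.02).
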