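---
title: "Methods: functional classification of retinal ganglion cell input"
author: "rgclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: functional classification of retinal ganglion cell input}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`rgclass` analyzes two kinds of data from retrograde-labeling
experiments in the retina: (1) trial-structured spike times of
individually recorded, retrogradely labeled retinal ganglion cells
(RGCs) responding to a standard light-stimulus battery, and (2) maps of
labeled cell positions on the flattened retina, one boolean label per
fluorophore channel. From the first it derives per-cell functional
metrics and a six-group classification whose proportions can be
compared between projection targets; from the second it derives the
spatial organization of the labeled populations. A synthetic-data
generator produces both kinds of input with known ground truth, which
is how the pipeline is validated.

# Spike-train metrics

## Spike density function

All rate estimates are spike density functions (SDFs): each spike
contributes a Gaussian kernel of standard deviation `bandwidth`
(default **25 ms**), kernels are summed on a 1-ms grid and averaged
across trials. Each spike's kernel is renormalized by the kernel mass
inside the analysis span, so the integral of the SDF equals the mean
spike count per trial even for spikes near the span edges. Kernel
evaluation is exact (truncated only beyond 8 bandwidths, where the
normal density is ~5e-15 of its peak) and implemented in C++; the test
suite checks it pointwise against a brute-force `dnorm()` sum at 1e-9
AP/s. The bandwidth is a configuration field and every metrics table
records the value it was computed with: the source analysis method does
not state a kernel width, so it must remain visible rather than baked
in.

## Latency, duration, polarity

*Latency* is the earliest time after the driving light transition at
which the SDF exceeds a threshold continuously for at least 50 ms, the
threshold being `baseline + 0.1 × (peak − baseline)` within the search
window. Two refinements matter in practice:

- The transition latency is measured from stimulus **onset** for ON and
  ON-OFF cells but from stimulus **offset** for OFF cells, whose
  response follows the light decrement. Without this, cells with high
  maintained rates (~10 AP/s) trigger the 10%-of-peak rule on baseline
  noise during the lit period.
- The threshold is baseline-referenced (the `baseline` argument of
  `detectLatency()`, default 0 so the bare fraction-of-peak rule is
  preserved for callers that want it).

*Response duration* is the integral of the SDF over a 500-ms window
starting at latency, divided by the peak response and the window
length; 1 means firing at peak throughout, values near 0 mean a brief
transient. The pipeline normalizes by the peak of the whole response
window rather than the duration window alone, so that a spuriously
early latency cannot make a transient cell look sustained (the window
would then contain only baseline, and baseline/peak is small).

*Polarity* compares baseline-subtracted onset and offset component
peaks through the on–off index `(on − off)/(on + off)`: ON at or above
+0.5, OFF at or below −0.5, ON-OFF in between, no label when the larger
component is below the responsiveness floor (5 AP/s). Two pipeline
safeguards keep the maximum-over-window statistic honest: each
component is searched only within 0.6 s of its transition, and a
component only counts as evoked if its peak clears the baseline noise
floor of the SDF — the spontaneous rate plus `polarityNoiseK` (default
2) standard deviations estimated from the pre-stimulus segment.
Otherwise the silent component of a tonically active cell accrues 2–3
SD of noise and drags the index toward 0.

## Tuning curves and derived metrics

Per-condition responses are the peak of the trial-averaged SDF in the
response window (stationary spots: onset to 0.6 s after offset; drifting
stimuli: the transit window). The best size is the measured argmax
(ties toward the smaller stimulus); the interpolated best size is the
argmax of a four-parameter gamma-function fit
`R(x) = baseline + amplitude · g(x)/g(mode)` with
`g(x) = (x/scale)^(shape−1) e^(−x/scale)`, fitted by
Levenberg–Marquardt from four starting shapes (1.5, 2, 3, 5) under
non-negativity bounds. The normalization makes `amplitude` the fitted
peak above baseline, so the degenerate flat-curve limit is `amplitude =
0` (solved analytically and flagged `"flat"`). A fitted mode at or
beyond the largest tested stimulus is flagged
`"unbounded_within_range"` and clipped to twice the tested maximum; a
failed fit is flagged, never silent, and the interpolated best falls
back to the measured argmax. Tuning width is the trapezoidal integral
of the measured points divided by the peak — a flat curve gives the
full stimulus range, which is also the upper bound.

The temporal cutoff frequency is the lowest frequency above the
response maximum at which the response crosses half-maximal, located by
linear interpolation on a log2 frequency axis between the tested
frequencies (1, 2, 4 Hz in the standard battery); cells whose response
never falls below half-maximum within the tested range have no cutoff
(`NA`), which is itself informative.

## Direction selectivity

Direction tuning is summarized by the normalized vector sum length
`NVSL = |Σ rⱼ e^{iθⱼ}| / Σ rⱼ` over the eight tested directions, and
the preferred direction is the vector-sum angle. NVSL is invariant to
positive rescaling of all responses, and — because the tested
directions are symmetric — to adding any constant to all responses.

The per-direction response `rⱼ` is, by default, the **mean spike count
per trial during the bar transit**. The alternative — the peak of the
trial-averaged SDF — is available via
`metricsConfig(directionMode = "peak")`. The count was chosen as the
default after measuring both on synthetic direction-selective cells
(von Mises concentration 2, 5 trials per direction, 60 AP/s peak):
the transit count integrates the whole response and estimates the
preferred direction with an angular error SD of about 3.5 degrees,
while the peak statistic — a maximum over a smoothed, noisy trace —
has an error SD near 6 degrees, too noisy to place 95% of cells within
±10 degrees of ground truth. The package's direction-recovery tests
and the acceptance script quantify this under exactly those
conditions.

# Classification

The classifier is a fixed decision list over the metrics, with every
threshold in `classifierThresholds()`:

1. ON-OFF polarity and NVSL > `nvsl_ds` (default **0.2**) →
   `ON_OFF_DS`.
2. OFF polarity → `OFF_SUSTAINED` if response duration ≥
   `duration_sustained` (default **0.4**), else `OFF_TRANSIENT`.
3. ON polarity → `ON_SMALL_TRANSIENT` if transient **and** size-tuning
   width < `small_width_max` (default **500 μm**); otherwise
   sustained/transient by duration.
4. Anything else — unresponsive cells, cells with missing
   prerequisites, and ON-OFF cells without direction selectivity — is
   `UNCLASSIFIED`.

The `duration_sustained = 0.4` default sits in the gap between the
sustained (~0.6–0.7) and transient (~0.15–0.3) duration modes the
generator produces, and sweeping it over \[0.3, 0.5\] is a
configuration change, not a code change. The ≤200-μm best-size
criterion for the small-transient group is advisory: the label is
assigned on the width criterion alone and `small_size_advisory` flags
calls whose measured best size exceeds 200 μm. Narrow-width OFF cells
are kept as `OFF_TRANSIENT`; no seventh class is invented. On-Off
cells failing the NVSL criterion are left unclassified rather than
forced into a group — this is the package's own handling of the
remainder, since the upstream grouping does not define one.

# Population statistics

Class proportions between projection groups are compared with the 1-df
Pearson χ² on 2×2 tables, **without** continuity correction by default:
on the table \[\[45,44\],\[36,67\]\] the uncorrected statistic is 4.77
(p ≈ 0.029) while the Yates-corrected one is weaker (p ≈ 0.042), and
only the uncorrected version reproduces the published significance
bound for that comparison; the correction is a flag, and it provably
never increases the statistic (property-tested). Rank comparisons use
the Wilcoxon–Mann–Whitney test, exact when the smaller sample has ≤8
observations and there are no ties (verified against full enumeration
of rank assignments for all n, m ≤ 6), and the tie-corrected normal
approximation otherwise. All tests are two-sided; sidedness was not
stated upstream, so the conservative default is used.

Labeling fractions come with Wilson 95% intervals (via `prop.test`
without correction), and replicate retinas are summarized as mean ±
SE of the per-retina fractions. Co-labeling fractions are computed
inside a density mask: the retina is binned on a square grid (default
**100 μm**) and cells of the reference channel count only in grid
cells whose density is at least `minDensity` (default **0.25**) of the
peak — "densely labeled" is qualitative in the source, so the mask
parameters are reported with every output.

# Retinotopy of labeled-cell maps

Each channel's point cloud gets a moment-based 2D Gaussian fit: center
= sample mean, axes = square roots of the covariance eigenvalues,
orientation = major-eigenvector angle. The eigenvalue convention was
chosen over an axis-aligned variant (also derivable from the fit's
covariance slot) because the fitted "standard deviation" should not
depend on how the retina happened to be oriented on the microscope.
Centroid vectors from the optic nerve head (the coordinate origin by
convention; angles counter-clockwise from +x) give the angular
separation (wrapped to \[0, 180\]) and the inter-centroid distance;
spatial exclusivity is tested by counting points of one channel within
k Mahalanobis standard deviations (default 2, boundary inclusive) of
the other channel's center. Fitting uses cell coordinates, not
fluorescence intensity — positions are assumed already extracted from
the images; an intensity-grid variant would be an extension, not a
replacement. Anatomical (nasal/temporal) axes are deliberately not
assigned: tissue orientation is not always tracked at dissection, so
angles are reported in retina-intrinsic coordinates.

# The synthetic-data generator

The generator exists so that every downstream metric has a testable
ground truth. Each cell class is a parameter bundle
(`cellTypeParams()`) driving a separable rate model: spontaneous rate
plus `peak_gain × contrast × size gain × direction gain × speed gain ×
temporal gain × kernel(t)`, where the kernel is an exponential decay
(time constant `kinetics_tau`) triggered at stimulus onset, offset, or
both according to polarity, and gated off when the stimulus ends.
Direction gain is von Mises (`exp(κ(cos Δθ − 1))`, flat at κ = 0),
size and speed gains are mode-normalized gamma functions, and the
temporal-modulation gain is a first-order low-pass
`1/√(1 + (f/f_c)²)`. Moving-bar protocols use a transit envelope whose
time constant is `max(kinetics_tau, 240 μm / speed)`: a bar drives a
cell for as long as it crosses the receptive-field region, so even
step-transient cells respond throughout the transit. Spikes are drawn
by discrete-grid thinning (1-ms bins, at most one spike per bin with
probability `1 − exp(−r dt)`), all randomness from a single generator
stream seeded once with the master seed. Per-cell keyed streams were
considered and rejected: streams keyed by consecutive integers are
mutually correlated in Mersenne–Twister, which measurably distorts
population-level recovery rates.

Default class parameters (the simulated study conditions): peak gain
**120 AP/s** for all classes, matching the response scale of the
recordings this emulates; sustained classes use a 600-ms kernel and
transient classes 50 ms, so the generated duration metric is bimodal
around ~0.65 vs ~0.2; the small-transient ON class has gamma size
tuning with mode 80 μm (shape 3, scale 40 μm) versus mode 400 μm
(shape 2, scale 400 μm) for broad classes; the ON-OFF DS class has
κ = 4 with a uniformly random preferred direction per cell; maintained
rates range from 1 AP/s (small-transient ON) to 8 AP/s (sustained
OFF). The default population composition mirrors the characterized
cohorts — e.g. 10/89 dLGN-projecting versus 20/103 SC-projecting
ON-OFF DS cells — and group-specific overrides give transient-OFF
cells a high maintained rate and high temporal cutoff in the
dLGN-projecting group (10.7 AP/s) versus low in the SC-projecting
group (1.8 AP/s), the printed projection-specific difference. The
sustained/transient split of ON cells is not itemized upstream; the
defaults put sustained ON cells in the majority for the
dLGN-projecting group and transient ON cells for the SC-projecting
group, consistent with the reported direction of the asymmetry.

Retinal maps are isotropic Gaussian clusters (default 500 cells,
SD 150 μm) at configurable centroid-vector angles ~875 μm from the
optic nerve head (inter-centroid distance ≈ 1,750 μm), resampled to
stay within the retina radius, with reference-channel cells carrying a
test label with probability `colabel_prob`.

**What the generator does not emulate** — and hence what passing tests
do not show about real data: no receptive-field spatial structure
beyond scalar size tuning, no contrast-response saturation (contrast is
a linear gain), no adaptation or serial correlation across trials, no
between-cell parameter variability within a class other than preferred
direction, no non-Poisson spiking statistics, and no anisotropic or
eccentricity-dependent labeling density. Classification recovery on
synthetic data therefore validates the estimator/classifier chain, not
the biological separability of real cell types.

# Problem sizes and numerical choices

The validation suite runs at deliberately chosen sizes: 200 cells per
class (1,200 total) for classification recovery, 200 cells for
preferred-direction recovery under the reference conditions (κ = 2,
5 trials/direction, 60 AP/s peak), 200 simulated retinas per true
angle for separation recovery, and 5 trials per stimulus condition
throughout — the trial count of the emulated protocol. Simulation grids
use 1-ms steps; SDF grids likewise. Gamma fits cap Levenberg–Marquardt
at 200 iterations per start. Tabular output writes doubles with 17
significant digits so write→read round trips are bit-exact. All
analysis operations are deterministic given their inputs; all
stochastic steps take explicit seeds.

# Known limitations

- The latency rule is threshold-based and inherits the noise of the
  SDF; with few trials and high maintained rates its variance is
  substantial even with the baseline-referenced threshold.
- The 500-μm small-transient width bound sits about two measurement
  SDs below the broad-class width under the default conditions, so a
  few percent of transient ON cells fall below it by chance; such calls
  are flagged by the advisory best-size check rather than suppressed.
- The gamma tuning-curve form is one concrete, documented choice; the
  upstream analysis cites a fit without printing its parameterization.
- Contrast-response functions are out of scope: the generator treats
  contrast as a scalar gain and the pipeline computes no contrast
  metrics.
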