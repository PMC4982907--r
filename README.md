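# rgclass

Functional classification of retinal ganglion cell (RGC) input to
retinorecipient brain areas.

Which kinds of visual information does each retinorecipient structure
receive? One way to answer this is to retrogradely label the RGCs that
project to a target — for example the superior colliculus (SC) or the
dorsal lateral geniculate nucleus (dLGN) — record the labeled cells'
spike responses to a standard battery of light stimuli, sort the cells
into functional groups, and compare the group proportions between
projection targets. `rgclass` implements that analysis end to end for
cell-attached recordings and retrogradely labeled retinal cell maps,
together with a synthetic-data generator with known ground truth, so
every stage of the pipeline can be validated without access to raw
recordings.

## What it computes

**Per-cell metrics** from trial-structured spike times and stimulus
epochs:

- **Spike density function (SDF)** — Gaussian-kernel rate estimate
  r(t), trial-averaged and edge-corrected so that ∫ r(t) dt equals the
  mean spike count per trial (default bandwidth 25 ms).
- **Response latency** — earliest time after the driving light
  transition at which the SDF exceeds 0.1 × peak continuously for at
  least 50 ms.
- **Response duration** — ∫ SDF over a 500-ms post-latency window,
  divided by (peak response × window length); ≈1 for sustained cells,
  ≈0 for transient ones.
- **Direction selectivity** — normalized vector sum length
  NVSL = |Σⱼ rⱼ e^{iθⱼ}| / Σⱼ rⱼ over 8 motion directions, with the
  preferred direction as the vector-sum angle.
- **Size and speed tuning** — best stimulus (measured argmax and the
  argmax of a gamma-function fit
  R(x) = b + a·(x/s)^{k−1}e^{−x/s}/g(mode)), and tuning width as the
  normalized area (trapezoidal integral / peak) of the tuning curve.
- **Temporal cutoff frequency** — the frequency at which responses to
  sinusoidal luminance modulation fall to half-maximal (log₂-linear
  interpolation between tested frequencies).
- **Polarity** — ON / OFF / ON-OFF from the on–off index
  (on − off)/(on + off) of baseline-subtracted onset and offset peaks.

**Classification** into six functional groups by explicit rules
(thresholds are configuration, not code): ON-OFF direction-selective
(NVSL > 0.2), sustained and transient OFF, sustained and transient ON,
and small-transient ON (transient ON cells with size-tuning width
< 500 μm, the "W3-like" phenotype).

**Population statistics**: 2×2 Pearson χ² tests on class-by-target
contingency tables (continuity correction off by default, switchable),
exact Wilcoxon–Mann–Whitney rank tests for small samples, Wilson
confidence intervals for labeling fractions, and density-masked
co-labeling fractions for double-retrograde-label experiments.

**Retinotopy** of labeled-cell maps: moment-based 2D Gaussian fits to
each fluorophore's point cloud, centroid vectors from the optic nerve
head (angle, distance), angular separation between population centers,
and Mahalanobis 2-SD overlap counts.

**Synthetic data**: an inhomogeneous-Poisson spike generator driven by
a separable response model (polarity kernel × von Mises direction gain
× gamma size/speed gains × low-pass temporal gain) covering the full
stimulus battery, plus simulated two-channel retinal label maps — both
with stored ground truth.

## Worked example

Simulate a small cohort (3 cells per class and projection group),
compute metrics, classify, and tabulate:

```r
library(rgclass)

cfg <- defaultPopulationConfig()
cfg$composition$n <- rep(3, nrow(cfg$composition))
ds <- simulateExperiment(cfg, seed = 7)

metrics <- computeCellMetrics(ds)
head(metrics[, c("cell_id", "polarity", "nvsl", "response_duration",
                 "best_size_um", "size_tuning_width_um")], 4)
#>   cell_id polarity   nvsl response_duration best_size_um size_tuning_width_um
#> 1   c0001   ON_OFF 0.5150             0.378          400                  607
#> 2   c0002   ON_OFF 0.5430             0.349          400                  610
#> 3   c0003   ON_OFF 0.4386             0.319          200                  560
#> 4   c0004      OFF 0.0263             0.619          800                  682

labels <- classifyCells(metrics)
tabulateClasses(labels, groups = c("dLGN", "SC"))
#>                     group
#> class                dLGN SC
#>   ON_OFF_DS             3  3
#>   OFF_SUSTAINED         3  3
#>   OFF_TRANSIENT         3  3
#>   ON_SUSTAINED          3  3
#>   ON_TRANSIENT          2  3
#>   ON_SMALL_TRANSIENT    4  3
#>   UNCLASSIFIED          0  0
```

The first three cells are ON-OFF direction-selective: both onset and
offset responses (`polarity ON_OFF`), strong direction tuning
(`nvsl` ≈ 0.44–0.54, well above the 0.2 criterion). Cell `c0004` is a
sustained OFF cell: offset-driven, long response duration (0.62), broad
size tuning (682 μm). One transient ON cell's measured width fell just
under the 500-μm bound and was routed to the small-transient group —
such boundary calls carry the `small_size_advisory` flag.

Comparing class proportions between projection targets uses the same
machinery as published counts. For 45/89 ON cells labeled from one
target versus 36/103 from the other:

```r
res <- chiSquare2x2(matrix(c(45, 36, 44, 67), 2))
sprintf("chi2 = %.2f, p = %.3f", res$statistic, res$p.value)
#> "chi2 = 4.77, p = 0.029"
```

A command-line front end wraps the same functions
(`inst/scripts/rgclass-cli.R`, subcommands
`simulate | metrics | classify | compare | retinomap`).

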