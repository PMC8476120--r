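# collapseKinetics

Quantifying how clusters of myosin motors bind to — and, strikingly, release
from — regulated thin filaments, from single-molecule fluorescence
kymographs.

## The science

Single myosin-S1 heads carrying GFP-tagged light chains decorate actin
"tightropes" (thin filaments regulated by tropomyosin and troponin) under
metastably activating conditions: near half-maximal calcium and low ATP.
Imaged at 3.3 frames/s (0.3 s frames, 126.4 nm pixels), each filament gives
a kymograph in which clusters of bound myosins — *active regions* — appear
as vertical streaks whose brightness counts the bound heads.

If heads release independently, driven by ATP binding, the per-frame
detachment probability of one head is

> P<sub>d</sub> = 1 − e^(−k<sub>T</sub>·[ATP]·t) = 1 − e^(−1.9 × 0.1 × 0.3) = 0.0554

(k<sub>T</sub> = 1.9 µM⁻¹s⁻¹, [ATP] = 0.1 µM, t = 0.3 s; the single-head
detachment rate constant is k<sub>T</sub>[ATP] = 0.19 s⁻¹), and the chance
of an *i*-head cluster emptying in one frame is P<sub>d</sub><sup>i</sup> —
vanishingly small for large clusters. The package measures the
frame-to-frame cluster-size **transition matrix** (rows: starting size 1–6,
columns: final size 0–6, zero diagonal), its model-predicted twin built
from P<sub>d</sub> and the empirically estimated attachment probability
P<sub>a</sub> (mean of the first superdiagonal, 0.15 in this system), the
**collapse-probability curve** (the matrix's first column), and the
effective detachment rate constant obtained by inverting it,
k = −ln(1 − P^(1/i))/t. A measured first column orders of magnitude above
P<sub>d</sub><sup>i</sup> is the signature of *catastrophic collapse* —
concerted release of the whole cluster.

The pipeline reproduces the full measurement chain: rolling-ball background
subtraction (radius 50 px) → per-frame multi-Gaussian peak fitting with BIC
model selection → per-kymograph photometric calibration (sum-of-Gaussians
histogram fit, mean ± 2 SD assignment bands, straight-line check of
intensity vs count) → nearest-neighbour track linking → transition
matrices, collapse curves and rate inversion. A ground-truthed stochastic
simulator with a Gaussian point-spread renderer makes every stage testable,
and a reversible-jump MCMC sampler for normal mixtures with an unknown
number of components provides the independent, bias-checking route from
pixel intensity to myosin count (mid-point cut-offs between successive
component means; the bundled nine-component reference table gives 81.55 for
the background/one-binder boundary).

## Worked example

Simulate six kymographs at the study conditions (P<sub>a</sub> = 0.15,
P<sub>d</sub> = 0.0554, no concerted channel), run the full image pipeline,
and compare the measured collapse curve with the binomial prediction:

```r
library(collapseKinetics)

cfg <- pipelineConfig(
  simulate = list(nKymographs = 6L, nFrames = 300L, initialSizes = c(4L, 2L)),
  imaging  = list(noiseSd = 4, unitIntensityCv = 0.1),
  seed = 11)
report <- runPipeline(cfg)

report$paEstimate
#> [1] 0.132        # generative value 0.15, 645 transitions
report$collapse[, c("size", "probability", "predicted", "nObs")]
#>   size probability predicted nObs
#> 1    1      0.0606    0.0554  561
#> 2    2      0.0050    0.0031  602
#> 3    3      0.0018    0.0002  563
#> 4    4      0.0000    0.0000  368
#> 5    5      0.0000    0.0000  187
#> 6    6      0.0000    0.0000   57
```

The measured first column tracks P<sub>d</sub><sup>i</sup>: no excess.
Adding a concerted collapse channel (20% per frame for clusters of two or
more) reproduces the catastrophic-collapse contrast — the same pipeline,
`simulate = list(..., pc = 0.2)`, now reports probabilities of 0.17–0.31
across sizes 2–4 where independent release predicts 0.003 down to 10⁻⁵,
`report$excessCollapse` is `TRUE`, and inverting the curve yields effective
detachment rate constants rising from ≈1.8 s⁻¹ at size 2 to ≈4.6 s⁻¹ at
size 4 (`report$rates`) against the single-head 0.19 s⁻¹.

Every intermediate artifact (background-subtracted TIFF, peak CSV,
calibration JSON, track CSV, matrix/collapse/rate CSVs, JSON report with a
config hash) is written when `runPipeline(cfg, outDir = ...)` is given an
output directory, and `inst/scripts/run_pipeline.R` wraps the same call for
the shell. The methods vignette
(`vignettes/collapse-kinetics-methods.Rmd`) documents the model, every
tunable parameter and the design decisions.

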