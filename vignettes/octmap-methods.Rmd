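---
title: "Automated coronary-calcium mapping in polar OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated coronary-calcium mapping in polar OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octmap)
```

## The problem

Intravascular optical coherence tomography (OCT) images a coronary artery
from inside: a rotating catheter records one radial intensity profile
(an *A-line*) per angular position, and a *pullback* stacks hundreds of such
polar frames along the vessel. Calcified plaque on these images governs how
a lesion should be prepared before stenting — heavily calcified segments
risk stent under-expansion — and is graded clinically by a 0–4
*OCT-calcium score*: 1 point for maximum calcium thickness > 0.5 mm,
2 points for maximum arc > 180°, 1 point for length > 5 mm, all strict
inequalities, with scores 3–4 called severe.

`octmap` implements the full desk-scale pipeline behind such a grading
tool: a seeded synthetic phantom with per-pixel ground truth, polar
preprocessing with an attenuation-coefficient channel, artifact
augmentation, a UNet-like ten-class pixel segmenter trained with a
cross-entropy + soft-Dice objective, calcium quantification, and the
evaluation statistics used to validate it (per-class ROC/AUC, Youden
thresholds, plaque confusion matrices, angular Dice, Pearson/Spearman/ICC
agreement). No clinical data ships with the package; the phantom generator
is a first-class, tested module that defines the study conditions for every
benchmark the package reports.

## The phantom: what it emulates and what it does not

Each synthetic frame is built as a per-A-line mean intensity profile
multiplied by speckle:

* **Geometry.** A catheter ring sits at the frame centre; the lumen is a
  near-zero (blood-cleared) region out to a smoothly varying radius
  (two Fourier harmonics with seeded coefficients); a thin bright band marks
  the lumen boundary; tissue follows.
* **Optics.** Reflected intensity inside tissue decays with the round-trip
  law `I(z) = I0 * exp(-2 mu z)` along the optical path, with a cumulative
  optical depth across layer boundaries. Each class has an entrance
  reflectivity and an attenuation coefficient: fibrous tissue is
  signal-rich and moderately attenuating (default reflectivity 1.0,
  mu = 1.8/mm), calcium signal-poor with sharp borders and *low*
  attenuation (0.35, 1.0/mm), lipid signal-poor with a diffuse border and
  *high* attenuation (0.55, 6.0/mm), generic wall tissue in between
  (0.75, 2.2/mm). The ordering — lipid high, calcium low — is the standard
  discriminator in OCT plaque reading; the numeric defaults sit in the range
  of published ex vivo estimates and were fixed once, before any benchmark
  was run. Lipid's diffuse border is produced by box-smoothing its radial
  reflectivity profile (7 px default); calcium's border is left sharp.
* **Speckle.** First-order OCT speckle is modelled as multiplicative
  gamma-distributed noise with mean 1 (shape 4 by default; larger = smoother).
* **Artifacts in the scene.** A bright guidewire arc casts a zeroed radial
  shadow; beyond a configurable penetration depth (2 mm default) pixels are
  labelled background.
* **Labels.** The ten pixel classes are: background, lumen interior,
  catheter, lumen boundary, guidewire, guidewire shadow, wall tissue,
  calcium, fibrous, lipid. Seven of these are the classes any polar OCT
  annotation scheme must contain; the residual three (background beyond
  penetration, lumen interior, catheter ring) are the unavoidable remaining
  regions of a polar frame and are flagged as a provisional choice. Labels
  are purely geometric (the generating class per pixel), so analytic
  sector-area oracles hold exactly up to grid quantization.

What the phantom does **not** emulate: blood-clearance failure, stents,
thrombus, plaque rupture, side branches, eccentric catheter position,
sew-up/saturation artifacts, or the texture statistics of real tissue.
Passing the package's benchmarks therefore demonstrates that the
architecture, losses, quantification and statistics are implemented
correctly and can learn the optical signatures the phantom encodes — it is
a synthetic proxy, not evidence of clinical performance.

## Preprocessing

The network consumes two channels, both normalized to [-1, 1] by the exact
affine map `(x - 127.5) / 127.5`:

1. **Log-compressed intensity** — `log(1 + I)` affinely rescaled to
   [0, 255]. (Whether "log-scale" should compress intensity or warp the
   radial axis is ambiguous in the field's usage; intensity compression was
   chosen and the radial axis kept linear.)
2. **Attenuation channel** — a per-pixel depth-resolved estimate
   `mu_hat[i] = I[i] / (2 * dr * sum(I[j], j > i))` computed on the
   *linear* (un-compressed) intensities, for which the estimator is exact
   on noiseless single-exponential decay up to discretization
   (`(exp(2 mu dr) - 1) / (2 dr)`, a +`mu dr` relative bias) and tail
   truncation. The estimate is clipped at `mu_max` (10/mm default, above
   any tissue of interest), scaled to [0, 1], gamma-adjusted (`x^gamma`,
   default gamma 0.5 to brighten low attenuation) and rescaled to [0, 255].
   The final `attenuation_window` samples (32 default) are masked to zero
   because the truncated tail sum makes the estimator blow up there;
   all-zero A-lines yield zero channels rather than division errors.

The attenuation channel is what makes the plaque classes nearly separable
per pixel: calcium is dark with a *dark* attenuation channel, lipid dark
with a *bright* one, fibrous bright.

## Artifact augmentation

Three seeded, label-consistent artifact models compose in a fixed order
(NURD → motion → reflection) so one seed fixes the stream:

* **NURD** (non-uniform rotational distortion): a single-harmonic angular
  displacement `theta' = theta + A sin(2 pi f theta / 360 + phase)`,
  image linearly interpolated, labels nearest-neighbour, wrap-around at
  360°. Warps with `A f (2 pi / 360) >= 1` would be non-monotone and are
  rejected. The defaults (A = 1.5°, f = 1) keep the warp mild: an arc of
  width `w` degrees changes pixel count by at most about `2A / w`, well
  under 5% for the plaque arcs the phantoms produce.
* **Motion**: a signed radial shift applied jointly to all A-lines;
  pixel (r, θ) maps to (r + s, θ), vacated pixels are zero-filled and
  labelled background.
* **Multiple reflection**: a ghost copy of each A-line's proximal half
  added at double depth with gain in [0, 1], clipped to [0, 255]; labels
  unchanged (the ghost is optical, not tissue).

Magnitudes and per-artifact probabilities are uncalibrated choices (no
reference values exist for the single-harmonic model); they are configurable
in `augmentConfig()`.

## The segmenter

`buildNetwork(netConfig())` constructs a UNet-like encoder–decoder over the
two-channel polar tensor:

* **Contracting path**: four blocks of two 3×3 convolutions + ReLU,
  followed by 2×2 max-pooling and dropout (rate 0.1 default; the value is
  an assumption, as is everything this paragraph flags); filters start at
  16 and double per block (16, 32, 64, 128), with a 256-filter two-convolution
  bottleneck at the bottom.
* **Expanding path**: per level, nearest-neighbour 2× upsampling followed
  by a 3×3 convolution + ReLU (upsample-then-convolve rather than transposed
  convolution), concatenation with the matching encoder activation (the
  feature bridge), and a second 3×3 convolution + ReLU.
* **Head**: a 1×1 convolution to 10 channels and a per-pixel softmax, so the
  output is a valid probability field.

Input height and width must be divisible by 2^depth = 16. The forward and
backward passes are compiled (RcppArmadillo, im2col + GEMM); gradients are
verified against central finite differences in the test suite.

**Objective.** `mix * CE + (1 - mix) * (1 - softDice)` with `mix = 0.5` by
default; CE is the mean over pixels of `w[y] * -log p[y]` and the soft Dice
is the loss-weight-averaged per-class `(2 sum(p t) + eps) / (sum p + sum t
+ eps)` with `eps = 1e-6`. All ten class weights default to 1, so the three
plaque morphologies are equally weighted. Optimization is Adam
(lr 1e-3, beta 0.9/0.999, no schedule) — a conventional baseline, since no
reference prescribes the optimizer. Dropout masks, initialization
(He-normal) and shuffling all derive from the single training seed, so a
fixed seed reproduces the loss trajectory exactly in single-threaded BLAS.

**Splits.** `trainSegNet()` splits at the *pullback* level and refuses any
identifier appearing in both splits, so validation frames always come from
vessels the optimizer never saw. The checkpoint returned is the epoch with
the best validation metric (mean plaque-class soft Dice by default).

## Quantification

`extractPlaques()` finds angularly connected components of a plaque class
with 8-connectivity on the polar grid and wrap-around across θ = 0/360
(vertical runs per column united by a union–find across adjacent columns
and the seam). Per component:

* **arc** — angular extent in degrees (a connected component's occupied
  columns always form a circular interval). Because the polar grid's
  A-lines emanate from the catheter axis, the angular extent in the grid
  *is* the arc referenced to the lumen region for the concentric phantom
  geometry; a lumen-centroid re-projection is not performed.
* **thickness** — per-A-line radial pixel extent × radial resolution,
  minimum and maximum over the component's A-lines. Thickness is measured
  radially (deterministic in acquisition geometry), not normal to the
  plaque surface.
* **truncation** — if the component's abluminal border abuts a signal void
  (guidewire shadow or background, or the frame edge), the thickness is
  reported with `truncated = TRUE` rather than guessed, mirroring the
  posterior-shadowing limitation of near-infrared imaging.

`lesionLength()` implements both reading conventions: `every_frame`
(automated reading — consecutive frames are contiguous when their calcium
arcs share at least one 1° bin; length = run count × frame spacing) and
`interval_quadrant` (manual reading — frames sampled every 1 mm, contiguity
requires calcium in the same fixed 90° quadrant, quadrants
[0,90), [90,180), [180,270), [270,360); length = run count × interval).
Length is counted as *run count × spacing* — each frame stands for one
spacing of tissue — since "span vs count" is underdetermined; a
single calcified frame therefore has length one spacing, not zero. When
multiple plaques share a frame, the lesion summary uses per-lesion maxima
(max arc, max thickness over all records), the natural reading of a
worst-feature score.

`octCalciumScore()` applies the strict-threshold rule; equality at a
threshold earns no point. `dichotomize()` maps scores 3–4 to `"severe"`.

## Evaluation statistics

* **ROC/AUC** — thresholds at midpoints between consecutive distinct
  scores (plus sentinels), sensitivity/specificity from cumulative counts,
  AUC as the Mann–Whitney rank statistic (identical to the trapezoid of
  this curve, and invariant under monotone transforms).
* **Youden** — maximizes J = sens + spec − 1; ties break toward the lower
  threshold; perfectly separated classes yield the midpoint of the gap.
* **Plaque confusion** — 3×3 over (calcium, fibrous, lipid), restricted to
  pixels that are plaque in *both* truth and prediction, so row sums equal
  ground-truth counts on the evaluated subset; accuracy = trace/total;
  precision by column, recall by row, F1 harmonic.
* **Angular (1-D) Dice** — `2|A∩B| / (|A|+|B|)` on 1° bins; two empty arcs
  are defined as agreement 1.
* **Agreement** — Pearson r with Fisher-z 95% CI, Spearman rho, and
  ICC(2,1): two-way random effects, absolute agreement, single measure,
  computed from the ANOVA decomposition with an F-distribution interval.
  ICC(2,1) was chosen because absolute agreement is the relevant notion for
  method comparison (a rescaled measurement should *not* score 1); the CI
  method (F-based, Shrout–Fleiss) is a package choice, as is using Pearson
  for thickness-like quantities and Spearman for arcs and scores.

## Benchmark problem sizes

The package's end-to-end benchmark (in the test suite) trains the default
network (base 16, depth 4) on 200 phantom frames of 64 × 128 px at
0.04 mm radial resolution (2.56 mm imaging depth), 8 pullbacks for training
and 2 held out, 6 epochs, batch 4, one fixed seed. On these conditions the
held-out calcium pixel AUC exceeds 0.99 and 3-class plaque accuracy exceeds
0.95, against acceptance floors of 0.90 and 0.70. Parameter-recovery checks
run on 100 frames at 256 × 480 px (0.01 mm pixels, 0.75° bins), where
extracted arcs land within one angular bin and thicknesses within one
radial pixel of the generating values. The scoring-rule worked examples in
`scripts/acceptance.R` rebuild each lesion as a phantom, re-measure it off
the label map, and score it.

## Numerical and degenerate-input choices

* Constant frames map to constant frames under log compression (the affine
  rescale is degenerate there).
* All-zero A-lines produce zero attenuation channels; the distal
  `attenuation_window` samples are masked.
* Speckle, dropout, shuffling, augmentation draws and phantom geometry all
  flow from explicit integer seeds; generation is bit-reproducible.
* Score inputs exactly at a threshold score zero points for that criterion
  (strict inequalities).
* `dice1D(empty, empty) = 1`; ROC requires at least one positive and one
  negative and refuses otherwise; agreement statistics refuse zero-variance
  inputs.
* TIFF I/O is 8-bit; write-then-read round-trips are bit-identical for
  8-bit content, and metadata/TIFF dimension mismatches are reported with
  both shapes.

## Known limitations

* The phantom's concentric geometry makes arc measurement exact by
  construction; eccentric catheters in real data would require lumen-centred
  re-projection before the arc is clinically interpretable.
* The attenuation estimator carries a +`mu dr` discretization bias and a
  truncation bias near the end of the imaging window; both are negligible
  for `mu <= 3/mm` at 0.01 mm pixels but grow with `mu`.
* The segmenter is CPU-bound and desk-scale; clinical resolutions
  (~1000 × 500 px, hundreds of frames) would need a GPU implementation.
* Training on phantoms cannot transfer to clinical pullbacks; the package
  provides the machinery, not trained clinical weights.
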