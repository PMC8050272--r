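---
title: "Quality control of deep-learning microscopy models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality control of deep-learning microscopy models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microQC)
```

# Why quantitative QC

A trained model that produces visually plausible microscopy output can
still be unreliable: denoisers hallucinate structure, segmenters merge
touching nuclei, detectors mislabel cell shapes. The only defensible check
is quantitative comparison against held-out ground truth, with per-pixel
error maps so failures can be localised rather than averaged away. This
vignette documents the models and conventions behind each metric, the
parameters that matter, and the design decisions taken where the
literature leaves choices open.

# Restoration metrics

## Normalisation pipeline

Restoration networks are free to change intensity scale and offset, so raw
intensity comparisons are meaningless. The package's convention:

1. the **target** (ground truth) is percentile-normalised,
   `(x − P(pmin)) / (P(pmax) − P(pmin))` with defaults `pmin = 1`,
   `pmax = 99.9` (robust against hot pixels; values are *not* clipped);
2. **source** and **prediction** are mapped onto the normalised target by
   the closed-form least-squares affine fit `alpha·x + beta`. This makes
   every downstream metric invariant to affine intensity rescaling of the
   compared image, which is the comparison convention of the
   content-aware restoration ecosystem. The fitted `(alpha, beta)` are
   recorded; a zero-variance image cannot be fitted and is flagged.

## SSIM

`ssimMap()` computes the structural-similarity map with Gaussian-weighted
local means, variances and covariance:

$$\mathrm{SSIM}(p) = \frac{(2\mu_1\mu_2 + C_1)(2\sigma_{12} + C_2)}
                          {(\mu_1^2+\mu_2^2+C_1)(\sigma_1^2+\sigma_2^2+C_2)}$$

with the standard constants $C_i = (K_i L)^2$, $K_1 = 0.01$, $K_2 = 0.03$,
data range $L = 1$ on normalised inputs, an 11-pixel window and window
sigma 1.5 px. These are the classic defaults of the metric's authors; the
source literature cites the metric without parameters, so the defaults are
exposed in `ssimParams()` and recorded in reports. Windows use replicated
borders. mSSIM is the plain mean of the map.

## NRMSE and PSNR

The RSE map is `|target − prediction|`. "Normalised" RMSE is ambiguous in
the field; the package defaults to dividing by the **population standard
deviation of the reference** (so a constant bias of one reference-sd gives
NRMSE = 1 exactly), with `range` and `mean` denominators selectable and the
choice recorded. PSNR is `20·log10(L) − 10·log10(MSE)`; identical images
give an `Inf` sentinel, flagged rather than silently dropped.

3D stacks are scored slice-wise and averaged, with per-slice maps — the
reduction used when a single scalar is quoted for volumetric data.

# Segmentation metrics

Semantic IoU is pixel-set intersection over union; two empty masks are
defined as IoU 1 *with a flag*, so batch QC over empty tiles does not
propagate NaN.

`optimizeThreshold()` reproduces the automatic threshold search used for
probability-map outputs: the map is min–max rescaled to 8-bit (integer
maps in 0..255 pass through), thresholds 1..254 are swept, and the IoU
argmax is returned with ties broken toward the lowest threshold. The sweep
granularity is deliberately the 8-bit integer grid: that is the precision
of the exported probability maps this search targets.

Instance matching computes IoU between every overlapping
(ground-truth, prediction) instance pair and solves the **optimal
one-to-one assignment maximising total IoU** among pairs with IoU ≥ τ
(maximum-weight bipartite matching; the common greedy-by-IoU rule is
available as `method = "greedy"` and differs only on ambiguous
merge/split scenes — both are test-covered against exhaustive
enumeration). τ defaults to 0.5 and is always recorded: published
instance scores are meaningless without it. From TP/FP/FN follow
precision, recall, F1, SQ (mean matched IoU), RQ (identical to F1) and
PQ = SQ·RQ. Because whole-image IoU and mean matched IoU answer different
questions, both are reported side by side in the CLI.

Centroid export uses the pixel-centre convention (0-based index + 0.5 when
converting to nm) and emits both a per-frame table and a dot raster
compatible with spot-tracking tools.

# Detection metrics

Boxes are 0-based half-open internally; PASCAL VOC XML (1-based inclusive)
is converted on read/write so round trips are exact. Matching ranks
predictions by confidence per class (ties broken deterministically by
image name then coordinates), consumes the best-IoU unmatched ground-truth
box at IoU ≥ τ, and counts double detections as false positives. AP
defaults to **all-point interpolation** (envelope integration); the
11-point PASCAL protocol is a flag, because the two references in common
use disagree and the choice changes AP by several points on small scenes.
mAP averages AP over classes present in the ground truth. F1 is evaluated
at an explicit operating confidence (default 0.3, recorded) — a detector's
F1 without its confidence threshold is not reproducible.

# The SMLM simulator

`simulateStack()` generates training-like raw data from
`SimulationParameters`:

| parameter | unit | meaning |
|---|---|---|
| `fovSizeNm`, `pixelSizeNm` | nm | field of view and camera pitch (FOV must divide into whole pixels) |
| `densityMean`, `densityStd` | emitters/µm² | per-frame Normal density law |
| `photonsMean`, `photonsStd` | photons | per-emitter truncated-Normal photon budget |
| `psfSigmaNm`, `psfSigmaStdNm` | nm | per-emitter truncated-Normal Gaussian PSF width |
| `adcPerPhoton` | e⁻/ADU | gain; counts are `photons / adcPerPhoton` |
| `readoutNoiseAdc`, `offsetAdc` | ADU | Gaussian read noise sd and baseline |
| `nFrames`, `seed` | — | length and full reproducibility |

Per frame the emitter count is
`round(max(0, N(densityMean, densityStd)) · area)`; positions are uniform
over the FOV. The PSF is rasterised as a **pixel-integrated Gaussian**
(differences of the Gaussian CDF per pixel edge), which is accurate in the
sigma ≈ 1 px regime where centre-sampling is visibly wrong. The camera
applies `offset + Poisson(expected photons)/gain + N(0, read noise)`,
clipped at zero. Three presets (`simulationPreset("bin4" | "bin10" |
"tubulin")`) carry parameters calibrated on experimental dSTORM
acquisitions of actin (raw movie sum-binned in groups of 4 or 10 frames to
raise apparent density) and microtubules.

Open choices, fixed as follows and recorded here: the density draw is one
Normal per frame (a per-frame Poisson law is available behind
`densityLaw = "poisson"`); the photon/sigma spreads are per emitter;
truncation of Normal draws at zero is by resampling (≤ 100 attempts, then
clamping); the gain convention is photoelectrons-per-ADU
(`invertedGain = TRUE` gives the reciprocal); emitters are only generated
inside the FOV and border spots are truncated without wraparound, so the
ground-truth table lists exactly the rendered emitters.

## Localisation chain

- `binFrames()` — grouped sum z-projection at full floating-point
  precision; the incomplete trailing group is dropped (the behaviour of
  the standard grouped-projection tool; the published 59,900-frame counts
  divide exactly).
- `renderHistogram()` — 2D counting at a chosen pitch; counts are
  conserved before the optional blur.
- `extractLocalisations()` — strict local maxima above a fraction of the
  image maximum, sub-pixel position by intensity-weighted centroid,
  nm conversion by the pixel-centre convention.
- `mergeEvents()` — links localisations to open tracks within a radius
  (default 40 nm) with a dark-frame allowance (default 0, i.e. gaps break
  tracks); assignment per frame is nearest-neighbour one-to-one with ties
  to the earliest track; each track collapses to its photon-weighted mean.
- `estimateDrift()` — time bins of equal localisation count (robust to
  blinking non-stationarity; equal-span is a trivial variant), rendered on
  a common grid, cross-correlated against the first bin with 3×3-centroid
  sub-pixel refinement; the per-frame trace interpolates linearly between
  bin centres, extrapolates linearly beyond them, and is re-anchored to
  exactly (0,0) at frame 1. Bins under 10 localisations are flagged.

On the synthetic drift fixtures (60 emitters, 100 frames, 8 nm
localisation jitter, 20 nm rendering), a 100 nm linear drift is recovered
to a few nm — comfortably inside the half-rendering-pixel bound the
package tests against.

# Augmentation

The eight symmetries of the square are applied as exact array
permutations — no interpolation — identically to both members of a
training pair, multiplying the dataset by exactly 8 (identity included;
that is the arithmetic behind "×8"). Rotation-only and mirror-only subsets
support staged protocols. Bounding boxes are mapped through the exact
coordinate transform on the half-open grid; a property test checks that
transforming the rasterised box equals rasterising the transformed box for
every element. Symmetric images produce duplicate augmented copies; these
are deliberately not deduplicated. Photometric and elastic augmentations
are out of scope.

# Training diagnostics

Overfitting has no standard numeric criterion; the package operationalises
"increasing divergence between validation and training loss" as: final
validation loss exceeds `(1 + delta)` times its minimum *while* the final
training loss is at or below its value at that minimum (default
`delta = 0.05`, recorded). The argmin epoch is recommended as the
checkpoint. The verdict is invariant to common rescaling of both curves.

Reports are deterministic apart from a single timestamp line: parameters
verbatim, every QC scalar with the configuration it was computed under
(τ, confidences, normalisation mode, seeds), markdown for humans and a
JSON twin for machines, with a shipped structural schema and an in-code
validator.

# What the synthetic generators do and do not show

The fixtures (`makeNucleiScene`, `makeNoisyPair`, `makeDetectionScene`,
`makeDriftedLocalisations`) are pure functions of their seed and exist to
close the QC loop analytically: perfect predictions must score exactly 1,
and countable corruption must move scores to computable values (dropping
`d·n` boxes gives recall `1 − d` exactly). They emulate the *statistics*
that matter to the metrics — disjoint labelled instances, Poisson+Gaussian
noise with known moments, class-dependent box aspect ratios, rigid linear
drift — not the appearance of real micrographs: no uneven illumination,
no structured background, no touching nuclei, no astigmatic PSFs, no
fiducials. Passing the closed-loop suite therefore certifies the metric
implementations and pipeline plumbing, not model performance on real data;
real QC still requires real held-out ground truth.

Problem sizes in the test-suite and acceptance runs were chosen to keep
every statistical check well-powered while remaining desk-scale: 16×16 to
64×64 images for metric-oracle equivalence (tolerances 1e-8 to 1e-12),
64×64×20-frame simulations for camera-moment recovery (3 standard-error
bounds), 50-emitter/100-frame scenes for merging and drift, and the full
59,900-frame arithmetic for binning counts.

# Known limitations

- Instance matching is 2D; volumetric data get semantic IoU only.
- No boundary-distance metrics (Hausdorff) and no frequency-domain
  resolution estimates.
- mAP is single-τ (default 0.5), not COCO-style τ-averaged.
- The simulator has no EM-gain excess noise and no 3D/astigmatic PSF;
  drift correction is cross-correlation only (no fiducial tracking).
- Float TIFF output is uncompressed (lossless contract over file size).
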