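---
title: "Quantifying hyperreflective dots on OCT b-scans: methods and design"
author: "hrdq"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Quantifying hyperreflective dots on OCT b-scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrdq)
```

## The problem

Hyperreflective dots (HRDs) are small bright particles visible on optical
coherence tomography (OCT) b-scans of eyes with diabetic macular edema
(DME). Two kinds matter clinically and behave differently: **hard
exudates** — lipid deposits larger than 40 µm, with reflectivity close to
the RPE–Bruch complex, that cast a *back shadow* (an attenuated signal
column beneath them) — and **small HRDs** of 20–40 µm at roughly
nerve-fiber-layer reflectivity without shadowing, hypothesized to be
activated microglia. Signals below 20 µm are treated as noise. Counting
and measuring these by hand across a 128-b-scan macular cube is slow and
subjective; `hrdq` implements an automated two-step pipeline:

1. **Segmentation** of HRD foreground per b-scan, either by a compact
   U-shaped convolutional network or by a deterministic intensity
   threshold (a reference path that keeps the rest of the pipeline
   testable without any training).
2. **Differentiation and quantification**: 8-connected component
   extraction per b-scan, physical Feret diameter measurement, a columnar
   back-shadow test, the three-rule classification above, and aggregation
   into per-region area (mm²) and count for the full 6 × 6 mm scan and
   the 3 mm and 1 mm fovea-centered circles.

Agreement between two annotation sources (two raters, or a rater and the
algorithm) is summarized with per-volume Dice, ICC(2,1), Pearson
correlation, and Bland–Altman limits of agreement.

## Geometry and conventions

All grids are indexed (b, z, x) = (b-scan, axial depth, lateral position),
z increasing from the inner retina downward, 1-based in R, with physical
coordinates at voxel centers. The reference geometry is the Topcon macular
cube: 6 × 6 × 2 mm over 128 × 512 × 885 voxels, i.e. spacings of 46.875 µm
(inter-slice), 2.2599 µm (axial) and 11.71875 µm (lateral):

```{r}
topconSpacing()
```

Volumes travel as ITK MetaImage (`.mhd`/`.mha`). On disk intensities are
unsigned 8- or 16-bit; in memory they are normalized to [0, 1] by the
type maximum, so network input scaling is deterministic. The bit depth and
calibration of vendor exports are not standardized, which makes this
normalization a package convention rather than a property of the data.

**Physical diameter.** Components are measured by the Feret (maximum
caliper) diameter over pixel centers, scaled anisotropically, **plus one
in-plane pixel diagonal** (≈ 11.9 µm at reference spacing) so a single
bright pixel has a physically meaningful size. Because the lateral pixel
(11.7 µm) is of the same order as the 20 µm noise cutoff, this convention
matters: it effectively shifts the size floor upward, and sub-resolution
scatterers can only stay below 20 µm as short single-column runs. The
boundary semantics are: *strictly* below 20 µm is noise, *strictly* above
40 µm with shadow is a hard exudate, and both exact boundaries fall to the
small-HRD class ("20 to 40 µm" read inclusively).

**Classification order.** Noise exclusion is applied before the shadow
test; under the three rules the final class does not depend on this order,
so it is purely a matter of skipping shadow tests that cannot change the
outcome.

## The segmentation network

The network is a U-shaped encoder–decoder with **three** down/upsampling
steps (HRDs are small, so a fourth level would mostly model context the
lesions never span). Each encoder stage is a **multi-scale convolution
module (MSCM)**: three parallel 3 × 3 convolutions at dilation rates 1, 2
and 3 (same padding, ReLU), concatenated and fused back to the stage width
by a 1 × 1 convolution. The two deepest encoder computations (third
encoder stage and the bridge) each carry a **channel attention module
(CAM)**: global average pooling, a fully connected bottleneck (reduction
4, ReLU), an expansion with sigmoid gate in (0, 1), applied
multiplicatively per channel. The decoder mirrors the encoder with
nearest-neighbour upsampling, a 3 × 3 convolution, skip concatenation and
a fusing 3 × 3 convolution; a final 1 × 1 convolution emits two class
scores per pixel. Channel widths are (c, 2c, 4c, 8c) with `baseChannels`
c = 16 by default and a `tiny` preset of c = 8 for CPU work. At equal base
width the parameter count is well under half that of a standard four-level
U-Net — multi-scale receptive fields without the parameter cost of depth.

Inputs must be divisible by 8 in both in-plane dimensions;
`segmentProbability()` zero-pads internally and crops the output back, so
callers never see the constraint.

Several architectural details are deliberate design choices where common
practice offers multiple options:

* **Loss** — the sum of a class-balanced pixel-wise cross-entropy
  (foreground weight = background/foreground ratio, capped at 100) and a
  soft-Dice loss on the foreground probability. Lesions occupy well under
  1 % of a b-scan; with an unweighted loss the optimizer settles into a
  saturated all-background prediction and the Dice gradient dies.
* **Output head zero-initialized** — training starts from maximal class
  entropy (p = 0.5 everywhere), which keeps the soft-Dice term active
  from the first step.
* **Gradient clipping** at global norm 5 — the published optimizer
  settings (SGD, learning rate 0.01, momentum 0.9, weight decay 1e-4,
  batch 2, 60 epochs) are aggressive for an unnormalized network; clipping
  guards the first epochs against ReLU die-off without altering the
  optimizer itself.
* **MSCM fusion by concatenation + 1 × 1 convolution** and **CAM as a
  single bottlenecked FC pair** — the minimal structures consistent with
  "parallel dilated branches" and "global average pooling + fully
  connected layer".
* **Augmentation** — each training sample receives k ∈ {2, 3, 4} distinct
  operations from {left-right flip, up-down flip, rotation, additive
  Gaussian noise}. Rotation is uniform in [−15°, +15°] with
  nearest-neighbour mask resampling (labels stay integral); noise σ is
  uniform in [0.01, 0.05] of the intensity range and touches the image
  only.

Training operates on per-b-scan 2-D images; volumes are flattened to
their b-scans. The 4-fold cross-validation harness (`makeFolds()`,
`crossValidate()`) partitions volume ids into near-equal folds, trains on
three and tests on the held-out fourth, and reports per-fold and mean
foreground Dice.

## The back-shadow test

The shadow signal feeds classification rule (1). `hrdq` uses a
deterministic columnar attenuation test: for a candidate component, the
mean intensity of the band directly beneath it (from the component bottom
to the per-column RPE depth estimate, excluding pixels of any segmented
component) is compared with the mean of two flanking bands of the same
width and depth range, offset laterally by twice the component width.
Shadow is declared iff beneath/flank < τ with τ = 0.75 by default — midway
between a fully shadowed ratio (the phantom renders 0.4) and the
speckle-only ratio (≈ 1). The decision is monotone in τ. Windows shorter
than 10 px (components sitting on the RPE) are untestable and return
`shadow = FALSE` with a `window_too_short` flag. The RPE depth itself is
the per-column argmax of intensity in the lower image half, median-smoothed
laterally over 15 px, with a fallback to 0.85 × depth (flagged) for flat
images. An interface slot (`segmentation = list(method = "network")` plus
a custom prob provider, or any per-component override) allows a learned
shadow detector to be swapped in; the deterministic test is the default
because it is fully specified, auditable (the ratio is reported per
component), and needs no training data.

## Quantification

A component belongs to every region containing its en-face centroid —
(b − 0.5) × inter-slice spacing along the slow axis, mean lateral pixel
center × lateral spacing across — so lesions are never split at circle
boundaries and count/area semantics stay consistent. The fovea defaults to
the geometric scan center (macular cubes are acquired fovea-centered) with
an explicit override for decentered scans. Area is the cross-sectional
pixel area (axial × lateral spacing) summed over the component, in mm²;
totals satisfy `total = hard_exudate + small_hrd` identically, and the
1 mm ⊆ 3 mm ⊆ full nesting holds by construction.

## Agreement statistics

* **Dice**, per volume and class; two empty masks agree vacuously
  (Dice = 1), which matters on lesion-free b-scans.
* **ICC(2,1)** — two-way random effects, absolute agreement, single
  measures, with the McGraw–Wong F-based 95 % CI. Absolute agreement is
  the right form for method comparison, where a constant offset between
  methods *should* lower reliability; the consistency form ICC(3,1) is
  available via a flag. Zero total variance leaves the ICC undefined (NA),
  never 1.
* **Pearson r** with the t-transform p-value (n − 2 df), via
  `stats::cor.test`.
* **Bland–Altman** mean difference and limits of agreement mean ±
  1.96 × SD (n − 1 denominator), using the conventional normal quantile
  rather than a t quantile.

P-values are reported at machine precision with no multiplicity
correction. Whether per-volume averaging or pixel pooling is used for Dice
is a genuine ambiguity in the field; `hrdq` reports the per-volume mean
(SD), the form consistent with quoting a mean and SD over eyes.

## The phantom generator

Real annotated DME volumes cannot ship with a package, so every stage is
exercised on layered-retina phantoms (`generateVolume()`): a dark
vitreous, a bright NFL-like band, a dark mid-retina band, a bright
RPE-like band with a slight parabolic axial profile (so its center is the
brightest row), and a dim sub-RPE zone. Lesions are physical discs in the
(z, x) plane of single b-scans — the inter-slice gap (≈ 47 µm) exceeds
most lesion diameters, matching per-b-scan manual labeling — at fixed
jittered lateral slots that keep lesions, shadows and flank bands disjoint
by construction. Hard exudates (45–150 µm) render at RPE reflectivity
with the full column beneath them attenuated by 0.4; small HRDs
(20–40 µm) at NFL reflectivity without shadow; sub-20 µm noise dots
appear in the image but not in the ground-truth mask. Speckle is
multiplicative gamma noise with mean 1 (variance 0.05 by default) and
never touches the mask, which is a pure function of the lesion plan.
Intensities are quantized to the 16-bit grid so MetaImage round-trips are
bit-exact.

Each lesion's recorded diameter is the Feret diameter *measured on its
rendered pixel set* — not the sampled target — so the recorded class is
exactly what the rule classifier decides, and the generator resamples any
lesion whose rasterization would land ambiguously near a 20/40 µm
boundary. A simulated second rater (`simulateRater()`) perturbs a mask
per component: drop with probability `dropProb`, class flip with
`flipProb`, and Chebyshev dilation/erosion by a radius drawn from
{−jitter, …, +jitter}; the zero-noise spec is exactly the identity.

What the phantoms deliberately do **not** model: cysts and subretinal
fluid, vessel shadows, layer undulation and pathology-induced layer loss,
vendor noise spectra, motion artifacts, and lesion clustering or
confluence. Passing phantom tests therefore demonstrates that the
*mechanics* of segmentation, measurement, shadow logic, regionalization
and statistics are correct — not that the trained network generalizes to
patient data, which requires labeled clinical volumes.

## Problem sizes and numerical choices

The test and acceptance runs use desk-scale problems chosen as the
smallest sizes at which every property is meaningfully exercised:
4 × 256 × 256 phantoms for the pipeline, classification and quantification
checks; 10 phantoms of 8 b-scans (≈ 220 lesions) for shadow-detection
accuracy; 20 two-b-scan volumes for the rater-agreement study (mirroring
the 20-eye scale of a typical clinical series); and an 8-patch
128 × 128 overfit run with the tiny preset for network capacity. The full
885 × 512 geometry is supported throughout. Degenerate inputs are handled
explicitly: empty masks (vacuous Dice), flat images (RPE fallback),
components on the RPE (untestable shadow), zero-variance series
(undefined ICC/r), and zero-epoch training (identity).

## Known limitations

* The shadow test is a stand-in with a heuristic τ; no published operating
  definition of "back shadow present" exists to calibrate it against.
* 2-D per-b-scan components mean a lesion spanning adjacent b-scans counts
  once per b-scan; 3-D merging is deliberately out of scope.
* The diameter convention (+1 pixel diagonal) shifts the effective noise
  cutoff by roughly one lateral pixel; comparisons with tools using bare
  Feret diameters must account for this.
* Training at clinical scale (2 560 b-scans, 60 epochs) is far outside
  the CPU budget of this package's reference implementation; the network
  is exercised at capacity-check scale.
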