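# hrdq — hyperreflective dot quantification on retinal OCT

`hrdq` detects, differentiates and quantifies hyperreflective dots (HRDs)
on OCT b-scans of diabetic macular edema, for researchers who need
per-eye lesion burdens without manual labeling of a 128-b-scan macular
cube. Two lesion types are distinguished by physical size and back
shadowing:

* **hard exudate** — diameter > 40 µm, with a back shadow (an attenuated
  signal column beneath the lesion), RPE-like reflectivity;
* **small HRD** — diameter 20–40 µm, no back shadow, NFL-like
  reflectivity (hypothesized activated microglia);
* anything < 20 µm is noise and is excluded.

The pipeline is: (1) per-b-scan foreground segmentation — a three-level
U-shaped CNN whose encoder stages are multi-scale dilated-convolution
modules (parallel 3×3 convolutions at dilation 1/2/3, fused 1×1) with
channel attention (global-average-pool + FC sigmoid gate) on the two
deepest stages, or a deterministic threshold reference path; (2)
8-connected component extraction, physical Feret diameter measurement
(anisotropic spacing, plus one pixel diagonal), a columnar
attenuation-ratio shadow test against the per-column RPE depth, the
three-rule classification, and aggregation into area (mm²) and count for
the full 6×6 mm scan and the 3 mm / 1 mm fovea-centered circles.
Agreement between two annotation sources is reported as per-volume Dice,
ICC(2,1) with 95 % CI, Pearson r, and Bland–Altman limits of agreement
(mean ± 1.96 SD).

Because clinical volumes cannot ship with a package, `hrdq` includes a
layered-retina phantom generator with exact ground truth (lesion discs of
controlled physical diameter, rendered back shadows, multiplicative
speckle) and a simulated second rater, so every stage is testable end to
end. Volumes travel as ITK MetaImage (`.mhd`/`.mha`).

## Worked example

```r
library(hrdq)

ph <- generateVolume(PhantomSpec(seed = 7L))   # 4 b-scans, 256 x 256
ph$volume
#> OCTVolume: 4 b-scans x 256 axial x 256 lateral
#>   spacing (um): inter-slice 46.88, axial 2.26, lateral 11.72
#>   extent (mm): 0.188 x 0.579 x 3
#>   intensity range: [0.00893, 1]

res <- runPipeline(ph$volume,
                   segmentation = list(method = "oracle", mask = ph$mask))
res$components[, c("bscan", "n_pixels", "diameter_um", "shadow", "ratio", "class")]
#>   bscan n_pixels diameter_um shadow ratio        class
#> 1     1       11        34.5  FALSE 1.015    small_hrd
#> 2     2       21        37.1  FALSE 0.966    small_hrd
#> 3     2       21        37.1  FALSE 0.993    small_hrd
#> 4     2       55        57.1   TRUE 0.402 hard_exudate
#> 5     3      175        87.3   TRUE 0.438 hard_exudate
#> 6     3      665       160.7   TRUE 0.405 hard_exudate
#> 7     3       21        37.1  FALSE 0.992    small_hrd
#> 8     4       21        37.1  FALSE 1.002    small_hrd
```

Each row is one connected component: its pixel count, physical Feret
diameter in µm, the shadow decision with the audited attenuation ratio
(≈ 0.4 beneath a rendered shadow, ≈ 1.0 where there is none), and the
resulting class. The per-region summary (`res$summary`) gives area and
count per class; note the totals are exactly hard exudate + small HRD and
the 1 mm ⊆ 3 mm ⊆ full nesting:

```r
res$summary
#>          roi        class area_mm2 count
#> 1   full_6x6    total_hrd 0.026218     8
#> 2 circle_3mm    total_hrd 0.026218     8
#> 3 circle_1mm    total_hrd 0.018167     2
#> 4   full_6x6 hard_exudate 0.023702     3
#> ...

rater2 <- simulateRater(ph$mask, RaterNoiseSpec(jitterPx = 1, dropProb = 0.05,
                                                flipProb = 0.05, seed = 2L))
diceCoef(ph$mask, rater2)
#> [1] 0.931
```

For a cohort, `runAgreement()` assembles the full report — Dice per
class, plus ICC / Pearson / Bland–Altman for all six parameters (area
and count × total, hard exudate, small HRD) in all three regions.

A command-line wrapper over the same functions ships in
`inst/scripts/hrdq.R` with subcommands `simulate`, `train`, `predict`,
`quantify`, `pipeline` and `agree`.

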