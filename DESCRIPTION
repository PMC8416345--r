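Package: hrdq
Title: Detection, Differentiation and Quantification of Hyperreflective Dots on Retinal OCT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for quantifying hyperreflective dots (HRDs) on optical
    coherence tomography b-scans of diabetic macular edema. Implements a
    three-level U-shaped segmentation network with multi-scale dilated
    convolution modules and channel attention, connected-domain extraction
    with physical-size measurement, back-shadow-aware classification of
    components into hard exudates and small HRDs, per-region area and count
    quantification, and rater-agreement statistics (Dice, ICC, Pearson,
    Bland-Altman). Includes a layered-retina OCT phantom generator with
    ground-truth annotations and a simulated second rater, plus ITK
    MetaImage volume input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, grDevices, jsonlite, yaml, Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
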