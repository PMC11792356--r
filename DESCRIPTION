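Package: thighfat
Title: Thigh Muscle Fat Infiltration Quantification from T1-Weighted MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intramuscular (intraMAT) and intermuscular (interMAT)
    adipose tissue in the thigh from T1-weighted MR volumes with co-registered
    muscle/bone/fascia label maps. Implements slice-wise non-local-means
    denoising, multiplicative bias-field correction, intensity normalization to
    [0, 255], automatic derivation of intraMAT/interMAT/fascia region masks,
    locally adaptive Gaussian-mean threshold fat segmentation, and volumetry
    over a mid-thigh region of interest. Includes a synthetic thigh phantom
    generator with known ground-truth fat volumes for validation, and the
    two-group comparison statistics (pooled t-test, Cohen's d, normality
    screening, noncentral-t sample-size calculation) used in cross-sectional
    muscle-quality studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    nortest,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
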