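Package: neobat
Title: Quantification of Brown Adipose Tissue from Water-Fat Separated MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying brown adipose tissue (BAT) depot volume and
    fat fraction from two-point Dixon water-fat separated magnetic resonance
    images of human neonates. Implements magnitude dual-echo water-fat
    separation, fat signal fraction mapping with validity masking, rule-based
    BAT candidate masks, threshold-constrained seeded region growing for
    supraclavicular, axillary, spinal and nuchal white-adipose regions, depot
    volume and fat-fraction quantification with cohort summaries, scan-rescan
    voxelwise agreement, intraclass-correlation variance decomposition
    (ICC/WSC/N), and ROC calibration of fat-fraction classification
    thresholds. A synthetic phantom generator (skew-normal tissue fat-fraction
    distributions, ellipsoidal depots, dual-echo forward model, scan-rescan
    replicates and rater seed jitter) makes every stage testable without scan
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
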