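Package: myoquant
Title: Quantification of Myotube Maturation from Label Masks, Calcium
    Recordings and qPCR Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable quantification pipeline for in vitro skeletal-muscle
    maturation readouts: nuclei-arrangement morphometry on calibrated
    segmentation masks (area filtering, border-to-border single-linkage
    clustering, eccentricity and orientation of isolated nuclei, fusion
    index, marker-positive fractions), parametrization of cytosolic calcium
    transients evoked by burst electric-field stimulation (F/F0
    normalization, per-burst peak amplitudes, responder classification,
    decay time, remaining-calcium percentage), acetylcholine-receptor
    cluster and sarcomere-striation quantification, geNorm-style qPCR
    normalization against housekeeping genes with fold changes relative to
    a reference condition, and the accompanying statistics (per-field
    medians, Wilcoxon rank-sum with tie-corrected normal approximation,
    Student t tests, mean plus or minus SEM). Ground-truth-annotated
    synthetic data generators emulate each input modality so every stage is
    verifiable without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
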