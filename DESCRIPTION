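Package: mtvbench
Title: Benchmarking PET Metabolic Tumor Volume Delineation Algorithms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing PET metabolic tumor volume (MTV) delineation
    algorithms on synthetic PET/CT phantoms, as used in radiotherapy planning
    for rectal carcinoma. Implements six delineation arms (an absolute SUV 2.5
    threshold and a 45 percent relative threshold, each under two
    reference-uptake software dialects, a fuzzy locally adaptive Bayesian
    classifier, and a gradient/watershed method), grid resampling between PET
    and planning-CT spaces, mask/contour conversion with DICOM RT Structure
    Set round trips, and agreement statistics (Jaccard conformity index,
    intraclass correlation with 95 percent lower confidence limits, paired
    tests, Friedman test, Bland-Altman analysis). A synthetic phantom cohort
    generator provides ground-truth lesions spanning the clinically observed
    volume range.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
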