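Package: tmtvkit
Title: Total Metabolic Tumor Volume Delineation and Method Agreement for FDG PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Threshold-based delineation of total metabolic tumor volume
    (TMTV) in 3D standardized-uptake-value (SUV) images, and the statistics
    used to compare delineation methods. Provides volume-of-interest
    construction (single-region prism extrusion, slice-wise editing,
    per-lesion regions), absolute and relative SUV isocontour segmentation
    with TMTV, SUVmean, SUVmax, SUVpeak and TLG extraction, Bland-Altman and
    correlation agreement statistics between paired delineation outputs,
    ROC/Youden prognostic cutoff selection with Kaplan-Meier survival
    comparison, and a seeded synthetic PET phantom cohort generator for
    validating the whole pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    survival,
    stats,
    tools,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    oro.nifti,
    pROC,
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
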