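Package: mihcTME
Title: Spatial Single-Cell Proteotyping of the Tumor Microenvironment from Multiplex IHC
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for multiplex immunohistochemistry (mIHC) single-cell
    tables from tumor tissue: hierarchical marker gating into immune and stromal cell
    subsets, kernel-density tissue segmentation into tumor-cell-nest (TN) and
    intratumoral-stroma (ISA) compartments, compartment-specific density, positivity and
    effector-to-target features, unsupervised clustering of key tumor-microenvironment
    features with the uncentered-correlation average-linkage method, and survival
    statistics (Kaplan-Meier, log-rank, Cox proportional hazards, durable-clinical-benefit
    classification) linking those features to immune-checkpoint-inhibitor efficacy in
    metastatic non-small-cell lung cancer. Includes a calibrated synthetic-cohort
    generator emulating the spatial structure (cancer-cell nests, stromal corridors,
    compartment-biased infiltration) and proportional-hazards outcome model that the
    analysis assumes, plus a bulk-expression companion (Welch-t differential expression,
    signature scores, composite transcriptional profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    survival,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
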