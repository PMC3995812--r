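Package: mirstroma
Title: Compartment-Specific Quantification of Chromogenic ISH Signal and
    Survival Analysis for Tumor-Stroma Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies chromogenic in situ hybridization (ISH) signal
    separately in the tumor and stroma compartments of serial tissue
    sections ("virtual double staining"): optical-density stain unmixing
    of RGB brightfield images, deterministic serial-section registration,
    transfer of a cytokeratin-derived tumor mask, and computation of the
    total-blue-signal scores TBS (stroma), TBT (tumor) and the total
    stroma area TSA. Includes the downstream survival workflow (tertile
    stratification, Spearman screening, univariate and backward-eliminated
    multivariate Cox proportional-hazards models, Schoenfeld-residual
    proportional-hazards diagnostics, Cox and Kaplan-Meier curves) and a
    synthetic-data generator producing paired section images with known
    ground truth and survival cohorts with configured hazard ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    survival,
    tiff,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
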