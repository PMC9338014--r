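Package: chimeraComplex
Title: Detection of Destabilized Protein Complexes from SEC-SILAC
    Co-Fractionation Proteomics
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Identifies protein complexes that are destabilized in yeast
    hybrid chromosome-replacement lines from size-exclusion chromatography
    (SEC) SILAC co-fractionation proteomics. Raw per-fraction heavy/light
    intensities are pooled, concentration-corrected and normalized into
    elution patterns; the elution pattern difference (EPD, an L1 distance
    over 27 fractions) is computed per protein, and complex-level
    instability is inferred with paired one-sided Wilcoxon signed-rank
    tests against a same-strain control with Benjamini-Hochberg FDR
    control. Companion modules classify common-response genes from
    fold-change tables, compare protein-transcript correlations via
    Fisher's r-to-z, quantify growth, sporulation and aggregation
    phenotypes, and correlate them with per-line chimeric-complex counts.
    A synthetic data generator with planted ground truth makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Software, StatisticalMethod
RoxygenNote: 7.3.3
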