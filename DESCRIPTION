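Package: goTLM
Title: Protein Subcellular Localization by Weighted Fusion of Gene
    Ontology and Sequence Composition Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts the subcellular localization of proteins with a
    multiclass support vector machine over a fused kernel.  Five
    Gaussian channel kernels are computed per protein pair: biological
    process, molecular function and cellular component gene-ontology
    term vectors, plus amino-acid and di-peptide composition spectra.
    The channel weights are estimated non-parametrically by inner
    cross-validation, weighting each channel by the product of its
    sensitivity and multiclass Matthews correlation coefficient, so
    that uninformative or poorly annotated channels contribute little
    to the fused kernel.  Includes cross-validation and holdout
    evaluation protocols, per-location performance reports, a
    configurable synthetic-data generator for testing, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    e1071,
    Biostrings,
    jsonlite,
    yaml,
    withr
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
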