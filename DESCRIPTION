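Package: znblup
Title: Genomic Prediction of Maize Kernel Zinc with RR-BLUP/GBLUP
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ridge-regression BLUP / GBLUP genomic prediction toolkit built
    around maize kernel zinc concentration. Provides a VanRaden genomic
    relationship matrix, REML variance components via a single spectral
    decomposition, marker-effect ridge solutions with GEBV prediction,
    genotype quality control for codominant (GBS-style SNP) and dominant
    (rAmpSeq-style presence/absence) marker platforms, least-squares means
    for multi-environment phenotypes, and a full evaluation battery:
    replicated k-fold cross-validation, training-population-size,
    marker-density and marker-quality sweeps, phenotype-stratified
    training-set scenarios, cross-population transfer, and
    marker-assisted-selection comparison. A synthetic-data module simulates
    association panels and doubled-haploid populations with controlled
    additive architecture so the whole pipeline runs without external
    downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
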