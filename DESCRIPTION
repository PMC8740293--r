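Package: peagp
Title: Genomic Prediction and Reliability Screening for Germplasm Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genomic prediction in plant germplasm
    collections, modelled on genotyping-by-sequencing panels of inbred pea
    accessions. Provides synthetic genotype/phenotype simulation with known
    truth (admixed subpopulation structure, linkage-disequilibrium blocks,
    GBS-like defects), VCF site filtering and k-nearest-neighbour genotype
    imputation, multi-year mixed-model BLUPs with entry-mean and Cullis
    heritabilities, five genomic prediction models (RR-BLUP/GBLUP, partial
    least squares, random forest, BayesC-pi, multi-kernel RKHS), a battery
    of cross-validation designs (model comparison, training-size and
    marker-density curves, population-structure adjustment), and
    reliability-scored prediction of genotyped but nonphenotyped accessions.
License: MIT
Encoding: UTF-8
Imports:
    lme4,
    vcfR,
    randomForest,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
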