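Package: usvqtl
Title: Heritability and QTL Analysis of Mouse Infant Ultrasonic Vocalizations
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative-genetic analysis of infant ultrasonic vocalization
    (USV) traits in recombinant inbred (RI) mouse panels and a reciprocal
    diallel cross. Implements ANOVA variance partitioning and three
    heritability estimators (individual h2, broad-sense H2, and the
    strain-mean heritability HRIxbar2 = Va/(Va + Ve/n)) with subsample
    confidence intervals; reciprocal-F1 parent-of-origin tests and call-type
    profile summaries; Haley-Knott regression QTL scans on strain means with
    permutation-derived genome-wide thresholds, 1.5-LOD support intervals,
    bootstrap peak histograms, and a kinship-adjusted mixed-model scan; and
    evidence-based candidate-gene triage within QTL intervals. Includes a
    synthetic-data generator for RI genotype mosaics, structured phenotypes,
    diallel families, and multinomial call-type counts, plus readers and
    writers for the GeneNetwork .geno genotype dialect and tabular phenotype,
    strain-mean, and scan files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
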