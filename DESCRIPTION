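Package: estrascreen
Title: Phenotyping Pipelines for Beta-Estradiol-Titratable Yeast Strain
    Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification and scoring pipeline for genome-scale yeast
    strain collections in which native promoters are replaced by a
    beta-estradiol-inducible synthetic promoter. Covers colony-grid
    quantification of pinned agar plate images with plate, positional and
    competition-effect normalization; assembly of colony time series into
    smoothed growth curves and area-under-growth-curve (AUGC) dose-response
    profiles; hierarchical clustering of dose-response behaviors (Chebyshev
    distance) with rule-based behavior labels; expression-growth association
    statistics; bespoke per-strain scores (Aux score for auxotroph-like
    behavior, an overexpression-toxicity caller, reversibility and inducer
    dependence classes, synthetic dosage lethality calls); and a BAR-seq
    barcode-counting and competitive-fitness module with spike-in and
    time-zero normalization. A synthetic-data generator produces strain
    panels, growth tables, plate image stacks and FASTQ runs with known
    ground truth so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tiff,
    jsonlite,
    yaml,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    png,
    withr,
    optparse
Config/testthat/edition: 3
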