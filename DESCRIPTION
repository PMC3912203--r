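Package: bandenrich
Title: Positional Enrichment and Coordinate-Control Analysis of
    Dysregulated Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-group bulk RNA-seq FPKM studies:
    estimates an expression-above-background threshold from exonic versus
    intergenic FPKM distributions (intersection of false discovery and
    false negative rate curves), calls differential expression with
    signed fold-changes and Benjamini-Hochberg step-up adjustment, tests
    positional enrichment of the dysregulated gene set at chromosomes and
    cytogenetic subbands against a resampling null drawn from the
    expressed-gene universe, and quantifies coordinate control
    (co-expression) of gene clusters per phenotype group with permutation
    significance. Ships a synthetic-data generator that emulates the
    study design (planted differential expression concentrated on chosen
    subbands, a latent-factor-correlated gene module whose correlation
    weakens in one group) so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
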