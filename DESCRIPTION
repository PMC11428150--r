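Package: slem
Title: Stepwise Deep Learning with Multi-Precision Data for SNP Combination Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse, biologically labelled five-layer neural networks
    (SNPs, transcript isoforms, protein markers, cellular phenotypes, disease)
    whose architecture and initial weights are derived from covariate-adjusted
    association statistics on precise multilevel assay data, then trains them on
    large end-to-end genotype/diagnosis cohorts with gradient masking. Trained
    networks are interpreted through per-SNP path-product impact scores,
    mediator-module extraction, and exhaustive screening of genotype-state
    combinations of high-impact SNPs by precision and hypergeometric enrichment,
    with holdout re-evaluation. Includes a synthetic-data generator with planted
    multilevel structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
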