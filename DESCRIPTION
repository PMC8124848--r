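Package: diffOmicsNet
Title: Genotype-Specific Differential Correlation Networks for
    Transcript and Metabolite Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds and compares genotype-specific Pearson correlation
    networks over combined transcript and metabolite profiles from a
    two-genotype by two-treatment design. Counts are filtered, TMM
    normalized and voom transformed; differential expression uses
    moderated t-statistics; metabolites and traits are tested by
    balanced two-way ANOVA with Tukey letter displays; gene sets are
    tested for GO term over-representation by the hypergeometric
    distribution. Networks of the two genotypes are compared edge-wise
    with the Fisher z test for correlation differences, central nodes
    are selected by degree and betweenness, and tau-threshold scores
    quantify genotype-specific connectivity. A synthetic data generator
    with planted ground truth supports calibration and recovery checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    limma,
    edgeR,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
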