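Package: hybridmap
Title: Genetic Mapping of Gut Microbiome Traits in a Hybrid Mouse Intercross
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Heritability estimation and additive-plus-dominance genome-wide
    association mapping of microbial abundance traits in a multi-line hybrid
    mouse intercross. Provides a forward simulator for hybrid-zone derived
    intercross genotypes and compositional abundance traits, genotype quality
    control with LD pruning and hybrid-index computation, genomic relatedness
    matrices (centred, standardised, leave-one-chromosome-out), a restricted
    maximum likelihood engine for multi-kernel linear mixed models with
    simulation-based restricted likelihood ratio tests, per-SNP scans with
    additive and dominance terms, genomic control, effective-test thresholds,
    dominance-architecture classification, percent variance explained, and
    LD-defined significant regions with permutation-based overlap and gene-set
    enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    tools,
    utils,
    vegan,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
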