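Package: TriadScreen
Title: Screening of Direction-Constrained lncRNA-miRNA-mRNA Regulatory Modules
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream inference for three-layer (mRNA, lncRNA, miRNA)
    expression studies contrasting drought and control conditions in two
    genotypes. Provides negative-binomial Wald differential-expression calling
    per genotype, consensus lncRNA filtering and positional classification,
    cis (genomic window) and trans (expression correlation) lncRNA-target
    assignment, a plant miRNA complementarity scorer, a three-class
    drought-resistance gene screen, and a direction-constrained
    lncRNA-miRNA-mRNA (ceRNA) module screen. A synthetic-data generator with
    planted ground truth makes every stage testable end to end without
    sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    withr
Config/testthat/edition: 3
biocViews: Transcriptomics, DifferentialExpression, GeneRegulation,
    NetworkInference, Software
RoxygenNote: 7.3.3
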