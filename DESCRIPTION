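Package: cnseq
Title: Small-Cohort FPKM Transcriptomics with Cross-Species Gene
    Mutability Scoring
Version: 0.1.0
Authors@R:
    person("CN", "Seq Maintainers", email = "maintainers@cnseq.dev",
           role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq FPKM matrices from small
    postmortem brain cohorts: validated expression-matrix input/output,
    nonparametric and Welch-based per-gene group comparisons with fold
    changes, star labels and p-value/effect-size ranking, principal
    component analysis with genes as observations, hierarchical
    clustering of samples and gene subgroup profiles, a minimal
    weighted running-sum gene-set enrichment engine with a permutation
    null, and a cross-species gene mutability assessment based on
    telomere proximity, A+T content, panel matching rates and
    transcript-size conservation. A synthetic-data module generates
    FPKM matrices, genomes and gene-set collections with known truth so
    every stage is testable without external downloads, and a pipeline
    driver orchestrates all stages from a single configuration file.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
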