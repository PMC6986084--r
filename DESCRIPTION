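Package: apomixnet
Title: Candidate Apomixis Gene Discovery from Transcriptome Coexpression
    and Differential Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for screening candidate apomixis genes in polyploid
    grass transcriptomes. Implements class-specific expression detection
    with Venn partitioning over phenotypic classes, a two-step
    empirical-Bayes negative-binomial differential-expression workflow
    producing posterior probabilities of equal/differential expression
    (PPEE/PPDE), filtering of tabular alignment hits against
    marker-delimited syntenic intervals to nominate transcripts linked to
    the apomixis-controlling region, a highest-reciprocal-rank (HRR)
    Pearson coexpression network clustered with a heuristic cluster
    chiseling algorithm (HCCA) over node vicinity networks, seed
    first-neighbor subnetwork extraction, and hypergeometric GO
    over-representation with Bonferroni correction. A seeded synthetic
    expression-data generator with planted ground truth makes the whole
    pipeline testable without sequencing data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
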