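Package: RGscore
Title: Reference-Gene Suitability Scoring for qPCR Normalization from
    RNA-Seq Counts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores candidate reference genes for qPCR normalization from
    bulk RNA-seq count matrices with matched tumor/normal designs. Raw
    counts are TMM-normalized to counts per million; eleven parametric
    expression-stability components (pooled and paired trimmed fold
    changes, decile outlier statistics, within-pool variability, average
    expression, and Spearman correlations with six clinical
    characteristics) are combined by a weighted geometric mean into an
    expression score on a 0-100 scale. Multiplicative anti-scorings for
    somatic mutation burden, transcript-isoform count and pseudogene
    count yield a final score, and a negative-exponent power mean
    aggregates per-condition scores into a pan-cancer score. Advisory
    Gene Ontology keyword penalties and publication counts over a local
    abstract corpus support manual candidate triage, and optimal
    non-co-expressed reference-gene pairs are selected per condition. A
    synthetic-data generator emulates the full input contract so every
    step is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, Normalization, RNASeq, Software
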