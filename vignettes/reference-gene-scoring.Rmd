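---
title: "Scoring reference-gene candidates from RNA-seq counts"
author: "RGscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring reference-gene candidates from RNA-seq counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RGscore)
```

# The problem

Quantitative PCR measures a target gene's expression relative to a
reference gene (RG) assumed to have constant mRNA level across the
samples under study. In cancer cohorts that assumption fails routinely:
classic references such as *GAPDH* or *ACTB* shift between tumor and
normal tissue in many cancer types. Large tumor/normal RNA-seq cohorts
make it possible to screen candidates for expression stability before
committing to a qPCR design. RGscore implements a multi-component
scoring system for exactly that screen: from a raw count matrix plus
sample, clinical and gene-annotation tables, it produces per-gene
suitability scores, advisory annotation columns, pan-cancer aggregates
and optimal non-co-expressed RG pairs.

# The scoring model

## The parametric component curve

Every component scores one gene-level variable $x$ with the same
reversed-sigmoid curve:

$$S \;=\; \frac{100}{1 + Sq \cdot \left(\dfrac{\max(x - IV,\,0)}{IP - IV}\right)^{CS}}$$

* **IV** ("ideal value"): for $x \le IV$ the component saturates at 100 —
  variation below IV is considered biologically negligible.
* **IP** ("inflection point"): the marginally acceptable value of $x$;
  with $Sq = 1$, $S(IP) = 50$ exactly.
* **CS** ("curve slope"): the exponent controlling how sharply the score
  collapses past the ideal region; more important components get larger
  CS.
* **Sq** ("squeeze"): rescales the penalised region without moving the
  saturation boundary; $S(IP) = 100/(1+Sq)$ for any CS.

`componentScore()` implements the curve; it refuses non-finite $x$,
treating that as an upstream feature-extraction fault rather than
something to paper over.

## The 48 expression instances

Eleven expression components expand into 48 scored instances per gene
(`expandRegistry()`), each driven by one feature computed from
TMM-normalised counts per million (CPM):

| Component | Variable ($x$) | Applications |
|---|---|---|
| S_DP | abs. pooled trimmed log2 fold change (tumor vs normal means, 10–90th pct) | 1 |
| S_DL | abs. trimmed mean of per-pair log2 fold changes | 1 |
| S_DoO / S_DoU | abs. mean of the top / bottom decile of paired log2 fold changes | 1 + 1 |
| S_DLc | trimmed mean of absolute paired log2 fold changes | 1 |
| S_EStD | trimmed SD / trimmed mean of CPM (relative SD) | 2 (normal, tumor) |
| S_EoH / S_EoL | log2 of decile mean over trimmed mean (high / low outliers) | 2 + 2 |
| S_EA | $1/\log_2(\text{trimmed-mean tumor CPM})$ | 1 |
| S_Cp | $-\log_2 p$ of a clinical Spearman correlation | 18 (3 measures × 6 characteristics) |
| S_Cr | abs. Spearman $r_s$ of the same correlations | 18 |

The three expression measures for the correlation block are per-patient
tumor CPM, per-patient normal CPM and the paired log2 fold change, each
restricted to its 10–90th percentile samples before correlating; the six
characteristics are pathologic T, N, M, stage, the follow-up
person-neoplasm-cancer-status and the follow-up treatment-success
status. The curve and aggregation parameters of every component live in
`inst/extdata/scoring_config.yaml` and are the package defaults
(`defaultScoringConfig()`); any of them can be overridden through a user
YAML file.

## Aggregation

The expression score is a weighted geometric mean over the instances,

$$S^{Exp} = \left(\prod_i \min(S_i + CA_i,\,100)^{W_i}\right)^{1/\sum_i W_i},$$

computed in log space for numerical stability. $CA_i$ softens the impact
of one bad component; the components with $CA = 0$ (the pooled/paired
fold changes and average expression) retain veto power — a hard zero
zeroes $S^{Exp}$. The fold-change components carry the largest weights
($W = 4$), average expression $W = 6$ (so a low-expressed gene cannot
score well no matter how stable), and the 36 correlation instances carry
small weights (0.2–0.3 each) so they temper rather than dominate.

Three anti-scorings use the same curve on annotation variables: the
percentile of the gene's somatic-mutation count among all genes
(midrank convention, `mutationPercentile()`), the transcript-isoform
count and the pseudogene count. They multiply into the final score,
each scaled by 1/100:

$$S^{Final} = S^{Exp} \cdot \tfrac{S^{Mut}}{100} \cdot
  \tfrac{S^{Isoforms}}{100} \cdot \tfrac{S^{Pseudogenes}}{100}.$$

The 1/100 scaling is a deliberate normalisation choice: multiplying four
0–100 scores directly would put the product on a 0–10^8 scale, while
rankings are unchanged and the documented "theoretical maximum of 100"
is preserved. For the same reason $S_i + CA_i$ is clamped at 100 before
the geometric mean; without the clamp a component could exceed the
scale's ceiling.

## Pan-cancer aggregation

Across $M$ conditions, per-condition combined values
$v_j = S^{Exp}_j \cdot S^{Mut}_j/100$ aggregate through a power mean
with negative exponent $k = -0.4$ and constant add $CA = 12$:

$$S^{Exp\&Mut}_{Pan} = \left(\frac{1}{M}\sum_j (v_j + CA)^k\right)^{1/k}.$$

A negative exponent makes the mean harmonic-like: one unstable condition
drags the aggregate down, which is the behaviour wanted from a
"universal" RG screen. The formula carries the $+CA$ offset through:
identical inputs $v$ return $v + 12$, and the package reports the value
as the formula defines it rather than subtracting the offset afterwards
— only the ranking matters downstream, and `runPanCancer()` records
$M$, $k$ and $CA$ as attributes of its output. A gene absent from some
conditions is aggregated over the conditions it has, with its own $M$
recorded and a `partial` flag set.

## Advisory annotation components

Two further components are deliberately *not* folded into
$S^{Final}$; they are reported for manual triage:

* **GO keyword penalty** (`goPenalty()`): six categories of
  cancer-associated processes — cell cycle (5 points), differentiation
  (4), stress response (3), immune response (2), angiogenesis (2),
  intercellular interactions (2) — matched case-insensitively as
  substrings of the gene's GO term names; maximum 18 raw points. The raw
  score is normalised by (number of GO terms)^0.3 to balance annotation
  depth against study bias; a gene with fewer than 3 terms gets a flat
  10-point penalty, undivided, since nothing reliable is known about it.
* **Publication counts** (`publicationCounts()`): mentions of the gene
  or an alias (word-boundary match over title + abstract of a local
  corpus), and the subset whose titles contain a cancer keyword
  (`cancer`, `tumor`, `*carcinoma` as a wildcard suffix, `sarcoma`,
  `glioma`, `glioblastoma`; an extension list — leukemia, lymphoma,
  melanoma, neoplasm, oncogene, metastasis — ships in the configuration,
  clearly separated so it can be edited or disabled).

## Pair selection

`selectPair()` returns, per condition, the pair of genes that are both
highly scored and not co-expressed: among genes with $S^{Exp}$ above the
threshold (default 65), all pairs with $|r_s|$ of tumor-pool CPM below
the cutoff are eligible, and the pair maximising the geometric mean of
the two expression scores wins, with a lexicographic tie-break. Both the
cutoff ($|r_s| < 0.5$) and the use of the tumor pool (the larger one)
are package choices exposed in the configuration, as is the pair
objective — selecting on the product of scores is one reasonable reading
of "focus on the expression scores", and it is deterministic. When no
pair qualifies, the best-available pair is returned flagged ineligible
rather than nothing, so reports stay complete.

# Numerical conventions

* **Percentile bands.** A value is kept by the $lo$–$hi$ band iff its
  fractional rank $(i - 0.5)/n$ lies in $[lo/100, hi/100)$. This single
  convention defines the 10–90 trims and the 0–10/90–100 deciles
  everywhere (so for $n = 10$ the top decile is exactly the largest
  value), is deterministic under ties, and is mirrored by the
  independent sort-and-slice oracle in the test suite. If a narrow band
  is empty on a very small vector, the mean falls back to the order
  statistic nearest the band midpoint; a trimmed SD on fewer than two
  surviving values is an error.
* **Pseudocount.** Every log2 ratio adds $\varepsilon = 0.25$ CPM to
  numerator and denominator. This is small relative to the CPM floor
  below which the average-expression component zeroes a gene, so it
  protects against zeros without distorting expressed genes.
* **Low-expression sentinel.** Genes with trimmed-mean tumor CPM below
  2 (or $\le 1$, where $1/\log_2$ degenerates) keep their row but have
  the average-expression instance scored 0 — with $W = 6$ this
  effectively removes them while keeping output rows stable across
  runs.
* **TMM.** Scaling factors follow the trimmed mean of M-values
  procedure: 30% two-sided trim on log-ratios, 5% on average log
  abundance, inverse-variance precision weights, reference column by
  upper-quartile proximity, factors rescaled to geometric mean 1.
  All-zero genes are excluded from estimation but retained as zero CPM.
  The test suite cross-checks the implementation against
  `edgeR::calcNormFactors` on fixed and random matrices.
* **Spearman p-values** use the large-sample t approximation; exact
  permutation appears only as a test oracle. Degenerate correlations
  (fewer than 3 complete patients, a single-level characteristic, a
  constant expression vector) return $r_s = 0,\ p = 1$ — maximally
  stable — with a flag, so missing clinical data never punishes a gene.
* **Clinical encodings.** Stage I–IV → 1–4 with sub-letters stripped;
  pathologic T/N/M use their numeric index with Tis/TX/NX/MX as
  missing; tumor free/with tumor → 0/1; treatment success from complete
  remission (0) to progressive disease (3). These orderings are the
  natural severity orderings; only rank matters to Spearman.
* **Datasets without pairs** fall back to the pooled fold change for
  the paired components and neutralise the paired correlation measure,
  with a flag and a warning — pooled-only cohorts still get a usable
  (if less informative) score.

# The synthetic test-bed

Real inputs of this kind (cohort read counts, isoform/pseudogene
tables, somatic-mutation tallies) cannot ship with a package, so
`generateSyntheticData()` emulates the full input contract:
negative-binomial counts around per-gene CPM targets with log-normal
library-size variation, matched tumor/normal pairs sharing patient ids,
clinical tables derived from a latent per-patient severity variable
(with ~5% missingness and occasional TX entries), annotation tables, GO
term assignments and a small abstract corpus. Gene roles cover the
behaviours the scoring system must discriminate: one designed "ideal"
reference gene — stable, high CPM, one isoform, no pseudogenes,
near-zero mutation rate, neutral GO annotation — plus stable genes
carrying realistic annotation burdens (a typical human gene has several
transcript isoforms, so the ideal profile is the unique annotation-clean
one by construction), tumor-shifted genes (|log2 shift| ∈ [0.5, 2]),
over-dispersed genes, genes below the expression floor, clinically
associated genes (expression coupled to the clinical latent variable
through a Gaussian copula on ranks), and outlier-prone genes.
Generation is bit-reproducible for a fixed seed, and
`writeSyntheticData()` emits exactly the TSV dialects the pipeline
consumes.

What the generator does **not** emulate: TCGA batch structure, tumor
purity, molecular subtypes, gene–gene correlation beyond the designed
blocks, or realistic GO/PubMed annotation breadth. Passing tests on
this test-bed therefore demonstrate that the scoring machinery ranks
designed stability correctly under count noise — not that any specific
real gene is a good reference in any specific cancer.

Test problem sizes are chosen to exercise the statistics at meaningful
sample counts while staying quick: the ranking-recovery suite runs 20
seeds of a 50-gene panel with 60 tumor / 30 normal samples and 30
pairs; distributional checks use 60 pairs where law-of-large-numbers
accuracy (±0.1 log2 units on a trimmed fold change) is asserted.

# Known limitations

* The correlation components assume one tumor sample per patient is
  representative; multiple samples per patient are averaged.
* The GO penalty matches directly assigned term names only — no
  ontology graph traversal or ancestor propagation — and keyword lists
  are substring-based, so term-name phrasing matters.
* The cancer-keyword list for publication triage is open-ended by
  nature; the shipped extension is an editable approximation.
* Scores are comparable within a run, not across cohorts of very
  different size: correlation p-values sharpen with cohort size, so the
  36 correlation instances bite harder in large cohorts.
* TMM assumes most genes are not differentially expressed; panels
  engineered to violate this (many strongly shifted genes, all in one
  direction) bias the factors and thereby the pooled fold changes.
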