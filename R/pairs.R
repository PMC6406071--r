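#' Co-expression between two candidate reference genes
#'
#' Spearman correlation of two genes' CPM across a sample subset. A pair
#' of reference genes must not be co-expressed, otherwise a shared
#' regulatory artefact would go undetected by dual-gene normalisation.
#' Constant expression vectors make the correlation undefined; such pairs
#' return `r = 0` with a flag.
#'
#' @param cpm Gene x sample CPM matrix.
#' @param geneA,geneB Row names in `cpm`.
#' @param samples Column subset (>= 3 samples); default all columns.
#' @return List with `r` and `flag`.
#' @export
coexpression <- function(cpm, geneA, geneB, samples = colnames(cpm)) {
  if (length(samples) < 3L) stop("co-expression needs at least 3 samples")
  if (!all(c(geneA, geneB) %in% rownames(cpm)))
    stop("gene(s) not present in the CPM matrix")
  a <- cpm[geneA, samples]
  b <- cpm[geneB, samples]
  if (length(unique(a)) < 2L || length(unique(b)) < 2L)
    return(list(r = 0, flag = TRUE))
  list(r = stats::cor(rank(a), rank(b)), flag = FALSE)
}

#' Select the optimal reference-gene pair
#'
#' Among genes whose expression score exceeds `scoreThreshold`, all pairs
#' with absolute co-expression below `rCutoff` are eligible; the pair
#' maximising the geometric mean of the two expression scores wins, with
#' lexicographic gene-id tie-break. When fewer than two genes pass the
#' threshold, or no pair passes the co-expression cutoff, the
#' best-available pair is returned flagged ineligible.
#'
#' @param scores data.frame with columns `gene`, `s_exp` (e.g. from
#'   [scoreTable()]), or an [RGScores-class].
#' @param cpm Gene x sample CPM matrix.
#' @param samples Sample subset for the co-expression correlation
#'   (conventionally the tumor pool, the larger one).
#' @param scoreThreshold Minimum per-gene expression score (default 65).
#' @param rCutoff Maximum absolute co-expression (default 0.5).
#' @return List with `best` (one-row data.frame: `gene_a`, `gene_b`,
#'   `s_exp_a`, `s_exp_b`, `r_s`, `eligible`) and `eligible` (all
#'   eligible pairs ranked by decreasing score geometric mean).
#' @export
selectPair <- function(scores, cpm, samples = colnames(cpm),
                       scoreThreshold = 65, rCutoff = 0.5) {
  if (is(scores, "RGScores")) scores <- scoreTable(scores)
  stopifnot(all(c("gene", "s_exp") %in% names(scores)))
  if (nrow(scores) < 2L) stop("pair selection needs at least 2 genes")
  scores <- scores[order(scores$gene), , drop = FALSE]
  cand <- scores[scores$s_exp > scoreThreshold, , drop = FALSE]
  fallback <- FALSE
  if (nrow(cand) < 2L) {
    fallback <- TRUE
    cand <- scores[order(-scores$s_exp, scores$gene), , drop = FALSE]
    cand <- utils::head(cand, 2)
  }
  idx <- utils::combn(nrow(cand), 2)
  pairTab <- do.call(rbind, lapply(seq_len(ncol(idx)), function(k) {
    i <- idx[1, k]; j <- idx[2, k]
    ga <- cand$gene[i]; gb <- cand$gene[j]
    if (ga > gb) { tmp <- ga; ga <- gb; gb <- tmp
                   i2 <- j; j <- i; i <- i2 }
    cx <- coexpression(cpm, ga, gb, samples)
    data.frame(gene_a = ga, gene_b = gb,
               s_exp_a = cand$s_exp[i], s_exp_b = cand$s_exp[j],
               r_s = cx$r, r_flag = cx$flag)
  }))
  pairTab$gm <- sqrt(pairTab$s_exp_a * pairTab$s_exp_b)
  pairTab$eligible <- !fallback &
    pmin(pairTab$s_exp_a, pairTab$s_exp_b) > scoreThreshold &
    abs(pairTab$r_s) < rCutoff
  pairTab <- pairTab[order(-pairTab$gm, pairTab$gene_a, pairTab$gene_b), ,
                     drop = FALSE]
  eligible <- pairTab[pairTab$eligible, , drop = FALSE]
  best <- if (nrow(eligible)) eligible[1, , drop = FALSE]
          else pairTab[1, , drop = FALSE]
  rownames(best) <- NULL
  rownames(eligible) <- NULL
  list(best = best, eligible = eligible)
}
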