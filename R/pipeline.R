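#' Score every gene of one condition
#'
#' The per-condition scoring run: extracts the expression features,
#' evaluates the 48 component instances with their configured curves,
#' aggregates them into the expression score, applies the three
#' anti-scorings from the gene annotation, and attaches the advisory
#' GO-penalty and publication-count columns when the corresponding
#' annotations are supplied. Genes missing from the annotation table
#' receive neutral anti-scores (100) with a warning, or are skipped,
#' per `missingAnnotation`.
#'
#' @param dataset An [RGDataset-class].
#' @param annotation Optional data.frame with columns `gene`,
#'   `n_isoforms`, `n_pseudogenes` and (optionally) `mutation_count`,
#'   `aliases`.
#' @param goTerms Optional data.frame `gene`, `go_terms`
#'   (semicolon-joined term names).
#' @param corpus Optional abstract corpus (`id`, `title`, `abstract`).
#' @param config Scoring configuration.
#' @param condition Condition label carried into outputs.
#' @param strict Passed to [buildRegistry()].
#' @param missingAnnotation `"neutral"` or `"skip"`.
#' @return An [RGScores-class].
#' @export
scoreCondition <- function(dataset, annotation = NULL, goTerms = NULL,
                           corpus = NULL, config = defaultScoringConfig(),
                           condition = "condition", strict = TRUE,
                           missingAnnotation = c("neutral", "skip")) {
  missingAnnotation <- match.arg(missingAnnotation)
  registry <- buildRegistry(config, strict = strict)
  instances <- expandRegistry(registry, config)
  fx <- extractFeatures(dataset, config)
  genes <- rownames(fx$features)
  flags <- fx$flags

  xv <- .instanceXValues(fx, instances)
  breakdown <- matrix(NA_real_, length(genes), nrow(instances),
                      dimnames = list(genes, instances$instance))
  for (j in seq_len(nrow(instances))) {
    p <- instances[j, ]
    x <- xv[, j]
    sc <- rep(0, length(x))
    ok <- is.finite(x)
    sc[ok] <- componentScore(x[ok], p$iv, p$ip, p$cs, p$sq)
    breakdown[, j] <- sc   # non-finite x = low-expression sentinel -> 0
  }
  sExp <- vapply(genes, function(g)
    aggregateExpressionScore(breakdown[g, ], instances), numeric(1))

  if (!is.null(annotation)) {
    m <- match(genes, annotation$gene)
    if (anyNA(m)) {
      if (missingAnnotation == "skip") {
        flags <- c(flags, sprintf("%d gene(s) without annotation skipped",
                                  sum(is.na(m))))
        keep <- !is.na(m)
        genes <- genes[keep]; breakdown <- breakdown[keep, , drop = FALSE]
        xv <- xv[keep, , drop = FALSE]; sExp <- sExp[keep]
        m <- m[keep]
      } else {
        flags <- c(flags, sprintf(
          "%d gene(s) without annotation given neutral anti-scores",
          sum(is.na(m))))
      }
    }
    mutCount <- annotation$mutation_count
    mutPct <- if (!is.null(mutCount) && sum(!is.na(mutCount)) >= 2) {
      pct <- rep(NA_real_, nrow(annotation))
      okm <- !is.na(mutCount)
      pct[okm] <- mutationPercentile(mutCount[okm])
      pct
    } else rep(NA_real_, nrow(annotation))
    anti <- suppressWarnings(antiScores(
      mutPct[m], annotation$n_isoforms[m], annotation$n_pseudogenes[m],
      config))
  } else {
    flags <- c(flags, "no gene annotation: anti-scores neutral (100)")
    anti <- data.frame(s_mut = rep(100, length(genes)),
                       s_isoforms = 100, s_pseudogenes = 100)
  }

  scores <- DataFrame(
    gene = genes, s_exp = unname(sExp),
    s_mut = anti$s_mut, s_isoforms = anti$s_isoforms,
    s_pseudogenes = anti$s_pseudogenes,
    s_final = finalScore(unname(sExp), anti$s_mut, anti$s_isoforms,
                         anti$s_pseudogenes))

  advisory <- .advisoryColumns(genes, annotation, goTerms, corpus, config)

  new("RGScores", condition = condition, scores = scores,
      breakdown = breakdown, xvalues = xv,
      advisory = advisory, instances = instances, flags = flags)
}

.instanceXValues <- function(fx, instances) {
  ft <- fx$features
  genes <- rownames(ft)
  xv <- matrix(NA_real_, length(genes), nrow(instances),
               dimnames = list(genes, instances$instance))
  for (j in seq_len(nrow(instances))) {
    inst <- instances$instance[j]
    id <- instances$id[j]
    xv[, j] <- switch(id,
      S_DP  = abs(ft$log2fc_p),
      S_DL  = abs(ft$avg_log2fc_l_10_90),
      S_DoO = abs(ft$avg_log2fc_l_90_100),
      S_DoU = abs(ft$avg_log2fc_l_0_10),
      S_DLc = ft$avg_abs_log2fc_l_10_90,
      S_EStD = if (endsWith(inst, ".normal")) ft$relsd_normal
               else ft$relsd_tumor,
      S_EoH = pmax(if (endsWith(inst, ".normal")) ft$outlier_hi_normal
                   else ft$outlier_hi_tumor, 0),
      S_EoL = pmax(if (endsWith(inst, ".normal")) ft$outlier_lo_normal
                   else ft$outlier_lo_tumor, 0),
      S_EA  = ft$inv_log2_cpm,
      S_Cp  = {
        key <- sub("^S_Cp\\.", "", inst)
        -log2(pmax(fx$corrP[, key], .Machine$double.xmin))
      },
      S_Cr  = {
        key <- sub("^S_Cr\\.", "", inst)
        abs(fx$corrR[, key])
      },
      stop("no feature mapping for component ", id))
  }
  xv
}

.advisoryColumns <- function(genes, annotation, goTerms, corpus, config) {
  adv <- DataFrame(row.names = genes)
  if (!is.null(goTerms)) {
    m <- match(genes, goTerms$gene)
    res <- lapply(seq_along(genes), function(i) {
      terms <- if (is.na(m[i])) character(0)
               else strsplit(goTerms$go_terms[m[i]], ";", fixed = TRUE)[[1]]
      goPenalty(terms, config)
    })
    adv$go_raw_points <- vapply(res, `[[`, numeric(1), "raw_points")
    adv$go_normalized_penalty <-
      vapply(res, `[[`, numeric(1), "normalized_penalty")
    adv$go_n_terms <- vapply(res, `[[`, numeric(1), "n_terms")
    adv$go_insufficient <- vapply(res, `[[`, logical(1), "insufficient")
  }
  if (!is.null(corpus)) {
    aliases <- function(g) {
      if (!is.null(annotation) && "aliases" %in% names(annotation)) {
        i <- match(g, annotation$gene)
        if (!is.na(i))
          return(strsplit(annotation$aliases[i], ";", fixed = TRUE)[[1]])
      }
      g
    }
    pc <- lapply(genes, function(g)
      publicationCounts(corpus, aliases(g), config))
    adv$pubmed_total <- vapply(pc, `[[`, integer(1), "total_mentions")
    adv$pubmed_cancer <- vapply(pc, `[[`, integer(1), "cancer_mentions")
  }
  adv
}

#' Run one condition from files
#'
#' Thin file-level wrapper: reads the TSV inputs, builds the
#' [RGDataset-class], runs [scoreCondition()], and writes the scorecard
#' TSV, a ranked top-k report and the pair-selection report into
#' `outDir`.
#'
#' @param countsFile,samplesFile,clinicalFile,annotationFile,goFile,corpusFile
#'   Input paths (the last three optional, `NULL` to omit).
#' @param outDir Output directory.
#' @param condition Condition label.
#' @param topK Rows in the top-k report (default 5).
#' @param config Scoring configuration.
#' @param strict Passed to [buildRegistry()].
#' @return The [RGScores-class], invisibly.
#' @export
runCondition <- function(countsFile, samplesFile, clinicalFile = NULL,
                         annotationFile = NULL, goFile = NULL,
                         corpusFile = NULL, outDir = ".",
                         condition = "condition", topK = 5,
                         config = defaultScoringConfig(), strict = TRUE) {
  counts <- readCountsTSV(countsFile)
  samples <- readSampleSheet(samplesFile)
  if (!any(samples$tissue == "normal"))
    stop("condition '", condition, "': no normal samples; aborting")
  clinical <- if (!is.null(clinicalFile)) readClinicalTSV(clinicalFile)
  annotation <- if (!is.null(annotationFile)) readGeneAnnotation(annotationFile)
  goTerms <- if (!is.null(goFile)) readGoTerms(goFile)
  corpus <- if (!is.null(corpusFile)) readCorpus(corpusFile)
  dataset <- RGDataset(counts, samples, clinical, config = config)
  res <- scoreCondition(dataset, annotation, goTerms, corpus, config,
                        condition = condition, strict = strict)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeScores(res, file.path(outDir, paste0(condition, "_scores.tsv")))
  top <- topGenes(res, topK)
  utils::write.table(top, file.path(outDir, paste0(condition, "_top.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  pool <- config$pair$pool %||% "tumor"
  sub <- if (pool == "tumor") tumorSamples(dataset) else normalSamples(dataset)
  pr <- selectPair(res, cpmValues(dataset), sub,
                   config$pair$score_threshold %||% 65,
                   config$pair$r_cutoff %||% 0.5)
  pairOut <- cbind(condition = condition,
                   rbind(pr$best,
                         pr$eligible[
                           !(paste(pr$eligible$gene_a, pr$eligible$gene_b)
                             %in% paste(pr$best$gene_a, pr$best$gene_b)), ,
                           drop = FALSE]))
  utils::write.table(pairOut,
                     file.path(outDir, paste0(condition, "_pairs.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(flags(res)))
    message("flags for ", condition, ":\n  ",
            paste(flags(res), collapse = "\n  "))
  invisible(res)
}

#' Pan-cancer aggregation across conditions
#'
#' Aggregates per-condition expression and mutation scores per gene with
#' the negative-exponent power mean and multiplies by the
#' (condition-independent) isoform and pseudogene anti-scores. A gene
#' missing from some conditions is aggregated over the conditions it has
#' (with `m` recording that count) and flagged.
#'
#' @param results List of [RGScores-class], one per condition (>= 2).
#' @param k,ca Power-mean exponent and constant add (defaults from the
#'   configuration: -0.4 and 12).
#' @param config Scoring configuration.
#' @return data.frame sorted by decreasing `s_final_pan`: `gene`, `m`,
#'   `s_exp_mut_pan`, `s_isoforms`, `s_pseudogenes`, `s_final_pan`,
#'   `partial` (TRUE when scored over a strict subset of conditions).
#'   The attribute `"m_total"` records the number of conditions
#'   supplied.
#' @export
runPanCancer <- function(results, k = NULL, ca = NULL,
                         config = defaultScoringConfig()) {
  if (length(results) < 2L)
    stop("pan-cancer aggregation needs at least 2 completed conditions")
  k <- k %||% config$pan_cancer$k %||% -0.4
  ca <- ca %||% config$pan_cancer$ca %||% 12
  tabs <- lapply(results, scoreTable)
  allGenes <- sort(unique(unlist(lapply(tabs, `[[`, "gene"))))
  common <- Reduce(intersect, lapply(tabs, `[[`, "gene"))
  if (length(common) < length(allGenes))
    message("gene universes differ across conditions: ",
            length(allGenes) - length(common),
            " gene(s) scored over a subset of conditions")
  rows <- lapply(allGenes, function(g) {
    per <- do.call(rbind, lapply(tabs, function(t)
      t[t$gene == g, c("s_exp", "s_mut", "s_isoforms", "s_pseudogenes")]))
    pan <- panCancerScore(per$s_exp, per$s_mut,
                          sIsoforms = per$s_isoforms[1],
                          sPseudogenes = per$s_pseudogenes[1],
                          k = k, ca = ca)
    data.frame(gene = g, m = pan$m, s_exp_mut_pan = pan$sExpMutPan,
               s_isoforms = per$s_isoforms[1],
               s_pseudogenes = per$s_pseudogenes[1],
               s_final_pan = pan$sFinalPan,
               partial = pan$m < length(results))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$s_final_pan, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_total") <- length(results)
  attr(out, "k") <- k
  attr(out, "ca") <- ca
  out
}
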