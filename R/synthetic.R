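#' Synthetic gene panel specification
#'
#' Builds the per-gene profile table for the synthetic-data generator.
#' Roles emulate the behaviours the scoring system must discriminate:
#' one designed "ideal" reference gene (high stable expression, no
#' tumor shift, one transcript isoform, no pseudogenes, near-zero
#' mutation rate, neutral GO annotation); additional stable genes that
#' carry annotation burdens (isoforms, pseudogenes, mutations) so only
#' the ideal gene is penalty-free; tumor-shifted genes (|log2 shift|
#' drawn from 0.5-2); high-dispersion genes; low-expression genes below
#' the CPM floor; clinically associated genes; and outlier-prone genes.
#'
#' @param nGenes Number of genes (>= 10).
#' @param seed Random seed for the profile draws.
#' @return data.frame with one row per gene: `gene`, `role`, `base_cpm`,
#'   `tumor_shift`, `nb_size` (negative-binomial size; larger = less
#'   dispersed), `outlier_frac`, `outlier_mag`, `clinical_assoc`,
#'   `n_isoforms`, `n_pseudogenes`, `mutation_rate`, `go_profile`,
#'   `pubmed_cancer`.
#' @export
syntheticPanel <- function(nGenes = 50, seed = 1) {
  if (nGenes < 10L) stop("'nGenes' must be at least 10")
  .withSeed(seed, {
    nStable <- max(2L, round(0.16 * nGenes))
    nShifted <- max(2L, round(0.36 * nGenes))
    nNoisy <- max(1L, round(0.12 * nGenes))
    nLow <- max(1L, round(0.10 * nGenes))
    nClin <- max(1L, round(0.10 * nGenes))
    nOut <- nGenes - 1L - nStable - nShifted - nNoisy - nLow - nClin
    if (nOut < 0L) { nShifted <- nShifted + nOut; nOut <- 0L }
    roles <- c("ideal", rep("stable", nStable), rep("shifted", nShifted),
               rep("noisy", nNoisy), rep("low", nLow),
               rep("clinical", nClin), rep("outlier", nOut))
    n <- length(roles)
    panel <- data.frame(
      gene = sprintf("G%03d", seq_len(n)),
      role = roles,
      base_cpm = 0, tumor_shift = 0, nb_size = 100,
      outlier_frac = 0, outlier_mag = 1, clinical_assoc = 0,
      n_isoforms = 1L, n_pseudogenes = 0L, mutation_rate = 5,
      go_profile = "neutral", pubmed_cancer = FALSE,
      stringsAsFactors = FALSE)
    for (i in seq_len(n)) {
      r <- roles[i]
      if (r == "ideal") {
        panel$base_cpm[i] <- 500; panel$nb_size[i] <- 400
        panel$mutation_rate[i] <- 0.5
      } else if (r == "stable") {
        panel$base_cpm[i] <- round(runif(1, 150, 800))
        panel$tumor_shift[i] <- runif(1, -0.05, 0.05)
        panel$nb_size[i] <- 400
        panel$n_isoforms[i] <- sample(3:8, 1)
        panel$n_pseudogenes[i] <- sample(1:6, 1)
        panel$mutation_rate[i] <- runif(1, 40, 120)
        panel$go_profile[i] <- sample(c("neutral", "cancer"), 1)
        panel$pubmed_cancer[i] <- runif(1) < 0.5
      } else if (r == "shifted") {
        panel$base_cpm[i] <- round(runif(1, 50, 600))
        panel$tumor_shift[i] <- sample(c(-1, 1), 1) * runif(1, 0.5, 2)
        panel$nb_size[i] <- 100
        panel$n_isoforms[i] <- sample(1:5, 1)
        panel$n_pseudogenes[i] <- sample(0:3, 1)
        panel$mutation_rate[i] <- runif(1, 5, 60)
        panel$go_profile[i] <- sample(c("neutral", "cancer"), 1,
                                      prob = c(0.3, 0.7))
        panel$pubmed_cancer[i] <- runif(1) < 0.7
      } else {
        # all remaining roles: a typical human gene carries several
        # transcript isoforms and often a pseudogene, so only the
        # designed ideal profile is annotation-clean
        panel$n_isoforms[i] <- sample(2:6, 1)
        panel$n_pseudogenes[i] <- sample(0:2, 1)
        panel$mutation_rate[i] <- runif(1, 5, 40)
        if (r == "noisy") {
          panel$base_cpm[i] <- round(runif(1, 100, 500))
          panel$tumor_shift[i] <- runif(1, -0.1, 0.1)
          panel$nb_size[i] <- 2
        } else if (r == "low") {
          panel$base_cpm[i] <- runif(1, 0.3, 1.5)
          panel$nb_size[i] <- 50
          panel$go_profile[i] <- "sparse"
        } else if (r == "clinical") {
          panel$base_cpm[i] <- round(runif(1, 100, 500))
          panel$nb_size[i] <- 400
          panel$clinical_assoc[i] <- 0.6
        } else { # outlier
          panel$base_cpm[i] <- round(runif(1, 100, 500))
          panel$nb_size[i] <- 200
          panel$outlier_frac[i] <- 0.08
          panel$outlier_mag[i] <- 8
        }
      }
    }
    panel
  })
}

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.neutralGoTerms <- c(
  "rRNA processing", "tRNA aminoacylation for protein translation",
  "cytoplasmic translation", "ribosome biogenesis",
  "mRNA splicing, via spliceosome", "protein folding",
  "intracellular protein transport", "vesicle-mediated transport",
  "tRNA processing", "RNA metabolic process", "protein glycosylation",
  "nucleocytoplasmic transport", "proteolysis",
  "ubiquitin-dependent protein catabolic process")

.cancerGoTerms <- c(
  "mitotic cell cycle", "apoptotic process", "cell differentiation",
  "cellular response to stress", "immune response",
  "sprouting angiogenesis", "cell adhesion",
  "positive regulation of cell proliferation", "DNA repair",
  "cell migration", "inflammatory response")

#' Generate a synthetic condition dataset
#'
#' Emulates one condition's full input contract: a negative-binomial
#' gene x sample count matrix with per-sample library-size variation, a
#' sample sheet with tumor/normal classes and patient ids (the first
#' `nPairs` patients contribute matched tumor-normal pairs), a
#' per-patient clinical table whose six characteristics derive from a
#' latent severity variable, a gene annotation table (aliases, isoform,
#' pseudogene and mutation counts), GO term assignments and a small
#' abstract corpus. Clinically associated genes share the latent
#' variable with expression through a Gaussian copula on ranks at the
#' profiled strength. Generation is reproducible: a fixed seed yields
#' identical output.
#'
#' @param nGenes,nTumor,nNormal,nPairs Panel and cohort sizes; `nPairs`
#'   must not exceed `min(nTumor, nNormal)`.
#' @param seed Random seed.
#' @param meanLibSize Mean library size in reads (default 2e6).
#' @param panel Optional pre-built [syntheticPanel()] table.
#' @param config Scoring configuration (TMM constants for the dataset).
#' @return List with `dataset` ([RGDataset-class]), `annotation`,
#'   `goTerms`, `corpus`, `panel`, and `spec` (the generation
#'   parameters).
#' @export
generateSyntheticData <- function(nGenes = 50, nTumor = 60, nNormal = 30,
                                  nPairs = 30, seed = 1,
                                  meanLibSize = 2e6, panel = NULL,
                                  config = defaultScoringConfig()) {
  if (nPairs > min(nTumor, nNormal))
    stop("'nPairs' cannot exceed min(nTumor, nNormal)")
  if (is.null(panel)) panel <- syntheticPanel(nGenes, seed = seed)
  nGenes <- nrow(panel)
  .withSeed(seed + 1L, {
    tumorPat <- sprintf("P%03d", seq_len(nTumor))
    normalPat <- c(tumorPat[seq_len(nPairs)],
                   if (nNormal > nPairs)
                     sprintf("P9%02d", seq_len(nNormal - nPairs)))
    patients <- unique(c(tumorPat, normalPat))
    z <- setNames(rnorm(length(patients)), patients)

    samples <- data.frame(
      sample_id = c(paste0(tumorPat, "_T"), paste0(normalPat, "_N")),
      patient_id = c(tumorPat, normalPat),
      tissue = rep(c("tumor", "normal"), c(nTumor, nNormal)),
      stringsAsFactors = FALSE)
    lib <- setNames(round(meanLibSize * exp(rnorm(nrow(samples), 0, 0.3))),
                    samples$sample_id)

    counts <- matrix(0L, nGenes, nrow(samples),
                     dimnames = list(panel$gene, samples$sample_id))
    for (i in seq_len(nGenes)) {
      mu_cpm <- rep(panel$base_cpm[i], nrow(samples))
      isT <- samples$tissue == "tumor"
      mu_cpm[isT] <- mu_cpm[isT] * 2^panel$tumor_shift[i]
      if (panel$clinical_assoc[i] > 0) {
        rho <- panel$clinical_assoc[i]
        e <- rho * z[samples$patient_id] +
          sqrt(1 - rho^2) * rnorm(nrow(samples))
        mu_cpm <- mu_cpm * 2^(0.8 * e)
      }
      mu <- mu_cpm * lib / 1e6
      cnt <- rnbinom(nrow(samples), mu = mu, size = panel$nb_size[i])
      if (panel$outlier_frac[i] > 0) {
        hit <- runif(nrow(samples)) < panel$outlier_frac[i]
        cnt[hit] <- cnt[hit] * panel$outlier_mag[i]
      }
      counts[i, ] <- as.integer(cnt)
    }

    clinical <- .syntheticClinical(patients, z)
    annotation <- data.frame(
      gene = panel$gene,
      aliases = paste(panel$gene, paste0(panel$gene, "L"), sep = ";"),
      n_isoforms = panel$n_isoforms,
      n_pseudogenes = panel$n_pseudogenes,
      mutation_count = rpois(nGenes, panel$mutation_rate),
      stringsAsFactors = FALSE)
    goTerms <- data.frame(
      gene = panel$gene,
      go_terms = vapply(seq_len(nGenes), function(i)
        paste(.syntheticGo(panel$go_profile[i]), collapse = ";"),
        character(1)),
      stringsAsFactors = FALSE)
    corpus <- .syntheticCorpus(panel)

    dataset <- RGDataset(counts, samples, clinical, config = config)
    list(dataset = dataset, annotation = annotation, goTerms = goTerms,
         corpus = corpus, panel = panel,
         spec = list(nGenes = nGenes, nTumor = nTumor, nNormal = nNormal,
                     nPairs = nPairs, seed = seed,
                     meanLibSize = meanLibSize))
  })
}

.syntheticClinical <- function(patients, z) {
  n <- length(patients)
  noisy <- function(rho) rho * z[patients] + sqrt(1 - rho^2) * rnorm(n)
  lv <- function(v, br, labels) labels[findInterval(v, br) + 1L]
  stage <- lv(noisy(0.8), stats::qnorm(c(0.3, 0.6, 0.85)),
              c("Stage I", "Stage II", "Stage III", "Stage IV"))
  pt <- lv(noisy(0.7), stats::qnorm(c(0.25, 0.55, 0.8)),
           c("T1", "T2", "T3", "T4"))
  pn <- lv(noisy(0.6), stats::qnorm(c(0.5, 0.8)), c("N0", "N1", "N2"))
  pm <- lv(noisy(0.5), stats::qnorm(0.85), c("M0", "M1"))
  status <- ifelse(noisy(0.6) > stats::qnorm(0.6),
                   "with tumor", "tumor free")
  trt <- lv(noisy(0.6), stats::qnorm(c(0.5, 0.7, 0.85)),
            c("complete remission/response", "partial remission/response",
              "stable disease", "progressive disease"))
  out <- data.frame(patient_id = patients, pathologic_t = pt,
                    pathologic_n = pn, pathologic_m = pm,
                    pathologic_stage = stage,
                    neoplasm_cancer_status = status,
                    treatment_success = trt, stringsAsFactors = FALSE)
  for (col in setdiff(names(out), "patient_id")) {
    miss <- runif(n) < 0.05
    out[[col]][miss] <- NA
  }
  ix <- runif(n) < 0.02
  out$pathologic_t[ix & !is.na(out$pathologic_t)] <- "TX"
  out
}

.syntheticGo <- function(profile) {
  switch(profile,
    neutral = sample(.neutralGoTerms, sample(4:8, 1)),
    cancer = c(sample(.cancerGoTerms, sample(2:4, 1)),
               sample(.neutralGoTerms, sample(2:4, 1))),
    sparse = sample(.neutralGoTerms, sample(1:2, 1)),
    stop("unknown GO profile: ", profile))
}

.syntheticCorpus <- function(panel) {
  rows <- list()
  idc <- 0L
  for (i in seq_len(nrow(panel))) {
    g <- panel$gene[i]
    nRec <- sample(1:3, 1)
    for (k in seq_len(nRec)) {
      idc <- idc + 1L
      cancerRec <- panel$pubmed_cancer[i] && k == 1L
      title <- if (cancerRec)
        sprintf("Role of %s in breast cancer progression", g)
      else
        sprintf("Characterization of the %s gene in human tissues", g)
      rows[[idc]] <- data.frame(
        id = sprintf("SYN%06d", idc), title = title,
        abstract = sprintf(
          "We examined expression of %s (also known as %sL) across cohorts.",
          g, g),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a synthetic dataset to TSV files
#'
#' Emits exactly the file dialects the pipeline consumes: `counts.tsv`
#' (first column `gene`, then one column per sample), `samples.tsv`,
#' `clinical.tsv` (missing values as empty fields), `annotation.tsv`,
#' `go_terms.tsv` (semicolon-joined term names), `corpus.tsv`, and a
#' `manifest.yaml` recording the generation parameters.
#'
#' @param x Output of [generateSyntheticData()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeSyntheticData <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE, na = "")
  counts <- assay(x$dataset, "counts")
  tsv(data.frame(gene = rownames(counts), counts, check.names = FALSE),
      "counts.tsv")
  cd <- as.data.frame(colData(x$dataset))
  tsv(cd[, c("sample_id", "patient_id", "tissue")], "samples.tsv")
  tsv(clinicalTable(x$dataset), "clinical.tsv")
  tsv(x$annotation, "annotation.tsv")
  tsv(x$goTerms, "go_terms.tsv")
  tsv(x$corpus, "corpus.tsv")
  yaml::write_yaml(x$spec, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
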