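#' ComponentSpec: one scoring component
#'
#' Identity, curve parameters and aggregation parameters of one scoring
#' component, plus how many instances it contributes to the registry.
#'
#' @slot id Component identifier (e.g. `"S_DP"`).
#' @slot label Human-readable description.
#' @slot iv,ip,cs,sq Curve parameters of [componentScore()].
#' @slot ca Constant summand added before the geometric mean.
#' @slot w Weight (geometric-mean exponent).
#' @slot nApplied Number of instances this component contributes.
#' @aliases ComponentSpec
#' @export
setClass("ComponentSpec",
  representation(id = "character", label = "character",
                 iv = "numeric", ip = "numeric", cs = "numeric",
                 sq = "numeric", ca = "numeric", w = "numeric",
                 nApplied = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    ok <- tryCatch({
      checkScoringParams(object@iv, object@ip, object@cs, object@sq,
                         object@ca, object@w)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(ok)) msg <- c(msg, ok)
    if (object@nApplied < 0L)
      msg <- c(msg, "'nApplied' must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' @param id,label,iv,ip,cs,sq,ca,w,nApplied See slots.
#' @return `ComponentSpec()` returns a validated object.
#' @rdname ComponentSpec-class
#' @export
ComponentSpec <- function(id, label = id, iv, ip, cs, sq = 1, ca = 0, w = 1,
                          nApplied = 1L) {
  new("ComponentSpec", id = id, label = label,
      iv = as.numeric(iv), ip = as.numeric(ip), cs = as.numeric(cs),
      sq = as.numeric(sq), ca = as.numeric(ca), w = as.numeric(w),
      nApplied = as.integer(nApplied))
}

#' @param object,x A `ComponentSpec`.
#' @rdname ComponentSpec-class
#' @export
setGeneric("componentId", function(x) standardGeneric("componentId"))

#' @rdname ComponentSpec-class
#' @export
setMethod("componentId", "ComponentSpec", function(x) x@id)

setMethod("show", "ComponentSpec", function(object) {
  cat(sprintf(
    "ComponentSpec %s (%s)\n  IV=%g IP=%g CS=%g Sq=%g CA=%g W=%g, applied %d time(s)\n",
    object@id, object@label, object@iv, object@ip, object@cs,
    object@sq, object@ca, object@w, object@nApplied))
})

#' RGDataset: one condition's expression data
#'
#' A [SummarizedExperiment::SummarizedExperiment] with `counts` and `cpm`
#' assays (CPM = TMM-scaled counts per million), sample metadata
#' (`sample_id`, `patient_id`, `tissue`, `norm_factor` in `colData`), the
#' tumor-normal sample pairs and the per-patient clinical table.
#'
#' @slot pairs `DataFrame` with columns `tumor`, `normal` (sample ids) and
#'   `patient_id`; each row pairs one tumor and one normal sample of the
#'   same patient.
#' @slot clinical `DataFrame` keyed by `patient_id` with the six clinical
#'   characteristics.
#' @aliases RGDataset
#' @export
setClass("RGDataset",
  contains = "SummarizedExperiment",
  representation(pairs = "DataFrame", clinical = "DataFrame"),
  validity = function(object) {
    msg <- character(0)
    cd <- colData(object)
    need <- c("sample_id", "patient_id", "tissue")
    if (!all(need %in% names(cd)))
      msg <- c(msg, paste("colData must contain", paste(need, collapse = ", ")))
    else {
      if (!all(cd$tissue %in% c("tumor", "normal")))
        msg <- c(msg, "tissue must be 'tumor' or 'normal'")
      p <- object@pairs
      if (nrow(p)) {
        if (!all(c("tumor", "normal") %in% names(p)))
          msg <- c(msg, "pairs must have 'tumor' and 'normal' columns")
        else {
          idx <- match(c(p$tumor, p$normal), cd$sample_id)
          if (anyNA(idx))
            msg <- c(msg, "pairs reference unknown sample ids")
          else {
            it <- match(p$tumor, cd$sample_id)
            im <- match(p$normal, cd$sample_id)
            if (!all(cd$tissue[it] == "tumor" & cd$tissue[im] == "normal"))
              msg <- c(msg, "each pair must join one tumor and one normal sample")
            if (!all(cd$patient_id[it] == cd$patient_id[im]))
              msg <- c(msg, "paired samples must share a patient id")
          }
        }
      }
    }
    if (!all(c("counts", "cpm") %in% names(assays(object))))
      msg <- c(msg, "assays must contain 'counts' and 'cpm'")
    if (length(msg)) msg else TRUE
  })

#' Construct an RGDataset
#'
#' Runs TMM normalisation on the raw counts, computes the CPM matrix, and
#' derives tumor-normal pairs from shared patient ids when `pairs` is not
#' given.
#'
#' @param counts Non-negative integer gene x sample matrix with row and
#'   column names.
#' @param samples data.frame with columns `sample_id`, `patient_id`,
#'   `tissue` (`"tumor"`/`"normal"`), one row per column of `counts`.
#' @param clinical data.frame keyed by `patient_id` with the clinical
#'   characteristics (may be missing columns; they correlate as missing).
#' @param pairs Optional data.frame with columns `tumor`, `normal`; when
#'   `NULL`, every patient with exactly one tumor and one normal sample
#'   contributes a pair.
#' @param config Scoring configuration (TMM trim constants).
#' @return An [RGDataset-class].
#' @export
RGDataset <- function(counts, samples, clinical = NULL, pairs = NULL,
                      config = defaultScoringConfig()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have gene row names and sample column names")
  if (any(counts < 0)) stop("'counts' must be non-negative")
  samples <- as.data.frame(samples)
  if (!all(colnames(counts) == samples$sample_id))
    samples <- samples[match(colnames(counts), samples$sample_id), ]
  if (anyNA(samples$sample_id))
    stop("every counts column needs a sample sheet row")
  tmm <- tmmNormalize(counts,
                      logratioTrim = config$tmm$logratio_trim %||% 0.3,
                      sumTrim = config$tmm$sum_trim %||% 0.05,
                      doWeighting = config$tmm$weighting %||% TRUE)
  if (is.null(pairs)) {
    pat <- split(seq_len(nrow(samples)), samples$patient_id)
    pairs <- do.call(rbind, lapply(pat, function(i) {
      tu <- samples$sample_id[i][samples$tissue[i] == "tumor"]
      no <- samples$sample_id[i][samples$tissue[i] == "normal"]
      if (length(tu) == 1L && length(no) == 1L)
        data.frame(tumor = tu, normal = no,
                   patient_id = samples$patient_id[i][1])
    }))
    if (is.null(pairs))
      pairs <- data.frame(tumor = character(0), normal = character(0),
                          patient_id = character(0))
  }
  if (is.null(clinical))
    clinical <- data.frame(patient_id = unique(samples$patient_id))
  cd <- DataFrame(samples, norm_factor = tmm$factors, row.names = samples$sample_id)
  se <- SummarizedExperiment(
    assays = list(counts = counts, cpm = tmm$cpm), colData = cd)
  new("RGDataset", se, pairs = DataFrame(as.data.frame(pairs)),
      clinical = DataFrame(as.data.frame(clinical)))
}

#' @param x,object An `RGDataset`.
#' @return `cpmValues()` the CPM assay; `tumorSamples()`/`normalSamples()`
#'   sample ids; `samplePairs()` the pair table; `clinicalTable()` the
#'   clinical table.
#' @rdname RGDataset-class
#' @export
setGeneric("cpmValues", function(x) standardGeneric("cpmValues"))
#' @rdname RGDataset-class
#' @export
setMethod("cpmValues", "RGDataset", function(x) assay(x, "cpm"))

#' @rdname RGDataset-class
#' @export
setGeneric("tumorSamples", function(x) standardGeneric("tumorSamples"))
#' @rdname RGDataset-class
#' @export
setMethod("tumorSamples", "RGDataset",
          function(x) colData(x)$sample_id[colData(x)$tissue == "tumor"])

#' @rdname RGDataset-class
#' @export
setGeneric("normalSamples", function(x) standardGeneric("normalSamples"))
#' @rdname RGDataset-class
#' @export
setMethod("normalSamples", "RGDataset",
          function(x) colData(x)$sample_id[colData(x)$tissue == "normal"])

#' @rdname RGDataset-class
#' @export
setGeneric("samplePairs", function(x) standardGeneric("samplePairs"))
#' @rdname RGDataset-class
#' @export
setMethod("samplePairs", "RGDataset", function(x) as.data.frame(x@pairs))

#' @rdname RGDataset-class
#' @export
setGeneric("clinicalTable", function(x) standardGeneric("clinicalTable"))
#' @rdname RGDataset-class
#' @export
setMethod("clinicalTable", "RGDataset", function(x) as.data.frame(x@clinical))

setMethod("show", "RGDataset", function(object) {
  cat(sprintf(
    "RGDataset: %d genes, %d tumor / %d normal samples, %d T-N pairs\n",
    nrow(object), length(tumorSamples(object)),
    length(normalSamples(object)), nrow(object@pairs)))
  callNextMethod()
})

#' RGScores: per-gene scorecards for one condition
#'
#' Container for a condition's scoring run: one row per gene with the
#' expression score, anti-scorings and final score; the full per-instance
#' component breakdown and scored x-values; the advisory GO/PubMed
#' columns; the instance table the run used; and any flags raised.
#'
#' @slot condition Condition identifier.
#' @slot scores `DataFrame`: `gene`, `s_exp`, `s_mut`, `s_isoforms`,
#'   `s_pseudogenes`, `s_final`.
#' @slot breakdown Matrix genes x instances of component scores.
#' @slot xvalues Matrix genes x instances of the scored variables.
#' @slot advisory `DataFrame` of advisory columns (GO penalty, publication
#'   counts); zero columns when annotations were not supplied.
#' @slot instances Instance table from [expandRegistry()].
#' @slot flags Character vector of warnings/fallbacks recorded during the
#'   run.
#' @aliases RGScores
#' @export
setClass("RGScores",
  representation(condition = "character", scores = "DataFrame",
                 breakdown = "matrix", xvalues = "matrix",
                 advisory = "DataFrame", instances = "data.frame",
                 flags = "character"),
  validity = function(object) {
    msg <- character(0)
    if (nrow(object@scores) != nrow(object@breakdown))
      msg <- c(msg, "scores and breakdown disagree on gene count")
    s <- object@scores
    for (col in intersect(c("s_exp", "s_final"), names(s)))
      if (any(s[[col]] < 0 | s[[col]] > 100, na.rm = TRUE))
        msg <- c(msg, paste(col, "outside [0, 100]"))
    if (length(msg)) msg else TRUE
  })

#' @param x,object An `RGScores`.
#' @return `scoreTable()` the per-gene score data.frame;
#'   `scoreBreakdown()` the genes x instances score matrix; `topGenes()`
#'   the `k` highest-ranked genes.
#' @rdname RGScores-class
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))
#' @rdname RGScores-class
#' @export
setMethod("scoreTable", "RGScores", function(x) as.data.frame(x@scores))

#' @rdname RGScores-class
#' @export
setGeneric("scoreBreakdown", function(x) standardGeneric("scoreBreakdown"))
#' @rdname RGScores-class
#' @export
setMethod("scoreBreakdown", "RGScores", function(x) x@breakdown)

#' @param k Number of genes to report.
#' @param by Ranking column, `"s_final"` (default) or `"s_exp"`.
#' @rdname RGScores-class
#' @export
setGeneric("topGenes", function(x, k = 5, by = "s_final")
  standardGeneric("topGenes"))
#' @rdname RGScores-class
#' @export
setMethod("topGenes", "RGScores", function(x, k = 5, by = "s_final") {
  s <- scoreTable(x)
  if (!by %in% names(s)) stop("unknown ranking column: ", by)
  s <- s[order(-s[[by]], s$gene), , drop = FALSE]
  utils::head(s, k)
})

setMethod("show", "RGScores", function(object) {
  cat(sprintf("RGScores for condition '%s': %d genes, %d component instances\n",
              object@condition, nrow(object@scores), nrow(object@instances)))
  if (length(object@flags))
    cat(sprintf("  %d flag(s) raised; see flags()\n", length(object@flags)))
  top <- topGenes(object, 5)
  cat("  top genes by s_final:",
      paste(sprintf("%s (%.1f)", top$gene, top$s_final), collapse = ", "),
      "\n")
})

#' @rdname RGScores-class
#' @export
setGeneric("flags", function(x) standardGeneric("flags"))
#' @rdname RGScores-class
#' @export
setMethod("flags", "RGScores", function(x) x@flags)

#' @rdname RGScores-class
#' @export
setGeneric("advisoryTable", function(x) standardGeneric("advisoryTable"))
#' @rdname RGScores-class
#' @export
setMethod("advisoryTable", "RGScores", function(x) as.data.frame(x@advisory))
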