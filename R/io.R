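# Readers for the TSV input dialects. Each reader validates the column
# contract and reports the offending file (and line where determinable).

.readTsv <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed ", what, " TSV '", path, "': ",
                             conditionMessage(e)))
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " TSV '", path, "' lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read pipeline input tables
#'
#' `readCountsTSV()` reads a gene x sample count matrix (first column
#' `gene`, remaining columns one per sample); `readSampleSheet()` the
#' sample sheet (`sample_id`, `patient_id`, `tissue`);
#' `readClinicalTSV()` the per-patient clinical table (missing values as
#' empty fields); `readGeneAnnotation()` the annotation table (`gene`,
#' `aliases` semicolon-joined, `n_isoforms`, `n_pseudogenes`,
#' `mutation_count`); `readGoTerms()` either a simple TSV (`gene`,
#' `go_terms` semicolon-joined) or a GAF 2.x file with an accompanying
#' term-name TSV (`go_id`, `name`); `readCorpus()` the local abstract
#' corpus (`id`, `title`, `abstract`).
#'
#' @param path File path.
#' @return A data.frame (`readCountsTSV()`: a numeric matrix with gene
#'   row names).
#' @export
readCountsTSV <- function(path) {
  df <- .readTsv(path, "gene", "counts")
  if (ncol(df) < 2L) stop("counts TSV '", path, "' has no sample columns")
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(as.numeric(m))))
  if (length(bad)) {
    line <- (bad[1] - 1) %% nrow(df) + 2L  # +1 header, +1 1-based
    stop("counts TSV '", path, "': non-numeric count near line ", line)
  }
  storage.mode(m) <- "numeric"
  rownames(m) <- df$gene
  if (anyDuplicated(df$gene))
    stop("counts TSV '", path, "': duplicated gene ids")
  m
}

#' @rdname readCountsTSV
#' @export
readSampleSheet <- function(path)
  .readTsv(path, c("sample_id", "patient_id", "tissue"), "sample sheet")

#' @rdname readCountsTSV
#' @export
readClinicalTSV <- function(path) {
  df <- .readTsv(path, "patient_id", "clinical")
  for (col in setdiff(names(df), "patient_id"))
    df[[col]][df[[col]] %in% ""] <- NA
  df
}

#' @rdname readCountsTSV
#' @export
readGeneAnnotation <- function(path)
  .readTsv(path, c("gene", "n_isoforms", "n_pseudogenes"), "annotation")

#' @param termNames For GAF input: path to a TSV mapping `go_id` to
#'   `name`.
#' @rdname readCountsTSV
#' @export
readGoTerms <- function(path, termNames = NULL) {
  firstLine <- readLines(path, n = 1L)
  if (startsWith(firstLine, "!gaf-version") || !is.null(termNames)) {
    if (is.null(termNames))
      stop("GAF input needs a 'termNames' TSV (go_id, name) to resolve ",
           "term names")
    gaf <- utils::read.delim(path, header = FALSE, comment.char = "!",
                             stringsAsFactors = FALSE)
    if (ncol(gaf) < 5L) stop("malformed GAF file: ", path)
    tn <- .readTsv(termNames, c("go_id", "name"), "GO term-name")
    nm <- tn$name[match(gaf[[5]], tn$go_id)]
    keep <- !is.na(nm)
    agg <- tapply(nm[keep], gaf[[3]][keep],
                  function(x) paste(unique(x), collapse = ";"))
    return(data.frame(gene = names(agg), go_terms = as.character(agg),
                      stringsAsFactors = FALSE))
  }
  .readTsv(path, c("gene", "go_terms"), "GO terms")
}

#' @rdname readCountsTSV
#' @export
readCorpus <- function(path)
  .readTsv(path, c("id", "title", "abstract"), "corpus")

#' Write per-gene scorecards
#'
#' One row per gene: the composite scores followed by one column per
#' component instance (the full breakdown), as tab-separated text.
#'
#' @param x An [RGScores-class].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
writeScores <- function(x, path) {
  df <- cbind(scoreTable(x),
              as.data.frame(scoreBreakdown(x), check.names = FALSE))
  adv <- advisoryTable(x)
  if (ncol(adv)) df <- cbind(df, adv)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
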