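#' GO keyword penalty
#'
#' Advisory penalty for involvement in cancer-associated processes, based
#' on the gene's directly assigned GO term names. Six keyword categories
#' are checked by case-insensitive substring match against the term
#' names: cell cycle (5 points), differentiation (4), stress response
#' (3), immune response/inflammation (2), angiogenesis (2), and
#' intercellular interactions (2); a category contributes its points if
#' at least one of its keywords occurs, so the maximum raw penalty is
#' 5 + 4 + 3 + 2 + 2 + 2 = 18. A gene with fewer than `minTerms` (default
#' 3) GO terms is considered insufficiently annotated and receives a flat
#' penalty of 10, undivided. Otherwise the normalized penalty is the raw
#' points divided by the number of GO terms to the power 0.3, balancing
#' annotation depth against study bias.
#'
#' The penalty is advisory: it is reported alongside the scores for
#' manual exclusion of cancer-associated candidates, never multiplied
#' into the final score.
#'
#' @param goTerms Character vector of GO term names (possibly empty).
#' @param config Scoring configuration (category keywords and points).
#' @return List with `raw_points`, `category_hits` (named logical),
#'   `n_terms`, `normalized_penalty`, `insufficient`.
#' @examples
#' goPenalty(c("mitotic cell cycle", "stem cell division", "DNA repair",
#'             "immune response", "angiogenesis", "cell adhesion"))$raw_points
#' @export
goPenalty <- function(goTerms, config = defaultScoringConfig()) {
  gp <- config$go_penalty
  minTerms <- gp$min_terms %||% 3
  insufficientPenalty <- gp$insufficient_penalty %||% 10
  normExponent <- gp$norm_exponent %||% 0.3
  goTerms <- as.character(goTerms)
  goTerms <- goTerms[nzchar(goTerms)]
  nTerms <- length(goTerms)
  hay <- tolower(goTerms)
  hits <- vapply(gp$categories, function(cat)
    any(vapply(tolower(cat$keywords), function(kw)
      any(grepl(kw, hay, fixed = TRUE)), logical(1))), logical(1))
  points <- vapply(gp$categories, function(cat) cat$points, numeric(1))
  if (nTerms < minTerms) {
    return(list(raw_points = insufficientPenalty, category_hits = hits,
                n_terms = nTerms, normalized_penalty = insufficientPenalty,
                insufficient = TRUE))
  }
  raw <- sum(points[hits])
  list(raw_points = raw, category_hits = hits, n_terms = nTerms,
       normalized_penalty = raw / nTerms^normExponent,
       insufficient = FALSE)
}

#' Publication counts over a local abstract corpus
#'
#' Counts how many corpus records mention the gene (by symbol or alias,
#' word-boundary match over title plus abstract) and how many of those
#' have a cancer-related title. A title is cancer-related if it contains
#' any configured cancer keyword as a whole word; a keyword with a
#' leading `*` matches any word with that ending (so `*carcinoma` hits
#' "adenocarcinoma"). Matching is case-insensitive. No network access:
#' the corpus is a local table of records.
#'
#' @param corpus data.frame with columns `id`, `title`, `abstract`.
#' @param aliases Character vector of gene names (primary symbol plus
#'   aliases).
#' @param config Scoring configuration (cancer keyword lists; the
#'   extended list is included by default).
#' @param includeExtended Include the configured extension keywords
#'   (default `TRUE`).
#' @return List with `total_mentions`, `cancer_mentions`.
#' @export
publicationCounts <- function(corpus, aliases,
                              config = defaultScoringConfig(),
                              includeExtended = TRUE) {
  stopifnot(all(c("id", "title", "abstract") %in% names(corpus)))
  aliases <- unique(aliases[nzchar(aliases)])
  if (length(aliases) == 0L) stop("at least one gene name is required")
  if (nrow(corpus) == 0L) {
    warning("empty corpus: publication counts are zero", call. = FALSE)
    return(list(total_mentions = 0L, cancer_mentions = 0L))
  }
  text <- paste(corpus$title, corpus$abstract)
  aliasRe <- paste0("\\b(", paste(vapply(aliases, .escapeRe, character(1)),
                                  collapse = "|"), ")\\b")
  mentioned <- grepl(aliasRe, text, ignore.case = TRUE, perl = TRUE)
  kws <- config$pubmed$cancer_keywords
  if (includeExtended)
    kws <- c(kws, config$pubmed$cancer_keywords_extended)
  kwRe <- paste(vapply(kws, .cancerKeywordRe, character(1)), collapse = "|")
  cancerTitle <- grepl(kwRe, corpus$title, ignore.case = TRUE, perl = TRUE)
  list(total_mentions = sum(mentioned),
       cancer_mentions = sum(mentioned & cancerTitle))
}

.escapeRe <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

.cancerKeywordRe <- function(kw) {
  if (startsWith(kw, "*"))
    paste0("\\b\\w*", .escapeRe(substring(kw, 2)), "\\b")
  else
    paste0("\\b", .escapeRe(kw), "\\b")
}

#' Mutation-rate percentile
#'
#' Midrank percentile of each gene's somatic-mutation count within the
#' distribution over all genes of a condition: 100 x (number of genes
#' with strictly lower count + half the ties) / total. A heavily mutated
#' gene sits near 100 and is penalised by the mutation anti-scoring; the
#' percentiles of all genes average exactly 50.
#'
#' @param counts Named numeric vector of per-gene mutation counts
#'   (>= 2 genes).
#' @return Named numeric vector of percentiles in `[0, 100]`.
#' @examples
#' mutationPercentile(c(a = 0, b = 5, c = 5, d = 100))
#' @export
mutationPercentile <- function(counts) {
  if (length(counts) < 2L)
    stop("mutation percentiles need counts for at least 2 genes")
  if (any(counts < 0, na.rm = TRUE)) stop("mutation counts must be >= 0")
  100 * (rank(counts, ties.method = "average") - 0.5) / length(counts)
}
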