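#' Load the scoring configuration
#'
#' Reads a hierarchical YAML configuration describing every scoring
#' component's curve parameters (`iv`, `ip`, `cs`, `sq`), aggregation
#' constants (`ca`, `w`), the clinical characteristics and expression
#' measures driving the correlation components, feature-extraction
#' constants (trim bounds, pseudocount, CPM floor, TMM trims), GO penalty
#' categories and cancer-title keywords. `defaultScoringConfig()` returns
#' the configuration shipped with the package.
#'
#' @param path Path to a YAML file; `NULL` loads the packaged defaults.
#' @return A nested list; see the shipped
#'   `system.file("extdata", "scoring_config.yaml", package = "RGscore")`.
#' @export
loadScoringConfig <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "scoring_config.yaml", package = "RGscore")
  if (!nzchar(path) || !file.exists(path))
    stop("scoring configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  required <- c("components", "anti", "clinical_characteristics",
                "expression_measures")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("scoring configuration lacks section(s): ",
         paste(missing, collapse = ", "))
  cfg
}

.configCache <- new.env(parent = emptyenv())

#' @rdname loadScoringConfig
#' @export
defaultScoringConfig <- function() {
  if (is.null(.configCache$default))
    .configCache$default <- loadScoringConfig()
  .configCache$default
}

#' Build the component registry
#'
#' Expands the configured components into the full set of scoring
#' instances. The default configuration yields 48 expression instances:
#' the five fold-change components applied once each, the three
#' within-pool stability components applied to the normal and the tumor
#' pool, the average-expression component once, and the two clinical
#' correlation components applied 3 x 6 = 18 times each (three expression
#' measures crossed with six clinical characteristics).
#'
#' @param config Scoring configuration, see [defaultScoringConfig()].
#' @param strict If `TRUE` (default) a clinical-characteristics list whose
#'   length is not six is a configuration error; if `FALSE` any number
#'   (including zero) is accepted and the registry shrinks or grows
#'   accordingly.
#' @return A list of [ComponentSpec-class] objects, one per component.
#' @export
buildRegistry <- function(config = defaultScoringConfig(), strict = TRUE) {
  clin <- config$clinical_characteristics
  meas <- config$expression_measures
  if (strict && length(clin) != 6L)
    stop("configuration error: expected 6 clinical characteristics, got ",
         length(clin), " (use strict = FALSE to allow)")
  nCorr <- as.integer(length(clin) * length(meas))
  napp <- c(S_DP = 1L, S_DL = 1L, S_DoO = 1L, S_DoU = 1L, S_DLc = 1L,
            S_EStD = 2L, S_EoH = 2L, S_EoL = 2L, S_EA = 1L,
            S_Cp = nCorr, S_Cr = nCorr)
  ids <- names(config$components)
  unknown <- setdiff(ids, names(napp))
  if (length(unknown))
    stop("unknown component id(s) in configuration: ",
         paste(unknown, collapse = ", "))
  lapply(ids, function(id) {
    p <- config$components[[id]]
    ComponentSpec(id = id, label = p$label %||% id,
                  iv = p$iv, ip = p$ip, cs = p$cs, sq = p$sq,
                  ca = p$ca, w = p$w, nApplied = napp[[id]])
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Expand a registry into its instance table
#'
#' Each component contributes `nApplied` scored instances; this returns a
#' data.frame with one row per instance carrying the curve parameters and
#' an instance label identifying which application it is (which pool,
#' which expression measure x clinical characteristic).
#'
#' @param registry A list of [ComponentSpec-class], from [buildRegistry()].
#' @param config Scoring configuration (supplies the measure and
#'   characteristic names for correlation instance labels).
#' @return data.frame with columns `instance`, `id`, `iv`, `ip`, `cs`,
#'   `sq`, `ca`, `w`.
#' @examples
#' nrow(expandRegistry(buildRegistry()))  # 48
#' @export
expandRegistry <- function(registry = buildRegistry(),
                           config = defaultScoringConfig()) {
  clin <- config$clinical_characteristics
  meas <- config$expression_measures
  rows <- lapply(registry, function(sp) {
    labels <- switch(
      componentId(sp),
      S_DP  = "S_DP.all",
      S_DL  = "S_DL.paired",
      S_DoO = "S_DoO.paired",
      S_DoU = "S_DoU.paired",
      S_DLc = "S_DLc.paired",
      S_EStD = c("S_EStD.normal", "S_EStD.tumor"),
      S_EoH  = c("S_EoH.normal", "S_EoH.tumor"),
      S_EoL  = c("S_EoL.normal", "S_EoL.tumor"),
      S_EA   = "S_EA.tumor",
      S_Cp   = corrInstanceLabels("S_Cp", meas, clin),
      S_Cr   = corrInstanceLabels("S_Cr", meas, clin)
    )
    stopifnot(length(labels) == sp@nApplied)
    if (length(labels) == 0L) return(NULL)
    data.frame(instance = labels, id = componentId(sp),
               iv = sp@iv, ip = sp@ip, cs = sp@cs, sq = sp@sq,
               ca = sp@ca, w = sp@w)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

corrInstanceLabels <- function(id, measures, characteristics) {
  if (length(measures) == 0L || length(characteristics) == 0L)
    return(character(0))
  as.vector(t(outer(measures, characteristics,
                    function(m, c) paste(id, m, c, sep = "."))))
}
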