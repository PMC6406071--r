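#' Percentile-trimmed statistics
#'
#' Mean or standard deviation over the values whose fractional rank
#' `(i - 0.5) / n` (for the `i`-th order statistic of `n` values) lies in
#' `[lo/100, hi/100)`. This single boundary convention defines every
#' percentile subscript used by the scoring system: the 10-90 trimmed
#' mean, and the 0-10 / 90-100 decile means used for outlier statistics
#' (for `n = 10` the top decile is exactly the largest value). Ties are
#' broken by the stable sort order, so results are deterministic.
#'
#' If no value falls inside the band (possible for narrow bands on very
#' small vectors), the mean falls back to the single order statistic
#' nearest the band midpoint; the standard deviation errors, since a
#' spread cannot be estimated from fewer than two values.
#'
#' @param values Non-empty numeric vector.
#' @param lo,hi Percentile bounds, `0 <= lo < hi <= 100`.
#' @param stat `"mean"` or `"sd"`.
#' @return The trimmed statistic.
#' @examples
#' trimmedStat(1:10, 10, 90, "mean")  # mean of 2..9 = 5.5
#' trimmedStat(1:10, 90, 100, "mean") # 10: top decile = largest value
#' @export
trimmedStat <- function(values, lo = 10, hi = 90, stat = c("mean", "sd")) {
  stat <- match.arg(stat)
  n <- length(values)
  if (n == 0L) stop("'values' must be non-empty")
  if (anyNA(values)) stop("'values' must not contain NA")
  if (!(lo >= 0 && hi <= 100 && lo < hi))
    stop("need 0 <= lo < hi <= 100")
  v <- sort(values)
  keep <- .trimKeep(n, lo, hi)
  if (!any(keep)) {
    if (stat == "sd")
      stop("fewer than 2 values survive the ", lo, "-", hi, " trim")
    mid <- (lo + hi) / 200
    return(v[which.min(abs((seq_len(n) - 0.5) / n - mid))])
  }
  k <- v[keep]
  if (stat == "sd") {
    if (length(k) < 2L)
      stop("fewer than 2 values survive the ", lo, "-", hi, " trim")
    return(stats::sd(k))
  }
  mean(k)
}

.trimKeep <- function(n, lo, hi) {
  fr <- (seq_len(n) - 0.5) / n
  fr >= lo / 100 & fr < hi / 100
}

# indices (into the original vector) of the values kept by the trim band
.trimIndices <- function(values, lo, hi) {
  ord <- order(values)
  ord[.trimKeep(length(values), lo, hi)]
}

#' Pooled log2 fold change
#'
#' log2 ratio of the percentile-trimmed mean CPM of the tumor pool over
#' that of the normal pool, with a pseudocount added to both terms to
#' guard against zeros.
#'
#' @param cpm Gene x sample CPM matrix (or a single gene's vector pair via
#'   `tumorCols`/`normalCols` indexing).
#' @param tumorCols,normalCols Column ids/indices of the two pools.
#' @param lo,hi Trim bounds (default 10-90).
#' @param eps Pseudocount in CPM units (default 0.25).
#' @return Named numeric vector of per-gene pooled log2 fold changes.
#' @export
pooledLog2FC <- function(cpm, tumorCols, normalCols, lo = 10, hi = 90,
                         eps = 0.25) {
  cpm <- rbind(cpm)
  if (length(tumorCols) == 0L || length(normalCols) == 0L)
    stop("both pools must be non-empty")
  tm <- apply(cpm[, tumorCols, drop = FALSE], 1, trimmedStat, lo, hi, "mean")
  nm <- apply(cpm[, normalCols, drop = FALSE], 1, trimmedStat, lo, hi, "mean")
  if (eps == 0 && any(tm == 0 | nm == 0))
    stop("a pool has zero trimmed-mean CPM; use a positive pseudocount 'eps'")
  log2((tm + eps) / (nm + eps))
}

#' Paired log2 fold changes
#'
#' One log2 tumor:normal CPM ratio per patient pair, pseudocount applied
#' to both terms.
#'
#' @param cpm Gene x sample CPM matrix.
#' @param pairs data.frame with columns `tumor`, `normal` (sample ids
#'   matching `colnames(cpm)`).
#' @param eps Pseudocount in CPM units.
#' @return Gene x pair matrix of log2 fold changes.
#' @export
pairedLog2FC <- function(cpm, pairs, eps = 0.25) {
  if (nrow(pairs) < 1L) stop("at least one tumor-normal pair is required")
  bad <- !(pairs$tumor %in% colnames(cpm)) | !(pairs$normal %in% colnames(cpm))
  if (any(bad))
    stop("pair(s) reference missing sample(s): ",
         paste(sprintf("(%s, %s)", pairs$tumor[bad], pairs$normal[bad]),
               collapse = ", "))
  out <- log2((cpm[, pairs$tumor, drop = FALSE] + eps) /
              (cpm[, pairs$normal, drop = FALSE] + eps))
  colnames(out) <- if (!is.null(pairs$patient_id)) pairs$patient_id
                   else paste(pairs$tumor, pairs$normal, sep = ":")
  out
}

#' Within-pool stability features
#'
#' For one gene's CPM values in one pool: the relative standard deviation
#' of the 10-90 trimmed distribution (`relsd`), the log2 ratio of the top
#' decile mean over the trimmed mean (`outlier_hi`), the log2 ratio of the
#' trimmed mean over the bottom decile mean (`outlier_lo`), and the
#' reciprocal log2 trimmed-mean CPM (`inv_log2_cpm`, the average
#' expression variable). A trimmed mean at or below 1 CPM makes
#' `inv_log2_cpm` meaningless; it is returned as `NA` with
#' `low_expression = TRUE`, which downstream scoring maps to a hard zero
#' on the average-expression component.
#'
#' @param pool Numeric vector of one gene's CPM values in one pool.
#' @param lo,hi Trim bounds.
#' @param eps Pseudocount inside the outlier log2 ratios.
#' @param cpmFloor Trimmed-mean CPM below which the gene is flagged as
#'   low-expressed.
#' @return List with `relsd`, `outlier_hi`, `outlier_lo`, `inv_log2_cpm`,
#'   `trimmed_mean`, `low_expression`.
#' @examples
#' poolStability(rep(256, 12))  # relsd 0, outliers 0, inv_log2_cpm 1/8
#' @export
poolStability <- function(pool, lo = 10, hi = 90, eps = 0.25, cpmFloor = 2) {
  if (length(pool) < 10L)
    warning("pool has fewer than 10 samples; decile statistics are coarse",
            call. = FALSE)
  m <- trimmedStat(pool, lo, hi, "mean")
  s <- if (sum(.trimKeep(length(pool), lo, hi)) >= 2L)
    trimmedStat(pool, lo, hi, "sd") else 0
  relsd <- if (m > 0) s / m else 0
  mHi <- trimmedStat(pool, hi, 100, "mean")
  mLo <- trimmedStat(pool, 0, lo, "mean")
  low <- m < cpmFloor || m <= 1
  list(relsd = relsd,
       outlier_hi = log2((mHi + eps) / (m + eps)),
       outlier_lo = log2((m + eps) / (mLo + eps)),
       inv_log2_cpm = if (low) NA_real_ else 1 / log2(m),
       trimmed_mean = m,
       low_expression = low)
}

#' Spearman correlation with t-approximation p-value
#'
#' Rank correlation with a two-sided p-value from the large-sample t
#' approximation. Degenerate inputs (fewer than 3 complete observations,
#' or a constant vector) return the maximally stable result `r = 0,
#' p = 1` with a flag, so the correlation components score 100 rather
#' than fail.
#'
#' @param x,y Numeric vectors of equal length; `NA`s dropped pairwise.
#' @return List with `r`, `p`, `n`, `flag`.
#' @export
spearmanTest <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L || length(unique(x)) < 2L || length(unique(y)) < 2L)
    return(list(r = 0, p = 1, n = n, flag = TRUE))
  r <- stats::cor(rank(x), rank(y))
  if (!is.finite(r)) return(list(r = 0, p = 1, n = n, flag = TRUE))
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p <- min(max(p, .Machine$double.xmin), 1)
  }
  list(r = r, p = p, n = n, flag = FALSE)
}

# Ordinal encodings of the six clinical characteristics ----------------

.encodeStage <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x <- sub("^STAGE\\s*", "", x)
  x <- sub("[ABC0-9]+$", "", x)  # strip sub-letters: IIA -> II
  unname(c(I = 1, II = 2, III = 3, IV = 4)[x])
}

.encodeTNM <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[is.na(x) | x %in% c("TX", "NX", "MX", "TIS", "X", "")] <- NA
  out <- rep(NA_real_, length(x))
  has <- !is.na(x) & grepl("[0-9]", x)
  out[has] <- as.numeric(regmatches(x[has], regexpr("[0-9]", x[has])))
  out
}

.encodeStatus <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[grepl("tumor[ -]?free", x)] <- 0
  out[grepl("with[ -]?tumor", x)] <- 1
  out
}

.encodeTreatment <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_real_, length(x))
  out[grepl("complete", x)] <- 0
  out[grepl("partial", x)] <- 1
  out[grepl("stable", x)] <- 2
  out[grepl("progress", x)] <- 3
  out
}

#' Encode clinical characteristics as ordinals
#'
#' Maps the six clinical characteristics to numeric ordinals for Spearman
#' correlation: pathologic stage I/II/III/IV to 1-4 (sub-letters
#' stripped); pathologic T/N/M to their numeric index (Tis/TX/NX/MX to
#' missing); person-neoplasm-cancer-status tumor free/with tumor to 0/1;
#' treatment success from complete remission (0) to progressive disease
#' (3). Columns already numeric pass through; absent columns yield
#' all-missing encodings.
#'
#' @param clinical data.frame keyed by `patient_id`.
#' @param characteristics Character vector of characteristic column names.
#' @return data.frame with `patient_id` and one numeric column per
#'   characteristic.
#' @export
encodeClinical <- function(clinical,
                           characteristics = defaultScoringConfig()$clinical_characteristics) {
  out <- data.frame(patient_id = as.character(clinical$patient_id))
  for (ch in characteristics) {
    v <- if (ch %in% names(clinical)) clinical[[ch]]
         else rep(NA, nrow(clinical))
    out[[ch]] <-
      if (is.numeric(v)) as.numeric(v)
      else switch(ch,
        pathologic_stage = .encodeStage(v),
        pathologic_t = , pathologic_n = , pathologic_m = .encodeTNM(v),
        neoplasm_cancer_status = .encodeStatus(v),
        treatment_success = .encodeTreatment(v),
        suppressWarnings(as.numeric(as.character(v))))
  }
  out
}

#' Clinical correlations for one gene
#'
#' Correlates each expression measure (per-patient tumor CPM, normal CPM,
#' paired log2 fold change), restricted to its 10-90th percentile samples,
#' with each encoded clinical characteristic. Degenerate cases (fewer than
#' 3 patients with data, single-level characteristic) return `r = 0,
#' p = 1` flagged, i.e. maximally stable.
#'
#' @param measures Named list of per-patient numeric vectors (names are
#'   patient ids), one per expression measure.
#' @param clinicalEncoded Output of [encodeClinical()].
#' @param lo,hi Percentile restriction applied to each measure before
#'   correlating.
#' @return data.frame with columns `measure`, `characteristic`, `r`, `p`,
#'   `n`, `flag` (one row per measure x characteristic).
#' @export
clinicalCorrelations <- function(measures, clinicalEncoded, lo = 10, hi = 90) {
  chars <- setdiff(names(clinicalEncoded), "patient_id")
  rows <- list()
  for (m in names(measures)) {
    v <- measures[[m]]
    if (length(v) == 0L || all(!is.finite(v))) {
      for (ch in chars)
        rows[[length(rows) + 1L]] <- data.frame(
          measure = m, characteristic = ch, r = 0, p = 1, n = 0L,
          flag = TRUE)
      next
    }
    keep <- .trimIndices(v, lo, hi)
    v <- v[keep]
    cl <- clinicalEncoded[match(names(v), clinicalEncoded$patient_id), ,
                          drop = FALSE]
    for (ch in chars) {
      st <- spearmanTest(v, cl[[ch]])
      rows[[length(rows) + 1L]] <- data.frame(
        measure = m, characteristic = ch, r = st$r, p = st$p, n = st$n,
        flag = st$flag)
    }
  }
  do.call(rbind, rows)
}

#' Extract all per-gene scoring features
#'
#' Turns an [RGDataset-class] into the per-gene feature set feeding the 48
#' component instances: the pooled trimmed log2 fold change, the four
#' paired fold-change summaries, the per-pool stability features, the
#' average-expression term, and the 18 clinical Spearman correlations.
#' Genes below the average-expression CPM floor are retained with the
#' low-expression sentinel (rather than dropped) so output rows are stable
#' across runs. Datasets without tumor-normal pairs fall back to the
#' pooled fold change for the paired components, and the paired
#' correlation measure is flagged neutral; the fallback is recorded in the
#' returned flags.
#'
#' @param dataset An [RGDataset-class].
#' @param config Scoring configuration.
#' @return List with `features` (data.frame, one row per gene), `corrR`
#'   and `corrP` (gene x measure.characteristic matrices), `flags`
#'   (character).
#' @export
extractFeatures <- function(dataset, config = defaultScoringConfig()) {
  stopifnot(is(dataset, "RGDataset"))
  cpm <- cpmValues(dataset)
  genes <- rownames(cpm)
  tu <- tumorSamples(dataset)
  no <- normalSamples(dataset)
  if (length(tu) == 0L || length(no) == 0L)
    stop("both tumor and normal pools are required")
  pairs <- samplePairs(dataset)
  lo <- config$trim$lo %||% 10
  hi <- config$trim$hi %||% 90
  eps <- config$pseudocount %||% 0.25
  cpmFloor <- config$cpm_floor %||% 2
  flags <- character(0)

  fcP <- pooledLog2FC(cpm, tu, no, lo, hi, eps)

  havePairs <- nrow(pairs) > 0L
  if (havePairs) {
    L <- pairedLog2FC(cpm, pairs, eps)
  } else {
    flags <- c(flags,
      "no tumor-normal pairs: paired fold-change components fall back to the pooled fold change; paired correlation measure neutralised")
    warning("dataset has no tumor-normal pairs; paired components use the ",
            "pooled fold change", call. = FALSE)
  }

  cd <- as.data.frame(colData(dataset))
  clinEnc <- encodeClinical(clinicalTable(dataset),
                            config$clinical_characteristics)
  patientMean <- function(row, cols) {
    v <- tapply(row[cols], cd$patient_id[match(cols, cd$sample_id)], mean)
    setNames(as.numeric(v), names(v))
  }

  nInst <- length(config$expression_measures) *
           length(config$clinical_characteristics)
  corrCols <- corrInstanceLabels("", config$expression_measures,
                                 config$clinical_characteristics)
  corrCols <- sub("^\\.", "", corrCols)
  corrR <- matrix(NA_real_, length(genes), nInst,
                  dimnames = list(genes, corrCols))
  corrP <- corrR

  feat <- data.frame(row.names = genes,
    log2fc_p = fcP,
    avg_log2fc_l_10_90 = NA_real_, avg_log2fc_l_90_100 = NA_real_,
    avg_log2fc_l_0_10 = NA_real_, avg_abs_log2fc_l_10_90 = NA_real_,
    relsd_normal = NA_real_, relsd_tumor = NA_real_,
    outlier_hi_normal = NA_real_, outlier_hi_tumor = NA_real_,
    outlier_lo_normal = NA_real_, outlier_lo_tumor = NA_real_,
    inv_log2_cpm = NA_real_, cpm_tumor_trimmed = NA_real_,
    low_expression = FALSE)

  nLow <- 0L
  for (g in genes) {
    if (havePairs) {
      lg <- L[g, ]
      feat[g, "avg_log2fc_l_10_90"]  <- trimmedStat(lg, lo, hi, "mean")
      feat[g, "avg_log2fc_l_90_100"] <- trimmedStat(lg, hi, 100, "mean")
      feat[g, "avg_log2fc_l_0_10"]   <- trimmedStat(lg, 0, lo, "mean")
      feat[g, "avg_abs_log2fc_l_10_90"] <- trimmedStat(abs(lg), lo, hi, "mean")
    } else {
      feat[g, c("avg_log2fc_l_10_90", "avg_log2fc_l_90_100",
                "avg_log2fc_l_0_10")] <- fcP[g]
      feat[g, "avg_abs_log2fc_l_10_90"] <- abs(fcP[g])
    }
    stN <- suppressWarnings(poolStability(cpm[g, no], lo, hi, eps, cpmFloor))
    stT <- suppressWarnings(poolStability(cpm[g, tu], lo, hi, eps, cpmFloor))
    feat[g, "relsd_normal"] <- stN$relsd
    feat[g, "relsd_tumor"] <- stT$relsd
    feat[g, "outlier_hi_normal"] <- stN$outlier_hi
    feat[g, "outlier_hi_tumor"] <- stT$outlier_hi
    feat[g, "outlier_lo_normal"] <- stN$outlier_lo
    feat[g, "outlier_lo_tumor"] <- stT$outlier_lo
    feat[g, "inv_log2_cpm"] <- stT$inv_log2_cpm
    feat[g, "cpm_tumor_trimmed"] <- stT$trimmed_mean
    feat[g, "low_expression"] <- stT$low_expression
    if (stT$low_expression) nLow <- nLow + 1L

    measures <- list(
      cpm_tumor  = patientMean(cpm[g, ], tu),
      cpm_normal = patientMean(cpm[g, ], no),
      log2fc_paired = if (havePairs) setNames(L[g, ], colnames(L))
                      else numeric(0))
    measures <- measures[config$expression_measures]
    cc <- clinicalCorrelations(measures, clinEnc, lo, hi)
    key <- paste(cc$measure, cc$characteristic, sep = ".")
    corrR[g, key] <- cc$r
    corrP[g, key] <- cc$p
  }
  if (nLow > 0L)
    flags <- c(flags, sprintf(
      "%d gene(s) below the %g CPM trimmed-mean floor: average-expression component set to the zero sentinel",
      nLow, cpmFloor))
  list(features = feat, corrR = corrR, corrP = corrP, flags = flags)
}
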