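#' TMM scaling factors and CPM normalisation
#'
#' Between-sample normalisation by the trimmed mean of M-values: for each
#' sample versus a reference column, gene-wise log2 expression ratios (M)
#' and average log2 abundances (A) are computed on library-size-scaled
#' counts, the most extreme 30% of M values and 5% of A values are
#' trimmed on each side, and the scaling factor is 2 to the
#' precision-weighted mean of the surviving M values (weights from the
#' delta-method binomial variance). Factors are rescaled to geometric
#' mean 1 across samples. The reference is the column whose 75th
#' percentile of scaled counts is closest to the mean across samples.
#'
#' `tmmNormalize()` additionally returns the CPM matrix: counts divided by
#' effective library size (library size times factor), per million.
#'
#' All-zero gene rows are excluded from factor estimation but retained
#' (as zeros) in the CPM matrix.
#'
#' @param counts Non-negative gene x sample matrix; every column must
#'   have a positive total.
#' @param logratioTrim Two-sided trim fraction on M values (default 0.3).
#' @param sumTrim Two-sided trim fraction on A values (default 0.05).
#' @param doWeighting Use inverse-variance precision weights (default).
#' @param refColumn Optional reference column index; default picks by
#'   upper-quartile proximity.
#' @return `tmmFactors()`: numeric vector of per-sample scaling factors
#'   with geometric mean 1. `tmmNormalize()`: list with `factors` and
#'   `cpm`.
#' @examples
#' m <- matrix(rpois(40, 50), 10, 4,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
#' tmmFactors(m)
#' @export
tmmFactors <- function(counts, logratioTrim = 0.3, sumTrim = 0.05,
                       doWeighting = TRUE, refColumn = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("'counts' must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive library size")
  y <- counts[rowSums(counts) > 0, , drop = FALSE]
  if (nrow(y) == 0L) stop("no expressed genes")
  if (is.null(refColumn)) {
    f75 <- vapply(seq_len(ncol(y)), function(j)
      stats::quantile(y[, j], 0.75, names = FALSE) / lib[j], numeric(1))
    refColumn <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(y)), function(j)
    .tmmPairFactor(y[, j], y[, refColumn], lib[j], lib[refColumn],
                   logratioTrim, sumTrim, doWeighting), numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

.tmmPairFactor <- function(obs, ref, nO, nR, logratioTrim, sumTrim,
                           doWeighting) {
  p0 <- obs / nO
  pR <- ref / nR
  keep <- p0 > 0 & pR > 0
  if (!any(keep)) return(1)
  p0 <- p0[keep]; pR <- pR[keep]
  o <- obs[keep]; r <- ref[keep]
  logR <- log2(p0 / pR)
  absE <- (log2(p0) + log2(pR)) / 2
  v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratioTrim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * sumTrim) + 1
  hiS <- n + 1 - loS
  rkM <- rank(logR)
  rkA <- rank(absE)
  keep2 <- rkM >= loL & rkM <= hiL & rkA >= loS & rkA <= hiS
  if (!any(keep2)) return(1)
  f <- if (doWeighting)
    sum(logR[keep2] / v[keep2], na.rm = TRUE) / sum(1 / v[keep2], na.rm = TRUE)
  else mean(logR[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' @rdname tmmFactors
#' @export
tmmNormalize <- function(counts, logratioTrim = 0.3, sumTrim = 0.05,
                         doWeighting = TRUE, refColumn = NULL) {
  counts <- as.matrix(counts)
  f <- tmmFactors(counts, logratioTrim, sumTrim, doWeighting, refColumn)
  lib <- colSums(counts)
  cpm <- sweep(counts, 2, lib * f, "/") * 1e6
  list(factors = f, cpm = cpm)
}
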