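# Small deterministic fixtures built in code.

# A tiny condition: nGenes x (nTumor + nNormal) counts with paired
# patients, gene g001 stable and highly expressed, g002 2-fold up in
# tumors, remaining genes Poisson noise around fixed means.
tinyDataset <- function(nGenes = 6, nTumor = 12, nNormal = 12, seed = 42,
                        libSizes = NULL) {
  set.seed(seed)
  pat <- sprintf("P%02d", seq_len(max(nTumor, nNormal)))
  samples <- data.frame(
    sample_id = c(paste0(pat[seq_len(nTumor)], "_T"),
                  paste0(pat[seq_len(nNormal)], "_N")),
    patient_id = c(pat[seq_len(nTumor)], pat[seq_len(nNormal)]),
    tissue = rep(c("tumor", "normal"), c(nTumor, nNormal)))
  base <- c(500, 300, seq(50, 400, length.out = nGenes - 2))
  if (is.null(libSizes)) libSizes <- round(runif(nrow(samples), 8e5, 1.2e6))
  counts <- sapply(seq_len(nrow(samples)), function(s) {
    mu <- base
    if (samples$tissue[s] == "tumor") mu[2] <- mu[2] * 2
    rpois(nGenes, mu * libSizes[s] / 1e6)
  })
  dimnames(counts) <- list(sprintf("g%03d", seq_len(nGenes)),
                           samples$sample_id)
  clin <- data.frame(
    patient_id = pat,
    pathologic_t = paste0("T", sample(1:4, length(pat), TRUE)),
    pathologic_n = paste0("N", sample(0:2, length(pat), TRUE)),
    pathologic_m = sample(c("M0", "M1"), length(pat), TRUE),
    pathologic_stage = paste("Stage", sample(c("I", "II", "III", "IV"),
                                             length(pat), TRUE)),
    neoplasm_cancer_status = sample(c("tumor free", "with tumor"),
                                    length(pat), TRUE),
    treatment_success = sample(c("complete remission/response",
                                 "progressive disease"), length(pat), TRUE))
  RGDataset(counts, samples, clin)
}

# Independent sort-and-slice reference for trimmed statistics: keep the
# i-th order statistic iff (i - 0.5)/n lies in [lo/100, hi/100).
oracleTrimmed <- function(values, lo, hi, stat = "mean") {
  v <- sort(values)
  n <- length(v)
  kept <- v[sapply(seq_len(n), function(i)
    (i - 0.5) / n >= lo / 100 && (i - 0.5) / n < hi / 100)]
  if (stat == "mean") {
    if (length(kept) == 0) {
      mid <- (lo + hi) / 200
      return(v[which.min(abs((seq_len(n) - 0.5) / n - mid))])
    }
    mean(kept)
  } else sd(kept)
}

# Direct evaluation of the weighted-geometric-mean aggregation, by the
# product-and-root route (the implementation uses log space).
oracleAggregate <- function(s, ca, w) {
  prod(pmin(s + ca, 100)^w)^(1 / sum(w))
}

# Brute-force best pair: enumerate every gene pair, apply the
# eligibility rules, rank by geometric mean then lexicographic ids.
oracleBestPair <- function(scores, cpm, samples, threshold, rcut) {
  genes <- sort(scores$gene)
  best <- NULL
  for (i in seq_along(genes)) for (j in seq_along(genes)) {
    if (i >= j) next
    a <- genes[i]; b <- genes[j]
    sa <- scores$s_exp[scores$gene == a]
    sb <- scores$s_exp[scores$gene == b]
    if (min(sa, sb) <= threshold) next
    r <- suppressWarnings(cor(rank(cpm[a, samples]), rank(cpm[b, samples])))
    if (!is.finite(r)) r <- 0
    if (abs(r) >= rcut) next
    gm <- sqrt(sa * sb)
    if (is.null(best) || gm > best$gm ||
        (gm == best$gm && (a < best$a || (a == best$a && b < best$b))))
      best <- list(a = a, b = b, gm = gm)
  }
  best
}
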