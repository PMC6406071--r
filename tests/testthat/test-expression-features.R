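test_that("trimmed statistics follow the rank-band convention", {
  expect_equal(trimmedStat(1:10, 10, 90, "mean"), 5.5)   # mean of 2..9
  expect_equal(trimmedStat(10:1, 10, 90, "mean"), 5.5)   # order-free
  expect_equal(trimmedStat(1:10, 90, 100, "mean"), 10)   # top decile
  expect_equal(trimmedStat(1:10, 0, 10, "mean"), 1)      # bottom decile
  expect_equal(trimmedStat(rep(7, 5), 10, 90, "mean"), 7)
  expect_equal(trimmedStat(rep(7, 5), 10, 90, "sd"), 0)
  x <- rnorm(37)
  expect_equal(trimmedStat(x, 0, 100, "mean"), mean(x))
  expect_equal(trimmedStat(x, 0, 100, "sd"), sd(x))
  expect_error(trimmedStat(1:3, 90, 100, "sd"), "fewer than 2")
  expect_error(trimmedStat(numeric(0), 10, 90), "non-empty")
  expect_error(trimmedStat(1:5, 90, 10), "lo < hi")
})

test_that("trimmed statistics match the sort-and-slice oracle", {
  set.seed(101)
  for (rep in 1:200) {
    n <- sample(5:1000, 1)
    v <- rnorm(n) * 10^sample(-2:3, 1)
    band <- rbind(c(10, 90), c(0, 10), c(90, 100),
                  sort(runif(2, 0, 100)))[sample(4, 1), ]
    if (band[1] == band[2]) next
    expect_equal(trimmedStat(v, band[1], band[2], "mean"),
                 oracleTrimmed(v, band[1], band[2], "mean"),
                 tolerance = 1e-12)
  }
})

test_that("a single huge outlier cannot move a 10-90 trimmed mean", {
  set.seed(55)
  for (rep in 1:20) {
    v <- rnorm(sample(10:100, 1))
    vOut <- c(v[-1], 1e9)
    vOut2 <- c(v[-1], 1e15)
    expect_equal(trimmedStat(vOut, 10, 90, "mean"),
                 trimmedStat(vOut2, 10, 90, "mean"), tolerance = 1e-12)
  }
})

test_that("TMM factors absorb pure library-size differences", {
  set.seed(7)
  a <- rpois(200, 100)
  m <- cbind(s1 = a, s2 = a)
  rownames(m) <- paste0("g", seq_len(nrow(m)))
  expect_equal(unname(tmmFactors(m)), c(1, 1), tolerance = 1e-12)
  m2 <- cbind(s1 = a, s2 = 2L * a)  # exact depth doubling
  rownames(m2) <- rownames(m)
  norm <- tmmNormalize(m2)
  expect_equal(unname(norm$factors), c(1, 1), tolerance = 1e-12)
  expect_equal(norm$cpm[, 1], norm$cpm[, 2], tolerance = 1e-12)
})

test_that("TMM factors always have geometric mean one", {
  set.seed(19)
  m <- matrix(rnbinom(500 * 6, mu = 60, size = 3), 500, 6,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:6)))
  f <- tmmFactors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("TMM matches the worked 5-gene example and the edgeR oracle", {
  # one strongly differential gene (g5) that trimming must discard
  cnt <- matrix(c(100, 200, 300, 400, 5000,
                  120, 210, 280, 410, 300), ncol = 2,
                dimnames = list(paste0("g", 1:5), c("A", "B")))
  f <- tmmFactors(cnt)
  # frozen from an independent execution of the trimmed-M procedure
  expect_equal(unname(f), c(0.4689818396, 2.1322787273), tolerance = 1e-8)
  # live cross-check against the reference implementation
  dge <- edgeR::calcNormFactors(edgeR::DGEList(cnt))
  expect_equal(unname(f), dge$samples$norm.factors, tolerance = 1e-10)
  # and on random matrices with default trims
  set.seed(31)
  for (rep in 1:5) {
    m <- matrix(rnbinom(300 * 5, mu = 50, size = 2), 300, 5,
                dimnames = list(paste0("g", 1:300), paste0("s", 1:5)))
    m[1:10, 1] <- m[1:10, 1] * 20L  # some DE structure
    expect_equal(unname(tmmFactors(m)),
                 edgeR::calcNormFactors(edgeR::DGEList(m))$samples$norm.factors,
                 tolerance = 1e-10)
  }
})

test_that("pooled fold change has the expected symmetries", {
  set.seed(3)
  cpm <- matrix(runif(60, 50, 150), 3, 20,
                dimnames = list(c("a", "b", "c"), paste0("s", 1:20)))
  tu <- paste0("s", 1:10); no <- paste0("s", 11:20)
  same <- cbind(cpm[, tu], cpm[, tu])
  colnames(same) <- c(tu, no)
  expect_equal(unname(pooledLog2FC(same, tu, no)), rep(0, 3))
  doubled <- cbind(2 * cpm[, tu], cpm[, tu])
  colnames(doubled) <- c(tu, no)
  expect_equal(unname(pooledLog2FC(doubled, tu, no, eps = 0)), rep(1, 3))
  expect_equal(pooledLog2FC(cpm, tu, no), -pooledLog2FC(cpm, no, tu),
               tolerance = 1e-12)
  zero <- matrix(0, 1, 20, dimnames = list("z", colnames(cpm)))
  expect_error(pooledLog2FC(zero, tu, no, eps = 0), "pseudocount")
})

test_that("paired fold changes follow construction and decile rules", {
  pairs <- data.frame(tumor = paste0("P", 1:10, "_T"),
                      normal = paste0("P", 1:10, "_N"),
                      patient_id = paste0("P", 1:10))
  ratios <- c(rep(1, 9), 8)
  cpm <- cbind(matrix(100 * ratios, 1), matrix(100, 1, 10))
  dimnames(cpm) <- list("g1", c(pairs$tumor, pairs$normal))
  L <- pairedLog2FC(cpm, pairs, eps = 0)
  expect_equal(unname(trimmedStat(L[1, ], 90, 100, "mean")), 3)
  expect_equal(unname(trimmedStat(L[1, ], 10, 90, "mean")), 0)
  # reversing the tumor/normal labels negates every entry
  rev <- data.frame(tumor = pairs$normal, normal = pairs$tumor)
  cpm2 <- cpm; colnames(cpm2) <- c(pairs$normal, pairs$tumor)
  expect_equal(unname(pairedLog2FC(cpm, pairs, eps = 0)),
               -unname(pairedLog2FC(cpm2, pairs, eps = 0)))
  bad <- data.frame(tumor = "missing_T", normal = pairs$normal[1])
  expect_error(pairedLog2FC(cpm, bad), "missing_T")
})

test_that("pool stability features behave on constructed pools", {
  st <- poolStability(rep(256, 12), eps = 0)
  expect_equal(st$relsd, 0)
  expect_equal(st$outlier_hi, 0)
  expect_equal(st$outlier_lo, 0)
  expect_equal(st$inv_log2_cpm, 1 / 8)
  expect_false(st$low_expression)
  # scale invariance of the ratio features
  set.seed(2)
  pool <- runif(30, 50, 200)
  s1 <- poolStability(pool, eps = 0)
  s2 <- poolStability(pool * 37, eps = 0)
  expect_equal(s1$relsd, s2$relsd, tolerance = 1e-12)
  expect_equal(s1$outlier_hi, s2$outlier_hi, tolerance = 1e-12)
  expect_equal(s1$outlier_lo, s2$outlier_lo, tolerance = 1e-12)
  # a single 8-fold outlier in ten samples lands in the top decile
  st3 <- poolStability(c(rep(100, 9), 800), eps = 0)
  expect_equal(st3$outlier_hi, 3)
  # low-expression sentinel
  st4 <- suppressWarnings(poolStability(rep(0.5, 12)))
  expect_true(st4$low_expression)
  expect_true(is.na(st4$inv_log2_cpm))
  expect_warning(poolStability(rep(100, 5)), "fewer than 10")
})

test_that("decile outlier features are non-negative for pools >= 10", {
  set.seed(77)
  for (rep in 1:25) {
    pool <- exp(rnorm(sample(10:200, 1), 4, 1))
    st <- poolStability(pool, eps = 0)
    expect_gte(st$outlier_hi, 0)
    expect_gte(st$outlier_lo, 0)
  }
})

test_that("Spearman helper handles perfect, null and degenerate cases", {
  st <- spearmanTest(1:10, (1:10)^3)
  expect_equal(st$r, 1)
  expect_lt(st$p, 1e-10)
  expect_equal(spearmanTest(1:10, -(1:10))$r, -1)
  d <- spearmanTest(1:2, 2:1)           # too few observations
  expect_true(d$flag); expect_equal(c(d$r, d$p), c(0, 1))
  cst <- spearmanTest(1:10, rep(1, 10)) # single-level characteristic
  expect_true(cst$flag); expect_equal(c(cst$r, cst$p), c(0, 1))
  # null calibration: independent data rarely exceed |r| = 0.15 at n = 200
  set.seed(12)
  hits <- 0
  for (rep in 1:100) {
    r <- spearmanTest(rnorm(200), sample(rep(1:4, 50)))$r
    if (abs(r) < 0.15) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("clinical encodings map the six characteristics to ordinals", {
  cl <- data.frame(
    patient_id = paste0("P", 1:6),
    pathologic_t = c("T1", "T2a", "TX", "Tis", "T4", NA),
    pathologic_n = c("N0", "N1", "NX", "N2", "N3", "N0"),
    pathologic_m = c("M0", "M1", "MX", "M0", "M1", "M0"),
    pathologic_stage = c("Stage I", "Stage IIA", "Stage IIB", "Stage III",
                         "Stage IVA", NA),
    neoplasm_cancer_status = c("tumor free", "with tumor", "TUMOR FREE",
                               NA, "with tumor", "tumor free"),
    treatment_success = c("complete remission/response", "partial remission",
                          "stable disease", "progressive disease", NA,
                          "complete remission"))
  e <- encodeClinical(cl)
  expect_equal(e$pathologic_t, c(1, 2, NA, NA, 4, NA))
  expect_equal(e$pathologic_n, c(0, 1, NA, 2, 3, 0))
  expect_equal(e$pathologic_m, c(0, 1, NA, 0, 1, 0))
  expect_equal(e$pathologic_stage, c(1, 2, 2, 3, 4, NA))
  expect_equal(e$neoplasm_cancer_status, c(0, 1, 0, NA, 1, 0))
  expect_equal(e$treatment_success, c(0, 1, 2, 3, NA, 0))
})

test_that("clinical correlations emit 18 instances and detect monotone trends", {
  cfg <- defaultScoringConfig()
  pat <- paste0("P", 1:20)
  stage <- rep(1:4, each = 5)
  clin <- data.frame(patient_id = pat, pathologic_t = NA, pathologic_n = NA,
                     pathologic_m = NA, pathologic_stage = stage,
                     neoplasm_cancer_status = NA, treatment_success = NA)
  enc <- encodeClinical(clin)
  measures <- list(cpm_tumor = setNames(as.numeric(1:20) * 10, pat),
                   cpm_normal = setNames(rep(5, 20), pat),
                   log2fc_paired = setNames(rnorm(20), pat))
  cc <- clinicalCorrelations(measures, enc)
  expect_equal(nrow(cc), 18)
  # within the 10-90 restriction the increasing measure tracks stage
  r <- cc$r[cc$measure == "cpm_tumor" & cc$characteristic == "pathologic_stage"]
  expect_gt(r, 0.9)
  # constant measure is flagged maximally stable
  cn <- cc[cc$measure == "cpm_normal" & cc$characteristic == "pathologic_stage", ]
  expect_true(cn$flag); expect_equal(c(cn$r, cn$p), c(0, 1))
})

test_that("feature extraction recovers constructed gene behaviour", {
  ds <- tinyDataset(seed = 42)
  fx <- extractFeatures(ds)
  expect_equal(nrow(fx$features), 6)
  expect_equal(ncol(fx$corrR), 18)
  # stable high-expression gene: difference/stability features near zero
  f1 <- fx$features["g001", ]
  expect_lt(abs(f1$log2fc_p), 0.1)
  expect_lt(abs(f1$avg_log2fc_l_10_90), 0.1)
  expect_lt(f1$relsd_tumor, 0.1)
  # the engineered 2-fold tumor gene
  f2 <- fx$features["g002", ]
  expect_equal(f2$log2fc_p, 1, tolerance = 0.1)
  expect_equal(f2$avg_log2fc_l_10_90, 1, tolerance = 0.1)
})

test_that("features are invariant to sample order and uniform rescaling", {
  ds <- tinyDataset(seed = 8)
  fx <- extractFeatures(ds)
  counts <- assay(ds, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(ds))
  set.seed(1)
  perm <- sample(ncol(counts))
  dsPerm <- RGDataset(counts[, perm],
                      cd[perm, c("sample_id", "patient_id", "tissue")],
                      clinicalTable(ds))
  fxPerm <- extractFeatures(dsPerm)
  expect_equal(fxPerm$features, fx$features, tolerance = 1e-9)
  expect_equal(fxPerm$corrR, fx$corrR, tolerance = 1e-9)
  # depth rescaling is absorbed by TMM + CPM
  dsScaled <- RGDataset(counts * 4L,
                        cd[, c("sample_id", "patient_id", "tissue")],
                        clinicalTable(ds))
  fxScaled <- extractFeatures(dsScaled)
  expect_equal(fxScaled$features, fx$features, tolerance = 1e-9)
})

test_that("pair-free datasets fall back to pooled fold changes with a flag", {
  ds <- tinyDataset(seed = 4)
  counts <- assay(ds, "counts")
  cd <- as.data.frame(SummarizedExperiment::colData(ds))
  cd$patient_id <- paste0(cd$patient_id, ifelse(cd$tissue == "tumor",
                                                "a", "b"))
  cd$sample_id <- cd$sample_id
  dsNoPairs <- RGDataset(counts, cd[, c("sample_id", "patient_id", "tissue")])
  expect_equal(nrow(samplePairs(dsNoPairs)), 0)
  expect_warning(fx <- extractFeatures(dsNoPairs), "pooled fold change")
  expect_equal(fx$features$avg_log2fc_l_10_90, fx$features$log2fc_p)
  expect_true(any(grepl("fall back", fx$flags)))
})
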