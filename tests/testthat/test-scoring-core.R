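test_that("component curve hits its closed-form landmarks", {
  # inflection point with squeeze 1 gives exactly half the maximum
  expect_equal(componentScore(0.3, iv = 0.1, ip = 0.3, cs = 2), 50)
  expect_equal(componentScore(0.25, iv = 0.05, ip = 0.25, cs = 2.5), 50)
  expect_equal(componentScore(95, iv = 75, ip = 95, cs = 4), 50)
  # the ideal region saturates at 100
  expect_equal(componentScore(0.1, iv = 0.1, ip = 0.3, cs = 2), 100)
  expect_equal(componentScore(-5, iv = 0.05, ip = 0.25, cs = 2.5), 100)
  expect_equal(componentScore(0.04, iv = 0.05, ip = 0.25, cs = 2.5), 100)
  # isoform curve at the inflection with squeeze 0.4
  expect_equal(componentScore(3, iv = 1, ip = 3, cs = 2, sq = 0.4),
               100 / 1.4, tolerance = 1e-9)
  # at x = IP the score is 100/(1+Sq) whatever the slope
  for (cs in c(0.5, 1, 2, 7))
    expect_equal(componentScore(4, iv = 2, ip = 4, cs = cs, sq = 0.3),
                 100 / 1.3, tolerance = 1e-12)
})

test_that("component curve rejects invalid inputs and parameters", {
  expect_error(componentScore(NaN, 0, 1, 2), "non-finite")
  expect_error(componentScore(Inf, 0, 1, 2), "non-finite")
  expect_error(componentScore(NA_real_, 0, 1, 2), "non-finite")
  expect_error(componentScore(1, iv = 2, ip = 1, cs = 2), "exceed")
  expect_error(componentScore(1, iv = 0, ip = 1, cs = -1), "slope")
  expect_error(componentScore(1, iv = 0, ip = 1, cs = 1, sq = 0), "squeeze")
})

test_that("component curve is monotone non-increasing and bounded", {
  set.seed(11)
  for (rep in 1:50) {
    iv <- runif(1, -1, 1)
    ip <- iv + runif(1, 0.05, 2)
    cs <- runif(1, 0.2, 6)
    sq <- runif(1, 0.1, 3)
    x <- sort(runif(200, iv - 1, iv + 10))
    s <- componentScore(x, iv, ip, cs, sq)
    expect_true(all(diff(s) <= 1e-12))
    expect_true(all(s >= 0 & s <= 100))
    # strictly decreasing past the ideal value
    past <- x > ip
    if (sum(past) > 1) expect_true(all(diff(s[past]) < 0))
  }
  # approaches zero for extreme x
  expect_lt(componentScore(1e6, 0.05, 0.25, 2.5), 1e-10)
})

test_that("default registry expands to the documented 48 instances", {
  inst <- expandRegistry()
  expect_equal(nrow(inst), 48)
  counts <- table(inst$id)
  expect_equal(unname(counts[c("S_Cp", "S_Cr")]), c(18L, 18L),
               ignore_attr = TRUE)
  expect_equal(unname(counts[c("S_EStD", "S_EoH", "S_EoL")]), c(2L, 2L, 2L),
               ignore_attr = TRUE)
  expect_equal(sum(counts[c("S_DP", "S_DL", "S_DoO", "S_DoU", "S_DLc",
                            "S_EA")]), 6L)
  expect_false(anyDuplicated(inst$instance) > 0)
})

test_that("registry honours strict and lenient clinical configuration", {
  cfg <- defaultScoringConfig()
  cfg$clinical_characteristics <- character(0)
  expect_error(buildRegistry(cfg, strict = TRUE), "configuration error")
  inst <- expandRegistry(buildRegistry(cfg, strict = FALSE), cfg)
  expect_equal(nrow(inst), 12)  # 48 - 36 correlation instances
})

test_that("registry parameters reproduce the configured component table", {
  cfg <- defaultScoringConfig()
  inst <- expandRegistry()
  dp <- inst[inst$id == "S_DP", ]
  expect_equal(unlist(dp[, c("iv", "ip", "cs", "sq", "ca", "w")]),
               c(iv = 0.05, ip = 0.25, cs = 2.5, sq = 1, ca = 0, w = 4))
  cp <- inst[inst$id == "S_Cp", ][1, ]
  expect_equal(unlist(cp[, c("iv", "ip", "cs", "sq", "ca", "w")]),
               c(iv = 2, ip = 4, cs = 3, sq = 0.3, ca = 5, w = 0.3))
  expect_equal(cfg$anti$S_Mut[c("iv", "ip", "cs")],
               list(iv = 75, ip = 95, cs = 4))
})

test_that("expression-score aggregation matches closed forms", {
  inst2 <- data.frame(instance = c("a", "b"), ca = 0, w = 1)
  expect_equal(aggregateExpressionScore(c(a = 50, b = 100), inst2),
               sqrt(50 * 100), tolerance = 1e-12)
  # identical saturated components aggregate to the maximum
  inst <- expandRegistry()
  all100 <- setNames(rep(100, nrow(inst)), inst$instance)
  expect_equal(aggregateExpressionScore(all100, inst), 100,
               tolerance = 1e-12)
  # a zero component with no constant add annihilates the aggregate
  all0 <- setNames(rep(0, nrow(inst)), inst$instance)
  expect_equal(aggregateExpressionScore(all0, inst), 0)
  # missing instances are reported by name
  expect_error(aggregateExpressionScore(all100[-1], inst),
               inst$instance[1], fixed = TRUE)
})

test_that("aggregation is order-invariant and weight-scale-invariant", {
  set.seed(5)
  inst <- expandRegistry()
  s <- setNames(runif(nrow(inst), 0, 100), inst$instance)
  ref <- aggregateExpressionScore(s, inst)
  perm <- inst[sample(nrow(inst)), ]
  expect_equal(aggregateExpressionScore(s, perm), ref, tolerance = 1e-12)
  scaled <- inst
  scaled$w <- scaled$w * 7.3
  expect_equal(aggregateExpressionScore(s, scaled), ref, tolerance = 1e-12)
})

test_that("aggregation agrees with a direct product-form evaluation", {
  set.seed(23)
  for (rep in 1:30) {
    n <- sample(1:4, 1)
    inst <- data.frame(instance = letters[seq_len(n)],
                       ca = round(runif(n, 0, 10), 1),
                       w = round(runif(n, 0.1, 6), 2))
    s <- setNames(runif(n, 0, 100), inst$instance)
    got <- aggregateExpressionScore(s, inst)
    want <- oracleAggregate(as.numeric(s[inst$instance]), inst$ca, inst$w)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("anti-scorings apply the configured curves", {
  a <- antiScores(50, 1, 0)
  expect_equal(unlist(a), c(s_mut = 100, s_isoforms = 100,
                            s_pseudogenes = 100))
  expect_equal(antiScores(95, 1, 0)$s_mut, 50)
  expect_equal(antiScores(0, 1, 2)$s_pseudogenes, 100 / 1.4,
               tolerance = 1e-9)
  expect_warning(a <- antiScores(NA, 3, 0), "neutral")
  expect_equal(a$s_mut, 100)
  expect_error(antiScores(120, 1, 0), "\\[0, 100\\]")
  expect_error(antiScores(50, -1, 0), "non-negative")
})

test_that("final score combines factors on the 0-100 scale", {
  expect_equal(finalScore(80, 100, 100, 100), 80)
  expect_equal(finalScore(80, 50, 100, 100), 40)
  expect_equal(finalScore(80, 50, 0, 100), 0)
  expect_error(finalScore(120, 100, 100, 100), "\\[0, 100\\]")
  # never exceeds the expression score once any anti-score bites
  set.seed(3)
  se <- runif(20, 0, 100)
  sm <- runif(20, 0, 100)
  expect_true(all(finalScore(se, sm, 100, 100) <= se + 1e-12))
})

test_that("pan-cancer power mean reproduces its closed forms", {
  # identical per-condition values pass through with the constant offset
  r <- panCancerScore(rep(70, 12), rep(100, 12))
  expect_equal(r$sExpMutPan, 82, tolerance = 1e-12)
  expect_equal(r$m, 12)
  # two-condition worked value, frozen from direct evaluation of the
  # power-mean formula: ((42^-0.4 + 102^-0.4)/2)^(-1/0.4)
  r2 <- panCancerScore(c(30, 90), c(100, 100))
  expect_equal(r2$sExpMutPan, 62.9386703959, tolerance = 1e-9)
  # anti-scores scale the final pan-cancer value
  r3 <- panCancerScore(c(30, 90), c(100, 100), sIsoforms = 50)
  expect_equal(r3$sFinalPan, r2$sExpMutPan / 2, tolerance = 1e-12)
  expect_error(panCancerScore(numeric(0), numeric(0)), "no per-condition")
})

test_that("pan-cancer aggregate approaches the arithmetic mean as k -> 1", {
  set.seed(9)
  v <- runif(12, 10, 95)
  near1 <- panCancerScore(v, rep(100, 12), k = 0.999)$sExpMutPan
  expect_equal(near1, mean(v + 12), tolerance = 1e-3)
  # and sits below it for the default negative exponent (power-mean order)
  expect_lt(panCancerScore(v, rep(100, 12))$sExpMutPan, mean(v + 12))
})

test_that("ComponentSpec validity enforces the parameter invariants", {
  expect_error(ComponentSpec("bad", iv = 2, ip = 1, cs = 2), "exceed")
  expect_error(ComponentSpec("bad", iv = 0, ip = 1, cs = 2, w = -1),
               "positive")
  sp <- ComponentSpec("S_X", iv = 0, ip = 1, cs = 2, nApplied = 3L)
  expect_equal(componentId(sp), "S_X")
  expect_output(show(sp), "S_X")
})
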