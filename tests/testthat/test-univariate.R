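test_that("Mann-Whitney U and exact p match enumeration on worked examples", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p.value, 0.1)  # 2 of the 20 label arrangements are as extreme
  same <- mannWhitneyU(c(1, 2, 3), c(3, 1, 2))
  expect_equal(same$U, 9 / 2)
  expect_equal(same$p.value, 1)
  expect_equal(mannWhitneyU(c(1, 2), c(1, 3))$U, 1.5)
  # all values identical across both groups: p = 1 by convention
  expect_equal(mannWhitneyU(rep(2, 5), rep(2, 7))$p.value, 1)
  expect_equal(mannWhitneyU(rep(2, 30), rep(2, 40))$p.value, 1)
})

test_that("exact p equals exhaustive label-permutation enumeration", {
  set.seed(101)
  for (i in 1:12) {
    inst <- randomInstance(nmax = 11, tie = (i %% 2 == 0))
    got <- mannWhitneyU(inst$x, inst$y)$p.value
    expect_equal(got, bruteExactP(inst$x, inst$y), tolerance = 1e-12)
  }
})

test_that("large-sample p agrees with the tie-corrected normal reference", {
  set.seed(55)
  x <- round(rnorm(60), 1)
  y <- round(rnorm(45, 0.3), 1)
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mannWhitneyU(x, y)$p.value, ref$p.value, tolerance = 1e-10)
})

test_that("Cliff's delta matches brute force and its boundary cases", {
  expect_equal(cliffsDelta(c(5, 6, 7), c(1, 2, 3)), 1)
  expect_equal(cliffsDelta(rep(4, 5), rep(4, 5)), 0)
  expect_equal(cliffsDelta(c(1, 2), c(1, 3)), -0.25)
})

test_that("fast-path U, delta, AUC, Youden and HL equal brute-force oracles", {
  set.seed(2024)
  for (i in 1:220) {
    inst <- randomInstance(nmax = 60, tie = (i %% 3 != 0))
    x <- inst$x; y <- inst$y
    expect_equal(mannWhitneyU(x, y)$U, bruteU(x, y), tolerance = 1e-9)
    expect_equal(cliffsDelta(x, y), bruteDelta(x, y), tolerance = 1e-12)
    v <- c(x, y)
    lab <- c(rep("soluble", length(x)), rep("insoluble", length(y)))
    expect_equal(rocAUC(v, lab), bruteAUC(v, lab), tolerance = 1e-12)
    yt <- youdenThreshold(v, lab)
    bt <- bruteYouden(v, lab)
    expect_equal(yt$J, bt$J, tolerance = 1e-12)
    expect_equal(yt$threshold, bt$threshold)
    hl <- hodgesLehmann(x, y)
    expect_equal(hl[["shift"]], bruteHL(x, y), tolerance = 1e-9)
  }
})

test_that("AUC = (delta + 1) / 2 exactly, ties included", {
  set.seed(31)
  for (i in 1:50) {
    inst <- randomInstance(nmax = 60)
    v <- c(inst$x, inst$y)
    lab <- c(rep("soluble", length(inst$x)),
             rep("insoluble", length(inst$y)))
    expect_equal(rocAUC(v, lab), (cliffsDelta(inst$x, inst$y) + 1) / 2,
                 tolerance = 1e-14)
  }
})

test_that("Hodges-Lehmann worked examples and translation equivariance", {
  expect_equal(hodgesLehmann(c(1, 2, 3), c(0, 1, 2))[["shift"]], 1)
  set.seed(4)
  x <- rnorm(21)
  expect_equal(hodgesLehmann(x, x + 2.5)[["shift"]], -2.5, tolerance = 1e-9)
  hl <- hodgesLehmann(rnorm(40), rnorm(35))
  expect_lte(hl[["low"]], hl[["shift"]])
  expect_lte(hl[["shift"]], hl[["high"]])
})

test_that("bootstrap delta CI is deterministic, degenerate at separation", {
  x <- 1:20; y <- 101:120  # no overlap: delta constant at -1
  ci <- bootstrapDeltaCI(x, y, B = 200, seed = 5)
  expect_equal(unname(ci), c(-1, -1))
  a <- bootstrapDeltaCI(rnorm(30), rnorm(30), B = 150, seed = 9)
  b <- bootstrapDeltaCI(rnorm(30), rnorm(30), B = 150, seed = 9)
  # same seed gives the same interval regardless of ambient RNG state
  set.seed(123)
  x2 <- rnorm(30); y2 <- rnorm(30)
  expect_identical(bootstrapDeltaCI(x2, y2, B = 150, seed = 9),
                   bootstrapDeltaCI(x2, y2, B = 150, seed = 9))
  expect_error(bootstrapDeltaCI(x2, y2, B = 10), "B")
})

test_that("bootstrap CI covers the null delta at nominal-ish rate", {
  set.seed(77)
  covered <- 0
  reps <- 50
  for (i in 1:reps) {
    x <- rnorm(200); y <- rnorm(200)
    ci <- bootstrapDeltaCI(x, y, B = 400, seed = 1000 + i)
    if (ci[1] <= 0 && 0 <= ci[2]) covered <- covered + 1
  }
  expect_gte(covered / reps, 0.9)
})

test_that("BH adjustment reproduces the step-up on a hand example", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bhAdjust(0.2), 0.2)
  expect_equal(bhAdjust(rep(1, 5)), rep(1, 5))
  p <- c(0.04, 0.001, 0.9)
  expect_true(all(bhAdjust(p) >= p))
})

test_that("analyzeFeatures is order-invariant and flags injected shifts", {
  set.seed(12)
  n <- 120
  vals <- matrix(rnorm(n * 36), nrow = n,
                 dimnames = list(NULL, solubilityFeatureNames()))
  vals[, "length"] <- abs(vals[, "length"]) * 50 + 30
  labels <- rep(c("soluble", "insoluble"), each = n / 2)
  # inject a +1 SD shift on one feature only
  vals[labels == "soluble", "neg_ratio"] <-
    vals[labels == "soluble", "neg_ratio"] + 1
  sf <- SolubilityFeatures(vals, labels = labels,
                           ids = sprintf("p%03d", 1:n))
  res <- analyzeFeatures(sf, bootstrapB = 0, seed = 3)
  expect_equal(nrow(res), 36)
  expect_equal(res$feature_name[which.min(res$q_value)], "neg_ratio")
  expect_true(all(res$q_value >= res$p_value - 1e-15))
  expect_true(all(res$youden_j >= 0))
  expect_equal(res$auc, (res$delta + 1) / 2, tolerance = 1e-14)
  # permuting protein order leaves every statistic unchanged
  perm <- sample(n)
  sfp <- SolubilityFeatures(vals[perm, ], labels = labels[perm],
                            ids = sprintf("p%03d", 1:n)[perm])
  resp <- analyzeFeatures(sfp, bootstrapB = 0, seed = 3)
  expect_equal(resp, res)
  # identical classes: delta 0, q near 1
  sf0 <- SolubilityFeatures(rbind(vals[1:30, ], vals[1:30, ]),
                            labels = rep(c("soluble", "insoluble"),
                                         each = 30),
                            ids = sprintf("q%03d", 1:60))
  res0 <- analyzeFeatures(sf0, bootstrapB = 0)
  expect_true(all(res0$delta == 0))
  expect_true(all(res0$q_value > 0.9))
  expect_error(analyzeFeature(sf, "not_a_feature"), "unknown feature")
})

test_that("delta bootstrap CI brackets delta and feature seeds are stable", {
  set.seed(6)
  vals <- matrix(rnorm(80 * 36), nrow = 80,
                 dimnames = list(NULL, solubilityFeatureNames()))
  sf <- SolubilityFeatures(vals, labels = rep(c("soluble", "insoluble"), 40),
                           ids = sprintf("p%02d", 1:80))
  r1 <- analyzeFeature(sf, "neg_ratio", bootstrapB = 200, seed = 11)
  r2 <- analyzeFeature(sf, "neg_ratio", bootstrapB = 200, seed = 11)
  expect_equal(r1, r2)
  expect_lte(r1$delta_ci_low, r1$delta)
  expect_lte(r1$delta, r1$delta_ci_high)
})
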