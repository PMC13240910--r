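reducedModel <- function() {
  CompositeModel(c("length", "neg_ratio"), c(-0.215, 0.150),
                 c(236, 0.126531), c(231, 0.039934))
}

test_that("robust scaling is (x - median)/IQR with positive IQR required", {
  expect_equal(robustScale(10, 10, 3), 0)
  expect_equal(robustScale(13, 10, 3), 1)
  expect_equal(robustScale(236, 236, 231), 0)
  expect_error(robustScale(1, 0, 0), "IQR")
  expect_error(robustScale(1, 0, -2), "IQR")
})

test_that("the reduced two-feature score reproduces its coefficients", {
  m <- reducedModel()
  # length term at exactly one robust-scale unit
  expect_equal(compositeScore(m, c(length = 467, neg_ratio = 0.126531)),
               -0.215)
  # negative-charge term at exactly one robust-scale unit
  expect_equal(compositeScore(m, c(length = 236, neg_ratio = 0.166465)),
               0.150)
  expect_equal(compositeScore(m, c(length = 236, neg_ratio = 0.126531)), 0)
})

test_that("classification is the sign rule with the boundary insoluble", {
  expect_equal(as.character(classifyScore(c(0.01, 0, -3))),
               c("soluble", "insoluble", "insoluble"))
})

test_that("fitComposite pools both classes, is deterministic, validates", {
  set.seed(21)
  n <- 200
  vals <- matrix(rnorm(n * 36), nrow = n,
                 dimnames = list(NULL, solubilityFeatureNames()))
  labels <- rep(c("soluble", "insoluble"), each = n / 2)
  vals[labels == "soluble", "neg_ratio"] <-
    vals[labels == "soluble", "neg_ratio"] + 0.8
  sf <- SolubilityFeatures(vals, labels = labels,
                           ids = sprintf("p%03d", 1:n))
  res <- analyzeFeatures(sf, bootstrapB = 0)
  m <- fitComposite(sf, res, c("length", "neg_ratio"))
  expect_s4_class(m, "CompositeModel")
  pooled <- quantile(vals[, "neg_ratio"], c(0.25, 0.5, 0.75), names = FALSE)
  expect_equal(unname(m@medians[["neg_ratio"]]), pooled[2])
  expect_equal(unname(m@iqrs[["neg_ratio"]]), pooled[3] - pooled[1])
  expect_equal(unname(m@weights[["neg_ratio"]]),
               res$delta[res$feature_name == "neg_ratio"])
  m2 <- fitComposite(sf, res, c("length", "neg_ratio"))
  expect_equal(m, m2)
  expect_error(fitComposite(sf, res, "no_such_feature"), "missing")
  # constant feature has zero IQR
  vals2 <- vals; vals2[, "length"] <- 5
  sfc <- SolubilityFeatures(vals2, labels = labels,
                            ids = sprintf("p%03d", 1:n))
  expect_error(fitComposite(sfc, res, "length"), "IQR")

  # single-feature model: ranking by S equals (sign-adjusted) raw ranking
  m1 <- fitComposite(sf, res, "neg_ratio")
  s1 <- compositeScore(m1, sf)
  aucS <- rocAUC(s1, labels)
  aucF <- rocAUC(vals[, "neg_ratio"], labels)
  expect_true(abs(aucS - aucF) < 1e-12 || abs(aucS - (1 - aucF)) < 1e-12)

  # affine rescaling of a raw feature with refit constants leaves S unchanged
  vals3 <- vals; vals3[, "length"] <- 3.7 * vals3[, "length"] + 11
  sf3 <- SolubilityFeatures(vals3, labels = labels,
                            ids = sprintf("p%03d", 1:n))
  res3 <- analyzeFeatures(sf3, bootstrapB = 0)
  mA <- fitComposite(sf, res, c("length", "neg_ratio"))
  mB <- fitComposite(sf3, res3, c("length", "neg_ratio"))
  expect_equal(compositeScore(mB, sf3), compositeScore(mA, sf),
               tolerance = 1e-9)
})

test_that("evaluation metrics match the confusion-matrix formulas", {
  perfect <- evaluateScores(c(1, 2, -1, -2),
                            c("soluble", "soluble", "insoluble", "insoluble"))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$auc, 1)
  # everything predicted one class: MCC = 0 by convention
  oneClass <- evaluateScores(c(1, 2, 3, 4),
                             c("soluble", "soluble", "insoluble", "insoluble"))
  expect_equal(oneClass$mcc, 0)
  expect_equal(oneClass$specificity, 0)
  # TP=3 FP=1 FN=1 TN=3 gives MCC = 0.5 by the direct formula
  scores <- c(1, 1, 1, -1, 1, -1, -1, -1)
  labels <- c(rep("soluble", 4), rep("insoluble", 4))
  m <- evaluateScores(scores, labels)
  expect_equal(m$mcc, 0.5)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, 3 / 4)
  expect_equal(m$sensitivity, 3 / 4)
  expect_equal(m$specificity, 3 / 4)
  expect_equal(m$f1, 3 / 4)
})

test_that("composite models serialize to JSON and back", {
  m <- reducedModel()
  path <- tempfile(fileext = ".json")
  writeCompositeModel(m, path)
  back <- readCompositeModel(path)
  expect_equal(back@features, m@features)
  expect_equal(back@weights, m@weights)
  expect_equal(back@medians, m@medians)
  expect_equal(back@iqrs, m@iqrs)
})
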