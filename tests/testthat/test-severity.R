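test_that("two-group clustering splits separated clusters at the gap", {
  p <- twoGroupCluster(c(0, 1, 2, 10, 11, 12), "toy")
  expect_identical(cutoffBand(p), c(2, 10))
  expect_identical(p@nSevere, 3L)
  expect_identical(severityLabels(p),
                   rep(c("severe", "non_severe"), each = 3))
  expect_error(twoGroupCluster(rep(3, 6)), "degenerate")
  expect_error(twoGroupCluster(c(1, 2, 3)), "length")
})

test_that("the exhaustive split equals the k-means optimum on random data", {
  for (s in 1:20) {
    set.seed(s)
    x <- round(c(rnorm(15, 2, 1.5), rnorm(10, 10, 3)), 2)
    if (diff(range(x)) == 0) next
    p <- twoGroupCluster(x, "sim")
    expect_equal(cutoffBand(p)[1], kmeansCut(x),
                 info = paste("seed", s))
  }
})

test_that("reference cohort cluster splits land at the observed score gaps", {
  coh <- cohortFixture()
  pC <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
  expect_equal(cutoffBand(pC), c(19, 23.3))
  pW <- twoGroupCluster(coh$words_per_min, "words_per_min")
  expect_equal(cutoffBand(pW), c(31.2, 35.3))
  pB <- twoGroupCluster(coh$bnt, "bnt")
  expect_equal(cutoffBand(pB), c(7, 8))
  expect_identical(pB@nSevere, 33L)
})

test_that("discriminant resubstitution accuracy behaves as a separation measure", {
  toy <- c(0, 1, 2, 10, 11, 12)
  p <- twoGroupCluster(toy, "toy")
  expect_identical(discriminantAccuracy(toy, p), 1)

  coh <- cohortFixture()
  pB <- twoGroupCluster(coh$bnt, "bnt")
  expect_identical(discriminantAccuracy(coh$bnt, pB), 1)
  pC <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
  expect_identical(discriminantAccuracy(coh$cius_per_min, pC), 1)
  pW <- twoGroupCluster(coh$words_per_min, "words_per_min")
  expect_gte(discriminantAccuracy(coh$words_per_min, pW), 0.9)
})

test_that("trapezoidal AUC equals the pairwise U-statistic oracle", {
  for (s in 1:15) {
    set.seed(1000 + s)
    n <- sample(10:50, 1)
    pred <- round(rexp(n, 0.3), 1)          # deliberate ties
    sev <- runif(n) < 0.6
    if (!any(sev) || all(sev)) next
    part <- severityFromCutoff(ifelse(sev, 0, 1), 0, "lab")
    expect_equal(auc(rocAnalysis(pred, part)), pairwiseAUC(pred, sev),
                 tolerance = 1e-12, info = paste("seed", s))
  }
})

test_that("AUC is invariant under strictly monotone predictor transforms", {
  coh <- cohortFixture()
  part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
  raw <- rocAnalysis(coh$af_ll_cc, part)
  cub <- rocAnalysis(cubeRoot(coh$af_ll_cc), part)
  expect_equal(auc(raw), auc(cub), tolerance = 1e-12)
  # and the selected thresholds correspond through the same transform
  expect_equal(cub@sensitivity, raw@sensitivity)
  expect_equal(cub@specificity, raw@specificity)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  coh <- cohortFixture()
  part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
  ours <- auc(rocAnalysis(coh$af_ll_cc, part))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = severityLabels(part) == "severe",
    predictor = coh$af_ll_cc, direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("an uninformative predictor scores AUC 0.5", {
  part <- severityFromCutoff(c(1, 1, 2, 2, 2), 1, "lab")
  expect_equal(auc(rocAnalysis(rep(3.3, 5), part)), 0.5)
})

test_that("the arcuate load outclassifies raw lesion volume on the reference cohort", {
  coh <- cohortFixture()
  part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
  rocAf <- rocAnalysis(coh$af_ll_cc, part)
  rocVol <- rocAnalysis(coh$lesion_volume_cc, part)
  expect_gt(auc(rocAf), auc(rocVol))
  # the decision threshold falls between adjacent observed load values
  expect_equal(thresholdCc(rocAf), (3.70 + 3.78) / 2)
})

test_that("threshold stratification calls the boundary severe", {
  expect_identical(stratify(9.75, 4), "severe")
  expect_identical(stratify(0.07, 4), "non_severe")
  expect_identical(stratify(4, 4), "severe")
  expect_identical(stratify(c(1, 5), 4), c("non_severe", "severe"))
})

test_that("degenerate severity inputs are rejected", {
  part <- severityFromCutoff(c(1, 2, 3, 4), 2, "lab")
  expect_error(rocAnalysis(c(1, 2, 3), part), "length")
  expect_error(severityFromCutoff(c(1, 2), 5, "x"), "empty")
})
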