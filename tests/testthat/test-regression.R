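test_that("cube root transform", {
  expect_identical(cubeRoot(8), 2)
  expect_identical(cubeRoot(0), 0)
  expect_equal(cubeRoot(4.01), 4.01^(1 / 3))
  expect_error(cubeRoot(-1), "nonnegative")
})

test_that("a perfectly predictive model has R^2 = 1 and no exclusions", {
  coh <- cohortFixture()
  coh$mirror <- coh$af_ll_cc
  fit <- fitModel(coh, regressionSpec("cius_per_min", "mirror",
                                      covariates = character(),
                                      transform = "identity"))
  # not literally 1 on real data; use a constructed outcome instead
  coh$cius_per_min <- 3 + 2 * cubeRoot(coh$af_ll_cc)
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    fitModel(coh, regressionSpec("cius_per_min", "af_ll_cc",
                                 covariates = character())))
  expect_equal(rSquared(fit), 1)
  expect_identical(excludedIds(fit), character(0))
  expect_identical(fit@nUsed, 50L)
})

test_that("fitModel agrees with a hand-built lm and residual-based partial correlations", {
  coh <- cohortFixture()
  fit <- fitModel(coh, regressionSpec("cius_per_min", "af_ll_cc",
                                      outlierSd = Inf))
  df <- data.frame(y = coh$cius_per_min, x = coh$af_ll_cc^(1 / 3),
                   age = coh$age_years, mo = coh$months_post_stroke)
  ref <- lm(y ~ x + age + mo, data = df)
  expect_equal(rSquared(fit), summary(ref)$r.squared, tolerance = 1e-12)
  expect_equal(fit@adjRSquared, summary(ref)$adj.r.squared,
               tolerance = 1e-12)

  # partial r via the residual-residual correlation oracle
  rx <- resid(lm(x ~ age + mo, data = df))
  ry <- resid(lm(y ~ age + mo, data = df))
  expect_equal(unname(partialR(fit)["af_ll_cc"]), cor(rx, ry),
               tolerance = 1e-9)
})

test_that("R^2 is invariant to affine predictor rescaling and grows with added predictors", {
  coh <- cohortFixture()
  base <- fitModel(coh, regressionSpec("bnt", "af_ll_cc",
                                       outlierSd = Inf))
  coh$af_scaled <- 100 * coh$af_ll_cc + 7
  resc <- fitModel(coh, regressionSpec("bnt", "af_scaled",
                                       transform = "identity",
                                       outlierSd = Inf))
  ident <- fitModel(coh, regressionSpec("bnt", "af_ll_cc",
                                        transform = "identity",
                                        outlierSd = Inf))
  expect_equal(rSquared(resc), rSquared(ident), tolerance = 1e-12)

  more <- fitModel(coh, regressionSpec("bnt", c("af_ll_cc", "emc_ll_cc"),
                                       outlierSd = Inf))
  expect_gte(rSquared(more), rSquared(base) - 1e-12)
})

test_that("the studentized-residual pass removes at most 5% of the cohort", {
  coh <- cohortFixture()
  for (oc in c("cius_per_min", "words_per_min", "bnt")) {
    fit <- fitModel(coh, regressionSpec(oc, "af_ll_cc"))
    expect_lte(length(excludedIds(fit)), ceiling(0.05 * nrow(coh)))
    expect_identical(fit@nUsed + length(excludedIds(fit)), 50L)
  }
})

test_that("design and sample-size contracts are enforced", {
  coh <- cohortFixture()
  coh$dup <- coh$af_ll_cc
  expect_error(fitModel(coh, regressionSpec("bnt", c("af_ll_cc", "dup"))),
               "singular design")
  expect_error(fitModel(coh[1:5, ], regressionSpec("bnt", "af_ll_cc")),
               "too few")
  expect_error(fitModel(coh, regressionSpec("bnt", "not_a_column")),
               "lacks model column")
})

test_that("the dorsal-ventral comparison singles out the arcuate load", {
  coh <- cohortFixture()
  fit <- fitDorsalVentralComparison(coh, "cius_per_min")
  pr <- partialR(fit)
  expect_identical(names(pr), c("af_ll_cc", "emc_ll_cc", "uf_ll_cc"))
  expect_lt(pr[["af_ll_cc"]], 0)
  expect_identical(names(which.max(abs(pr))), "af_ll_cc")

  co <- fit@coefficients
  pAf <- co$p_value[co$term == "af_ll_cc"]
  pOther <- co$p_value[co$term %in% c("emc_ll_cc", "uf_ll_cc",
                                      "lesion_volume_cc")]
  expect_lt(pAf, 0.05)
  expect_true(all(pOther > 0.05))

  # naming: arcuate load is likewise the only significant predictor
  fitB <- fitDorsalVentralComparison(coh, "bnt")
  coB <- fitB@coefficients
  expect_lt(coB$p_value[coB$term == "af_ll_cc"], 0.05)
  expect_true(all(coB$p_value[coB$term %in% c("emc_ll_cc", "uf_ll_cc",
                                              "lesion_volume_cc")] > 0.05))
})

test_that("known slopes are recovered from simulated cohorts", {
  cfg0 <- syntheticConfig("compact", nPatients = 200, seed = 1)
  maps <- generateCanonicalMaps(cfg0)
  b1 <- cfg0$outcomeModel$cius_per_min[["beta1"]]
  covered <- logical(5)
  for (s in seq_len(5)) {
    cfg <- syntheticConfig("compact", nPatients = 200, seed = 9000 + s)
    st <- generateCohort(cfg, maps = maps)
    fit <- fitModel(st$cohort, regressionSpec("cius_per_min", "af_ll_cc"))
    ci <- confint(fit@fit)["af_ll_cc", ]
    covered[s] <- ci[1] <= b1 && b1 <= ci[2]
  }
  expect_gte(sum(covered), 4L)
})
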