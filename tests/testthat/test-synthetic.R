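test_that("identical seeds reproduce identical studies", {
  cfg <- syntheticConfig("compact", nPatients = 8, seed = 42)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(a$cohort, b$cohort)
  expect_identical(voxelValues(a$lesionMasks[[3]]),
                   voxelValues(b$lesionMasks[[3]]))
  expect_identical(voxelCounts(a$maps$AF), voxelCounts(b$maps$AF))
  # different seed, different cohort
  c2 <- generateCohort(syntheticConfig("compact", nPatients = 8,
                                       seed = 43))
  expect_false(identical(a$cohort$af_ll_cc, c2$cohort$af_ll_cc))
})

test_that("zero jitter collapses the subject maps onto one tube", {
  cfg <- syntheticConfig("compact", subjectJitterMm = 0, seed = 5)
  maps <- generateSubjectTractMaps(cfg)
  expect_length(maps, 12L)
  for (m in maps[-1])
    expect_identical(voxelValues(m), voxelValues(maps[[1]]))
  agg <- aggregateSubjectMaps(maps, "AF")
  expect_true(all(voxelCounts(agg) %in% c(0L, 12L)))
})

test_that("jittered subject maps aggregate into a graded map with a consensus core", {
  cfg <- syntheticConfig("cohort", seed = 11)
  agg <- aggregateSubjectMaps(generateSubjectTractMaps(cfg), "AF")
  cnt <- voxelCounts(agg)
  expect_identical(max(cnt), 12L)
  expect_true(any(cnt > 0L & cnt < 12L))  # graded margins
  # the unjittered tube core retains high agreement
  core <- voxelValues(generateSubjectTractMaps(
    syntheticConfig("cohort", subjectJitterMm = 0, seed = 11))[[1]]) == 1
  expect_gte(mean(cnt[core] >= 6L), 0.5)
})

test_that("lesion growth hits the target volume and stays 6-connected", {
  cfg <- syntheticConfig("cohort", seed = 2)
  les <- generateLesionMask(cfg, 12.68, c(-20, -10, 5), seed = 77)
  expect_identical(sum(voxelValues(les)), 1585)   # 12.68 / 0.008
  expect_equal(computeLesionVolume(les), 12.68)

  one <- generateLesionMask(cfg, 0.008, c(-20, -10, 5), seed = 78)
  expect_identical(sum(voxelValues(one)), 1)

  cfgC <- syntheticConfig("compact", seed = 2)
  for (s in 1:3) {
    small <- generateLesionMask(cfgC, 0.8, c(-18, -12, 2), seed = 80 + s)
    expect_true(isSixConnected(voxelValues(small)))
  }
})

test_that("geometry violations raise errors", {
  cfg <- syntheticConfig("compact", seed = 1)
  expect_error(generateLesionMask(cfg, 0.5, c(200, 0, 0), seed = 1),
               "outside the grid")
  expect_error(generateLesionMask(cfg, 1e6, c(-18, -12, 2), seed = 1),
               "geometry error")
  bad <- syntheticConfig("compact",
                         tractCenterline = rbind(c(-30, -34, 0),
                                                 c(-30, 34, 0)),
                         seed = 1)
  expect_error(generateSubjectTractMaps(bad), "exits the grid")
})

test_that("generated cohorts are exactly self-consistent with their volumes", {
  cfg <- syntheticConfig("compact", nPatients = 10, seed = 8)
  st <- generateCohort(cfg)
  for (i in seq_len(10)) {
    les <- st$lesionMasks[[st$cohort$patient_id[i]]]
    expect_identical(st$cohort$af_ll_cc[i],
                     computeLesionLoad(les, st$maps$AF)$load_cc)
    expect_identical(st$cohort$uf_ll_cc[i],
                     computeLesionLoad(les, st$maps$UF)$load_cc)
    expect_identical(st$cohort$lesion_volume_cc[i],
                     computeLesionVolume(les))
  }
  expect_identical(validateCohort(st$cohort), character(0))
})

test_that("noiseless outcomes are an exact function of load and fit with R^2 = 1", {
  cfg <- syntheticConfig("compact", nPatients = 15, seed = 21,
                         outcomeModel = list(
                           cius_per_min = c(beta0 = 45, beta1 = -19,
                                            sigma = 0),
                           words_per_min = c(beta0 = 70, beta1 = -26,
                                             sigma = 0),
                           bnt = c(beta0 = 15, beta1 = -5.5, sigma = 0)))
  st <- generateCohort(cfg)
  expect_equal(st$cohort$cius_per_min,
               pmax(0, 45 - 19 * cubeRoot(st$cohort$af_ll_cc)),
               tolerance = 1e-12)
  fit <- suppressWarnings(  # summary.lm flags the perfect fit
    fitModel(st$cohort, regressionSpec("cius_per_min", "af_ll_cc",
                                       covariates = character())))
  expect_equal(rSquared(fit), 1, tolerance = 1e-9)
  expect_identical(excludedIds(fit), character(0))
})

test_that("well-separated severity regimes are recovered by clustering", {
  cfg <- syntheticConfig("compact", nPatients = 60,
                         severityMixture = 0.4, seed = 31,
                         severeOutcomeShift = -20,
                         outcomeModel = list(
                           cius_per_min = c(beta0 = 45, beta1 = -19,
                                            sigma = 2),
                           words_per_min = c(beta0 = 70, beta1 = -26,
                                             sigma = 6),
                           bnt = c(beta0 = 15, beta1 = -5.5,
                                   sigma = 1.5)))
  st <- generateCohort(cfg)
  part <- twoGroupCluster(st$cohort$cius_per_min, "cius_per_min")
  agree <- mean((severityLabels(part) == "severe") ==
                  st$truth$severe[st$cohort$patient_id])
  expect_gte(max(agree, 1 - agree), 0.95)
})

test_that("a synthetic study round-trips through disk", {
  cfg <- syntheticConfig("compact", nPatients = 4, seed = 13)
  td <- file.path(withr::local_tempdir(), "study")
  st <- writeSyntheticStudy(cfg, td)
  expect_true(file.exists(file.path(td, "cohort.csv")))
  expect_true(file.exists(file.path(td, "truth.json")))
  back <- loadCohort(file.path(td, "cohort.csv"))
  expect_equal(back$af_ll_cc, st$cohort$af_ll_cc, tolerance = 1e-12)
  af <- readProbabilisticMap(file.path(td, "maps", "AF.nii.gz"))
  expect_identical(voxelCounts(af), voxelCounts(st$maps$AF))
  les <- readLesionMask(file.path(td, "lesions", "S01.nii.gz"))
  expect_identical(voxelValues(les), voxelValues(st$lesionMasks$S01))
  expect_error(writeSyntheticStudy(cfg, td), "not empty")
})
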