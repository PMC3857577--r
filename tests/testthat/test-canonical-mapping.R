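test_that("percentile threshold acts on the nonzero value distribution", {
  g <- VoxelGrid(c(2, 2, 1))
  v <- IntensityVolume(array(c(1, 2, 3, 4), c(2, 2, 1)), g)
  # 50th percentile of {1,2,3,4} is 2.5 (linear interpolation): keep 3, 4
  b <- thresholdPercentile(v, 50)
  expect_identical(as.numeric(voxelValues(b)), c(0, 0, 1, 1))

  # zeros are excluded from the distribution entirely
  g2 <- VoxelGrid(c(2, 2, 2))
  v2 <- IntensityVolume(array(c(0, 0, 0, 0, 1, 2, 3, 4), c(2, 2, 2)), g2)
  expect_identical(sum(voxelValues(thresholdPercentile(v2, 50))), 2)
  # near-zero percentile retains every nonzero voxel
  expect_identical(sum(voxelValues(thresholdPercentile(v2, 1e-6))), 4)
  expect_error(thresholdPercentile(
    IntensityVolume(array(0, c(2, 2, 2)), g2), 50), "all-zero")
})

test_that("subject-map aggregation matches a per-voxel tally oracle", {
  g <- tinyGrid()
  maps <- lapply(1:12, function(s) randomBinary(g, 0.3, seed = 100 + s))
  pm <- aggregateSubjectMaps(maps, "AF")
  expect_identical(nSubjects(pm), 12L)
  expect_identical(mapLabel(pm), "AF")

  # independent per-voxel loop over the input masks
  expected <- array(0L, gridShape(g))
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expected[i, j, k] <- sum(vapply(maps,
                                    function(m) voxelValues(m)[i, j, k], 0))
  expect_equal(voxelCounts(pm), expected, ignore_attr = FALSE)
  # conservation: total counts = total input mask volume in voxels
  expect_identical(sum(voxelCounts(pm)),
                   as.integer(sum(vapply(maps,
                                         function(m) sum(voxelValues(m)),
                                         0))))
  expect_true(all(probabilities(pm) >= 0 & probabilities(pm) <= 1))
})

test_that("aggregation degenerate cases and monotonicity", {
  g <- tinyGrid()
  base <- randomBinary(g, 0.4, seed = 7)
  identical12 <- aggregateSubjectMaps(rep(list(base), 12), "AF")
  expect_true(all(voxelCounts(identical12) %in% c(0L, 12L)))
  expect_identical(voxelCounts(identical12) == 12L,
                   voxelValues(base) == 1)

  v1 <- array(0, gridShape(g)); v1[1:10] <- 1
  v2 <- array(0, gridShape(g)); v2[11:20] <- 1
  disjoint <- aggregateSubjectMaps(list(BinaryVolume(v1, g),
                                        BinaryVolume(v2, g)), "d")
  expect_true(all(voxelCounts(disjoint) %in% c(0L, 1L)))
  expect_identical(nSubjects(disjoint), 2L)

  # adding one subject never decreases any voxel count
  maps <- lapply(1:5, function(s) randomBinary(g, 0.3, seed = 40 + s))
  before <- aggregateSubjectMaps(maps, "m")
  after <- aggregateSubjectMaps(c(maps, list(randomBinary(g, 0.3, 99))),
                                "m")
  expect_true(all(voxelCounts(after) >= voxelCounts(before)))

  expect_error(aggregateSubjectMaps(list(), "x"), "nonempty")
  gOther <- VoxelGrid(c(6, 6, 7))
  expect_error(aggregateSubjectMaps(list(base, randomBinary(gOther, 0.3, 1)),
                                    "x"), "grid mismatch")
})

test_that("gray-matter masking zeroes counts outside the mask only", {
  g <- tinyGrid()
  pm <- randomMap(g, 12, seed = 5)
  ones <- BinaryVolume(array(1, gridShape(g)), g)
  zeros <- BinaryVolume(array(0, gridShape(g)), g)
  expect_identical(voxelCounts(maskGrayMatter(pm, ones)), voxelCounts(pm))
  expect_true(all(voxelCounts(maskGrayMatter(pm, zeros)) == 0L))

  half <- array(0, gridShape(g)); half[1:3, , ] <- 1
  masked <- maskGrayMatter(pm, BinaryVolume(half, g))
  for (i in 1:6) for (j in 1:6) for (k in 1:6) {
    want <- if (i <= 3) voxelCounts(pm)[i, j, k] else 0L
    expect_identical(voxelCounts(masked)[i, j, k], want)
  }
  expect_identical(nSubjects(masked), nSubjects(pm))
})

test_that("map combination is a capped probability sum", {
  g <- tinyGrid()
  a <- randomMap(g, 12, seed = 21, label = "AF")
  b <- randomMap(g, 12, seed = 22, label = "fGM")
  zero <- ProbabilisticMap(array(0L, gridShape(g)), g, 12, "z")
  expect_identical(probabilities(combineMaps(a, zero)), probabilities(a))

  full <- ProbabilisticMap(array(12L, gridShape(g)), g, 12, "f")
  expect_true(all(probabilities(combineMaps(full, full)) == 1))

  comb <- combineMaps(a, b)
  expect_identical(mapLabel(comb), "AF+fGM")
  pa <- probabilities(a); pb <- probabilities(b)
  for (i in seq_along(pa))
    expect_equal(probabilities(comb)[i],
                 round(min(1, pa[i] + pb[i]) * 12) / 12)
  # capped combination never exceeds 1 and dominates each component
  # (up to the half-count rounding of the stored integer counts)
  expect_true(all(probabilities(comb) <= 1))
  expect_true(all(probabilities(comb) >= pa - 0.5 / 12 - 1e-9))
  expect_true(all(probabilities(comb) >= pb - 0.5 / 12 - 1e-9))
  expect_error(combineMaps(a, ProbabilisticMap(array(0L, gridShape(g)),
                                               g, 10, "x")),
               "subject counts")
})

test_that("probabilistic maps round-trip through NIfTI plus sidecar", {
  g <- tinyGrid()
  pm <- randomMap(g, 12, seed = 31, label = "AF")
  path <- file.path(withr::local_tempdir(), "af.nii.gz")
  writeProbabilisticMap(pm, path)
  back <- readProbabilisticMap(path)
  expect_identical(voxelCounts(back), voxelCounts(pm))
  expect_identical(nSubjects(back), 12L)
  expect_identical(mapLabel(back), "AF")
})
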