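# shared builders and independent oracles for the test suite

tinyGrid <- function(shape = c(6, 6, 6), spacing = c(2, 2, 2)) {
  VoxelGrid(shape, spacing = spacing)
}

randomIntensity <- function(grid, seed) {
  set.seed(seed)
  IntensityVolume(array(stats::runif(prod(gridShape(grid))),
                        dim = gridShape(grid)), grid)
}

randomBinary <- function(grid, p = 0.3, seed = 1) {
  set.seed(seed)
  BinaryVolume(array(stats::rbinom(prod(gridShape(grid)), 1, p),
                     dim = gridShape(grid)), grid)
}

randomLesion <- function(grid, p = 0.2, seed = 1, id = "pX") {
  b <- randomBinary(grid, p, seed)
  LesionMask(voxelValues(b), grid, id)
}

randomMap <- function(grid, n = 12, seed = 1, label = "AF") {
  set.seed(seed)
  ProbabilisticMap(array(sample(0:n, prod(gridShape(grid)),
                                replace = TRUE),
                         dim = gridShape(grid)), grid, n, label)
}

# naive triple-loop lesion load, the independent oracle for the
# vectorized implementation
bruteForceLoad <- function(lesion, map) {
  les <- voxelValues(lesion)
  cnt <- voxelCounts(map)
  n <- nSubjects(map)
  vvc <- voxelVolumeCc(lesion)
  d <- dim(les)
  total <- 0
  for (i in seq_len(d[1]))
    for (j in seq_len(d[2]))
      for (k in seq_len(d[3]))
        if (les[i, j, k] == 1)
          total <- total + cnt[i, j, k] / n
  total * vvc
}

# pairwise Mann-Whitney AUC with ties counted half, the oracle for the
# trapezoidal ROC area
pairwiseAUC <- function(predictor, severe) {
  xs <- predictor[severe]
  xn <- predictor[!severe]
  tot <- 0
  for (a in xs) tot <- tot + sum(a > xn) + 0.5 * sum(a == xn)
  tot / (length(xs) * length(xn))
}

# 1-D 2-means from both extreme initializations, the oracle for the
# exhaustive within-SS split
kmeansCut <- function(x) {
  k1 <- stats::kmeans(x, centers = c(min(x), max(x)))
  k2 <- stats::kmeans(x, centers = c(max(x), min(x)))
  best <- if (k1$tot.withinss <= k2$tot.withinss) k1 else k2
  max(x[best$cluster == which.min(best$centers)])
}

# 6-connectivity check by breadth-first search over a binary array
isSixConnected <- function(arr) {
  idx <- which(arr == 1, arr.ind = TRUE)
  if (nrow(idx) <= 1) return(TRUE)
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  all_keys <- key(idx)
  seen <- structure(logical(nrow(idx)), names = all_keys)
  queue <- idx[1, , drop = FALSE]
  seen[key(queue)] <- TRUE
  shifts <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                  c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue)) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (s in seq_len(6)) {
      nb <- cur + shifts[s, , drop = FALSE]
      kb <- key(nb)
      if (kb %in% all_keys && !seen[kb]) {
        seen[kb] <- TRUE
        queue <- rbind(queue, nb)
      }
    }
  }
  all(seen)
}
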