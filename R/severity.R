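#' Exact two-group clustering of a one-dimensional score
#'
#' Splits a behavioral score into severe and non-severe groups by
#' exhaustive search over all interval splits of the sorted scores,
#' choosing the split that minimizes the total within-group sum of
#' squares. For one variable and two groups this is the global optimum of
#' the k-means criterion (no seed dependence), and the severe group is the
#' one with lower scores, since lower fluency or naming is worse.
#'
#' @param scores numeric vector of at least 4 scores, not all equal.
#' @param variable name of the measure (for reporting).
#' @return A [SeverityPartition-class] object; its cutoff band is the open
#'   interval (max severe score, min non-severe score).
#' @examples
#' p <- twoGroupCluster(c(0, 1, 2, 10, 11, 12), "toy")
#' cutoffBand(p)  # (2, 10)
#' @export
twoGroupCluster <- function(scores, variable = "score") {
  stopifnot(is.numeric(scores), length(scores) >= 4L,
            all(is.finite(scores)))
  if (diff(range(scores)) == 0)
    stop("degenerate input: all scores are equal, no two-group split exists")
  s <- sort(scores)
  n <- length(s)
  # candidate splits are between distinct adjacent sorted values
  best_ss <- Inf
  best_cut <- NA_real_
  for (k in seq_len(n - 1L)) {
    if (s[k] == s[k + 1L]) next
    lo <- s[seq_len(k)]
    hi <- s[seq.int(k + 1L, n)]
    ss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best_cut <- s[k]
    }
  }
  severe <- scores <= best_cut
  new("SeverityPartition", variable = variable,
      labels = ifelse(severe, "severe", "non_severe"),
      scores = as.numeric(scores),
      cutoffBand = c(max(scores[severe]), min(scores[!severe])),
      nSevere = sum(severe), nNonSevere = sum(!severe))
}

#' Build a severity partition from an explicit score cutoff
#'
#' Labels observations severe when their score is less than or equal to
#' `cutoff`. Used to evaluate reported cutoff bands (the band's lower
#' endpoint is the maximum severe score) alongside the automatic split of
#' [twoGroupCluster()].
#'
#' @param scores numeric score vector.
#' @param cutoff maximum score assigned to the severe group.
#' @param variable measure name.
#' @return A [SeverityPartition-class].
#' @export
severityFromCutoff <- function(scores, cutoff, variable = "score") {
  severe <- scores <= cutoff
  if (!any(severe) || all(severe))
    stop("cutoff ", cutoff, " leaves one group empty for ", variable)
  new("SeverityPartition", variable = variable,
      labels = ifelse(severe, "severe", "non_severe"),
      scores = as.numeric(scores),
      cutoffBand = c(max(scores[severe]), min(scores[!severe])),
      nSevere = sum(severe), nNonSevere = sum(!severe))
}

#' Resubstitution accuracy of a linear discriminant on one variable
#'
#' Fits a linear discriminant (pooled within-group variance, priors
#' proportional to group sizes) to the scores against the partition
#' labels, then classifies the same scores and returns the proportion
#' classified into their own group. This quantifies how cleanly the
#' cluster cutoff separates the score distribution.
#'
#' @param scores numeric vector, same length/order as the partition.
#' @param partition a [SeverityPartition-class].
#' @return Resubstitution accuracy in `[0, 1]`.
#' @export
discriminantAccuracy <- function(scores, partition) {
  stopifnot(is(partition, "SeverityPartition"),
            length(scores) == length(partition@labels))
  grp <- factor(partition@labels, levels = c("severe", "non_severe"))
  if (any(table(grp) == 0L))
    stop("both severity groups must be nonempty for discriminant analysis")
  fit <- MASS::lda(x = data.frame(score = scores), grouping = grp,
                   prior = as.numeric(table(grp)) / length(grp))
  pred <- stats::predict(fit)$class
  mean(pred == grp)
}

#' ROC analysis of a lesion-load (or volume) classifier
#'
#' Evaluates a predictor against a severity partition over all decision
#' thresholds, predicting severe when the predictor is greater than or
#' equal to the threshold (larger load means worse outcome). Candidate
#' thresholds are the midpoints between consecutive distinct predictor
#' values plus one threshold below and one above all values, so every
#' attainable confusion table is visited. The area under the curve is
#' computed by the trapezoidal rule (equal to the normalized Mann-Whitney
#' U statistic with ties counted half). The reported decision threshold
#' maximizes Youden's J = sensitivity + specificity - 1, with ties broken
#' toward higher specificity; sensitivity, specificity and raw accuracy
#' are evaluated at that threshold.
#'
#' @param predictor numeric vector (lesion load in cc, or lesion volume).
#' @param partition a [SeverityPartition-class] of the same length.
#' @return A [RocResult-class] object.
#' @examples
#' coh <- cohortFixture()
#' part <- twoGroupCluster(coh$cius_per_min, "cius_per_min")
#' rocAnalysis(coh$af_ll_cc, part)
#' @export
rocAnalysis <- function(predictor, partition) {
  stopifnot(is(partition, "SeverityPartition"),
            length(predictor) == length(partition@labels),
            all(is.finite(predictor)))
  severe <- partition@labels == "severe"
  if (!any(severe) || all(severe))
    stop("degenerate labels: both severity groups must be nonempty")
  u <- sort(unique(predictor))
  thr <- if (length(u) == 1L) c(u - 1, u + 1)
         else c(u[1] - 1, (u[-1] + u[-length(u)]) / 2,
                u[length(u)] + 1)
  sens <- vapply(thr, function(t) mean(predictor[severe] >= t), 0)
  spec <- vapply(thr, function(t) mean(predictor[!severe] < t), 0)
  fpr <- 1 - spec
  o <- order(fpr, sens)
  aucv <- abs(sum(diff(fpr[o]) *
                  (sens[o][-1] + sens[o][-length(o)]) / 2))
  J <- sens + spec - 1
  cand <- which(J >= max(J) - 1e-12)
  best <- cand[which.max(spec[cand])]
  acc <- mean((predictor >= thr[best]) == severe)
  new("RocResult", auc = aucv, thresholdCc = thr[best],
      sensitivity = sens[best], specificity = spec[best],
      accuracy = acc, nPoints = length(thr),
      curve = data.frame(threshold = thr, sensitivity = sens,
                         specificity = spec))
}

#' Stratify a patient by lesion-load threshold
#'
#' Applies a decision threshold (e.g. the ~4 cc AF lesion-load rule) to a
#' single load value. A load equal to the threshold is called severe: for
#' a screening rule the boundary goes to the worse group.
#'
#' @param loadCc lesion load(s) in cc.
#' @param thresholdCc decision threshold in cc.
#' @return `"severe"` or `"non_severe"` per input value.
#' @examples
#' stratify(9.75, 4)  # severe
#' stratify(0.07, 4)  # non_severe
#' @export
stratify <- function(loadCc, thresholdCc) {
  stopifnot(all(is.finite(loadCc)), is.finite(thresholdCc))
  ifelse(loadCc >= thresholdCc, "severe", "non_severe")
}

#' Severity stratification report for a cohort
#'
#' For each behavioral measure: cluster the scores into two groups,
#' compute the discriminant resubstitution accuracy of the cutoff, and run
#' ROC analyses of the candidate imaging predictors against the severity
#' labels. One row per (measure, predictor).
#'
#' @param cohort a cohort `data.frame`.
#' @param measures behavioral measures to stratify.
#' @param predictors imaging predictor columns to evaluate.
#' @return A `data.frame` mirroring a clinical stratification table:
#'   measure, cutoff band, cluster accuracy (%), predictor, AUC (%),
#'   threshold (cc), sensitivity/specificity/accuracy (%) at threshold.
#' @export
severityReport <- function(cohort,
                           measures = c("cius_per_min", "words_per_min",
                                        "bnt"),
                           predictors = c("af_ll_cc", "fgm_ll_cc",
                                          "af_fgm_ll_cc",
                                          "lesion_volume_cc")) {
  rows <- list()
  for (ms in measures) {
    part <- twoGroupCluster(cohort[[ms]], ms)
    clAcc <- discriminantAccuracy(cohort[[ms]], part)
    for (pd in predictors) {
      rr <- rocAnalysis(cohort[[pd]], part)
      rows[[length(rows) + 1L]] <- data.frame(
        measure = ms,
        cutoff_low = part@cutoffBand[1], cutoff_high = part@cutoffBand[2],
        cluster_accuracy_pct = 100 * clAcc,
        predictor = pd, auc_pct = 100 * rr@auc,
        threshold_cc = rr@thresholdCc,
        sensitivity_pct = 100 * rr@sensitivity,
        specificity_pct = 100 * rr@specificity,
        accuracy_pct = 100 * rr@accuracy,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
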