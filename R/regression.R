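.FLUENCY_OUTCOMES <- c("cius_per_min", "words_per_min")

#' Cube root of a nonnegative volume
#'
#' Lesion loads are volumetric, and their relationship with fluency
#' outcomes is linearized by a cube-root transform of the predictor (the
#' transform also stabilizes variance). Naming scores relate linearly to
#' loads, so naming models leave predictors untransformed.
#'
#' @param x nonnegative numeric vector.
#' @return `x^(1/3)`, with `cubeRoot(0) == 0`.
#' @examples
#' cubeRoot(8)  # 2
#' @export
cubeRoot <- function(x) {
  if (any(x < 0, na.rm = TRUE))
    stop("cubeRoot is defined for nonnegative volumes only")
  x^(1 / 3)
}

#' Specify an outcome regression
#'
#' Describes one ordinary least-squares model of a behavioral outcome on
#' lesion-load (or lesion-volume) predictors plus covariates. With
#' `transform = "auto"` the predictors are cube-root transformed for
#' fluency outcomes (CIUs/min, Words/min) and left untransformed for the
#' BNT naming score. `outlierSd` controls the single studentized-residual
#' outlier pass of [fitModel()]; set it to `Inf` to disable the pass.
#'
#' @param outcome one of `"cius_per_min"`, `"words_per_min"`, `"bnt"`.
#' @param predictors character vector of lesion-load / lesion-volume
#'   column names.
#' @param covariates covariate columns; default age and months post-stroke.
#' @param transform `"auto"`, `"cube_root"` or `"identity"`.
#' @param outlierSd standardized-residual exclusion threshold (default
#'   2.5).
#' @return A list of class `"RegressionSpec"`.
#' @export
regressionSpec <- function(outcome,
                           predictors,
                           covariates = c("age_years",
                                          "months_post_stroke"),
                           transform = c("auto", "cube_root", "identity"),
                           outlierSd = 2.5) {
  outcome <- match.arg(outcome, c(.FLUENCY_OUTCOMES, "bnt"))
  transform <- match.arg(transform)
  if (transform == "auto")
    transform <- if (outcome %in% .FLUENCY_OUTCOMES) "cube_root"
                 else "identity"
  structure(list(outcome = outcome, predictors = predictors,
                 covariates = covariates, transform = transform,
                 outlierSd = outlierSd),
            class = "RegressionSpec")
}

# signed partial correlation of each model term with the outcome,
# controlling all other terms: r = t / sqrt(t^2 + df)
.partialFromFit <- function(fit) {
  s <- summary(fit)$coefficients
  tval <- s[, "t value"]
  r <- sign(tval) * sqrt(tval^2 / (tval^2 + fit$df.residual))
  r[setdiff(rownames(s), "(Intercept)")]
}

#' Fit an outcome-on-lesion-load regression
#'
#' Ordinary least squares of the outcome on the (optionally cube-root
#' transformed) predictors plus covariates. After the initial fit, cases
#' with internally studentized residual exceeding `outlierSd` in magnitude
#' are removed and the model is refit exactly once (no iteration). Partial
#' correlations are computed for every term, controlling all other terms,
#' with the coefficient sign preserved. P-values are two-sided and
#' uncorrected.
#'
#' @param cohort a cohort `data.frame` (see [loadCohort()]).
#' @param spec a [regressionSpec()].
#' @return A [RegressionFit-class] object.
#' @examples
#' fit <- fitModel(cohortFixture(),
#'                 regressionSpec("cius_per_min", "af_ll_cc"))
#' rSquared(fit)
#' @export
fitModel <- function(cohort, spec) {
  stopifnot(inherits(spec, "RegressionSpec"))
  cols <- c(spec$outcome, spec$predictors, spec$covariates)
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols))
    stop("cohort lacks model column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- cohort[, cols, drop = FALSE]
  keep <- stats::complete.cases(df)
  df <- df[keep, , drop = FALSE]
  ids <- as.character(cohort$patient_id[keep])
  if (nrow(df) < 10L)
    stop("too few usable records (", nrow(df), ") to fit a model")
  if (spec$transform == "cube_root")
    for (p in spec$predictors) df[[p]] <- cubeRoot(df[[p]])
  form <- stats::as.formula(paste(
    spec$outcome, "~",
    paste(c(spec$predictors, spec$covariates), collapse = " + ")))
  fit0 <- stats::lm(form, data = df)
  qrank <- fit0$rank
  if (qrank < length(c(spec$predictors, spec$covariates)) + 1L)
    stop("singular design: predictors/covariates are collinear")
  excluded <- character()
  sigma0 <- summary(fit0)$sigma
  if (is.finite(spec$outlierSd) && is.finite(sigma0) && sigma0 > 1e-10) {
    z <- stats::rstandard(fit0)
    drop_idx <- which(abs(z) > spec$outlierSd)
    if (length(drop_idx)) {
      excluded <- ids[drop_idx]
      df <- df[-drop_idx, , drop = FALSE]
      ids <- ids[-drop_idx]
      fit0 <- stats::lm(form, data = df)
    }
  }
  s <- summary(fit0)
  pr <- .partialFromFit(fit0)
  fstat <- s$fstatistic
  pmodel <- if (is.null(fstat)) NA_real_
            else unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE))
  coefs <- data.frame(term = rownames(s$coefficients),
                      estimate = s$coefficients[, "Estimate"],
                      p_value = s$coefficients[, "Pr(>|t|)"],
                      partial_r = c(NA_real_, pr)[
                        match(rownames(s$coefficients),
                              c("(Intercept)", names(pr)))],
                      row.names = NULL, stringsAsFactors = FALSE)
  new("RegressionFit", outcome = spec$outcome,
      predictors = spec$predictors, covariates = spec$covariates,
      transform = spec$transform,
      rSquared = s$r.squared, adjRSquared = s$adj.r.squared,
      pValueModel = pmodel, coefficients = coefs,
      partialR = pr[spec$predictors], nUsed = nrow(df),
      excludedIds = excluded, fit = fit0)
}

#' Compare dorsal and ventral tract lesion loads
#'
#' Multiple regression of an outcome on the dorsal-stream AF lesion load
#' together with the ventral-stream EMC and UF lesion loads, controlling
#' for total lesion volume. Fluency outcomes use cube-root-transformed
#' predictors; naming uses untransformed loads. This comparison model uses
#' all complete cases (no outlier pass): per-predictor partial correlations
#' are its readout, and they are reported controlling for all other loads
#' and lesion size.
#'
#' @param cohort a cohort `data.frame`.
#' @param outcome `"cius_per_min"`, `"words_per_min"` or `"bnt"`.
#' @return A [RegressionFit-class]; `partialR(fit)` holds the signed
#'   partial correlations of the AF, EMC and UF loads.
#' @examples
#' fit <- fitDorsalVentralComparison(cohortFixture(), "cius_per_min")
#' partialR(fit)["af_ll_cc"]
#' @export
fitDorsalVentralComparison <- function(cohort, outcome) {
  # lesion size is volumetric too, so it enters the predictor list and
  # shares the cube-root transform for fluency outcomes
  spec <- regressionSpec(outcome,
                         predictors = c("af_ll_cc", "emc_ll_cc",
                                        "uf_ll_cc", "lesion_volume_cc"),
                         covariates = character(),
                         transform = "auto", outlierSd = Inf)
  fit <- fitModel(cohort, spec)
  fit@predictors <- c("af_ll_cc", "emc_ll_cc", "uf_ll_cc")
  fit@covariates <- "lesion_volume_cc"
  fit@partialR <- fit@partialR[fit@predictors]
  fit
}

#' Tabulate the single-load regression surface
#'
#' Fits one single-predictor model per (outcome, load column) pair with
#' age and months-post-stroke covariates and the standard outlier pass,
#' mirroring the layout of a published regression table: outcome,
#' predictor, R^2, model p-value, and the predictor's partial R.
#'
#' @param cohort a cohort `data.frame`.
#' @param outcomes outcome columns to model.
#' @param loads lesion-load predictor columns.
#' @return A `data.frame` with one row per (outcome, load).
#' @export
regressionTable <- function(cohort,
                            outcomes = c("cius_per_min", "words_per_min",
                                         "bnt"),
                            loads = c("af_ll_cc", "fgm_ll_cc",
                                      "af_fgm_ll_cc")) {
  rows <- list()
  for (oc in outcomes) {
    for (ld in loads) {
      fit <- fitModel(cohort, regressionSpec(oc, ld))
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, predictor = ld, r_squared = fit@rSquared,
        p_value = fit@pValueModel, partial_r = unname(fit@partialR[ld]),
        n_used = fit@nUsed,
        excluded = paste(fit@excludedIds, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
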