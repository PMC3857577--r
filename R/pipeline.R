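#' Configure an end-to-end analysis run
#'
#' A run configuration names either real inputs (a cohort CSV, and
#' optionally directories of canonical maps and lesion masks) or a
#' synthetic study (a [syntheticConfig()]), plus the analysis switches and
#' the output directory. Exactly one of the two input modes must be set.
#' All analysis constants (which outcomes, which load columns, the outlier
#' SD, the cluster/ROC predictors) are surfaced here with their standard
#' defaults rather than hidden in code.
#'
#' @param cohortCsv path to a cohort CSV ([loadCohort()] schema).
#' @param mapsDir directory of canonical probabilistic maps written by
#'   [writeProbabilisticMap()] (optional; lesion loads are recomputed from
#'   imaging only when both `mapsDir` and `lesionsDir` are given).
#' @param lesionsDir directory of NIfTI lesion masks (optional).
#' @param synthetic a [syntheticConfig()], or `NULL` for real inputs.
#' @param outcomes behavioral outcomes to analyse.
#' @param loadColumns lesion-load columns for the regression surface.
#' @param rocPredictors predictor columns compared in stratification.
#' @param outlierSd studentized-residual exclusion threshold.
#' @param outDir output directory.
#' @param seed integer seed (logged; drives synthetic generation).
#' @param force overwrite an existing non-empty output directory.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(cohortCsv = NULL, mapsDir = NULL, lesionsDir = NULL,
                      synthetic = NULL,
                      outcomes = c("cius_per_min", "words_per_min", "bnt"),
                      loadColumns = c("af_ll_cc", "fgm_ll_cc",
                                      "af_fgm_ll_cc"),
                      rocPredictors = c("af_ll_cc", "fgm_ll_cc",
                                        "af_fgm_ll_cc",
                                        "lesion_volume_cc"),
                      outlierSd = 2.5,
                      outDir, seed = 1L, force = FALSE) {
  real <- !is.null(cohortCsv)
  synth <- !is.null(synthetic)
  if (real == synth)
    stop("exactly one of cohortCsv or synthetic must be given")
  if (synth) stopifnot(inherits(synthetic, "SyntheticConfig"))
  structure(list(cohortCsv = cohortCsv, mapsDir = mapsDir,
                 lesionsDir = lesionsDir, synthetic = synthetic,
                 outcomes = outcomes, loadColumns = loadColumns,
                 rocPredictors = rocPredictors, outlierSd = outlierSd,
                 outDir = outDir, seed = as.integer(seed), force = force),
            class = "RunConfig")
}

#' Load a run configuration from YAML or JSON
#'
#' Reads a configuration file whose keys mirror the arguments of
#' [runConfig()]; a `synthetic` block is passed to [syntheticConfig()].
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A `"RunConfig"`.
#' @export
loadRunConfig <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(lst$synthetic))
    lst$synthetic <- do.call(syntheticConfig, lst$synthetic)
  do.call(runConfig, lst)
}

.logLine <- function(log, stage, msg) {
  entry <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                   stage, msg)
  message(entry)
  c(log, entry)
}

#' Run the full lesion-load analysis pipeline
#'
#' Orchestrates maps -> loads -> regressions -> stratification and writes
#' a fixed output layout under the configured directory:
#' \describe{
#'   \item{`loads.csv`}{per-(patient, map) lesion loads - only when imaging
#'     inputs (or a synthetic study) are available; otherwise skipped with
#'     a logged notice.}
#'   \item{`regressions.csv`}{the single-load regression surface plus the
#'     dorsal-ventral comparison rows.}
#'   \item{`stratification.csv`}{cluster cutoffs, discriminant accuracy,
#'     and ROC of each candidate predictor per outcome.}
#'   \item{`roc_points/<outcome>_<predictor>.csv`}{full ROC curves.}
#'   \item{`run.json`}{log: package version, seed, stages, record counts.}
#' }
#' Reruns over a non-empty output directory require `force = TRUE`; with
#' the same configuration the outputs are identical.
#'
#' @param config a [runConfig()].
#' @return Invisibly, a list with the result tables and the log.
#' @export
runFullAnalysis <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  out <- config$outDir
  if (dir.exists(out) && length(dir(out)) && !config$force)
    stop("output directory ", out,
         " is not empty; rerun with force = TRUE")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  loads <- NULL

  if (!is.null(config$synthetic)) {
    log <- .logLine(log, "inputs",
                    sprintf("synthetic study (seed %d)",
                            config$synthetic$seed))
    study <- generateCohort(config$synthetic)
    cohort <- study$cohort
    loads <- batchLesionLoads(study$lesionMasks, unname(study$maps))
  } else {
    cohort <- loadCohort(config$cohortCsv)
    log <- .logLine(log, "inputs",
                    sprintf("cohort %s (%d patients)", config$cohortCsv,
                            nrow(cohort)))
    if (!is.null(config$mapsDir) && !is.null(config$lesionsDir)) {
      maps <- lapply(list.files(config$mapsDir, "\\.nii(\\.gz)?$",
                                full.names = TRUE),
                     readProbabilisticMap)
      lesions <- lapply(list.files(config$lesionsDir, "\\.nii(\\.gz)?$",
                                   full.names = TRUE), readLesionMask)
      loads <- batchLesionLoads(lesions, maps)
      log <- .logLine(log, "loads",
                      sprintf("%d lesion x map loads computed",
                              nrow(loads)))
    } else {
      log <- .logLine(log, "loads",
                      "no imaging inputs; loads.csv skipped, using cohort columns")
    }
  }
  viol <- validateCohort(cohort)
  if (length(viol))
    log <- .logLine(log, "validate",
                    paste(length(viol), "cohort violations:",
                          paste(utils::head(viol, 3), collapse = "; ")))
  else log <- .logLine(log, "validate", "cohort invariants hold")

  if (!is.null(loads))
    utils::write.csv(loads, file.path(out, "loads.csv"),
                     row.names = FALSE)

  reg <- regressionTable(cohort, outcomes = config$outcomes,
                         loads = config$loadColumns)
  dv <- do.call(rbind, lapply(config$outcomes, function(oc) {
    fit <- fitDorsalVentralComparison(cohort, oc)
    data.frame(outcome = oc,
               predictor = paste0("dorsal_ventral:",
                                  names(partialR(fit))),
               r_squared = rSquared(fit), p_value = fit@pValueModel,
               partial_r = unname(partialR(fit)), n_used = fit@nUsed,
               excluded = "", stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(reg, dv), file.path(out, "regressions.csv"),
                   row.names = FALSE)
  log <- .logLine(log, "regressions",
                  sprintf("%d models fitted", nrow(reg) + nrow(dv) / 3))

  strat <- severityReport(cohort, measures = config$outcomes,
                          predictors = config$rocPredictors)
  utils::write.csv(strat, file.path(out, "stratification.csv"),
                   row.names = FALSE)
  dir.create(file.path(out, "roc_points"), showWarnings = FALSE)
  for (ms in config$outcomes) {
    part <- twoGroupCluster(cohort[[ms]], ms)
    for (pd in config$rocPredictors) {
      rr <- rocAnalysis(cohort[[pd]], part)
      utils::write.csv(rocCurve(rr),
                       file.path(out, "roc_points",
                                 paste0(ms, "_", pd, ".csv")),
                       row.names = FALSE)
    }
  }
  log <- .logLine(log, "stratification",
                  sprintf("%d measure x predictor ROC rows", nrow(strat)))

  best <- strat[strat$measure == config$outcomes[1], ]
  log <- .logLine(log, "summary",
                  sprintf("highest AUC for %s: %s (%.1f%%)",
                          config$outcomes[1],
                          best$predictor[which.max(best$auc_pct)],
                          max(best$auc_pct)))
  jsonlite::write_json(
    list(package = "lesionload",
         version = as.character(utils::packageVersion("lesionload")),
         seed = config$seed, log = log),
    file.path(out, "run.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, loads = loads,
                 regressions = rbind(reg, dv), stratification = strat,
                 log = log))
}
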