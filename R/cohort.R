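.REQUIRED_COHORT_COLS <- c(
  "patient_id", "gender", "age_years", "months_post_stroke", "bnt",
  "words_per_min", "cius_per_min", "lesion_volume_cc", "af_ll_cc",
  "fgm_ll_cc", "af_fgm_ll_cc", "emc_ll_cc", "uf_ll_cc")

.OPTIONAL_COHORT_COLS <- c(
  "ravens", "word_discrimination_pct", "commands_pct",
  "word_repetition_pct")

.NUMERIC_COHORT_COLS <- setdiff(.REQUIRED_COHORT_COLS,
                                c("patient_id", "gender"))

#' Load a patient cohort table
#'
#' Reads a cohort CSV (UTF-8, one header row, `"N/A"` as the missing-value
#' token) holding one row per patient: demographics (gender, age, months
#' post-stroke), behavioral outcomes (Words/min, CIUs/min, 15-item BNT
#' naming score 0-15), total lesion volume in cc, and the five lesion-load
#' columns (AF, fGM, combined AF+fGM, EMC, UF) in cc. Optional
#' neuropsychological columns (Raven's matrices, comprehension subtests)
#' may be missing or `N/A`; required columns must parse as numeric.
#'
#' @param path CSV file path.
#' @return A `data.frame`, one row per patient, with `patient_id` as
#'   character.
#' @seealso [cohortFixture()] for the packaged 50-patient reference table,
#'   [validateCohort()] for invariant checking.
#' @export
loadCohort <- function(path) {
  if (!file.exists(path)) stop("cohort file does not exist: ", path)
  raw <- utils::read.csv(path, na.strings = "N/A", stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0L || ncol(raw) <= 1L)
    stop("cohort schema error: ", path, " has no data rows or columns")
  missing_cols <- setdiff(.REQUIRED_COHORT_COLS, names(raw))
  if (length(missing_cols))
    stop("cohort schema error: missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  out <- raw
  for (col in intersect(c(.NUMERIC_COHORT_COLS, .OPTIONAL_COHORT_COLS),
                        names(raw))) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) {
      if (col %in% .NUMERIC_COHORT_COLS)
        stop("cohort parse error: non-numeric value '", raw[[col]][bad[1]],
             "' in required column '", col, "', row ", bad[1])
      v[bad] <- NA_real_
    }
    if (col %in% .NUMERIC_COHORT_COLS && anyNA(v))
      stop("cohort parse error: missing value in required column '", col,
           "', row ", which(is.na(v))[1])
    out[[col]] <- v
  }
  out$patient_id <- as.character(raw$patient_id)
  out
}

#' Packaged 50-patient reference cohort
#'
#' The chronic-aphasia reference cohort shipped with the package
#' (`inst/extdata/reference_cohort.csv`): 50 chronic left-hemisphere stroke
#' patients with fluency (Words/min, CIUs/min), naming (BNT 0-15), lesion
#' volume, and AF/fGM/AF+fGM/EMC/UF lesion loads in cc. All desk-scale
#' statistics in the package documentation are computed from this table.
#'
#' @return The cohort `data.frame` (see [loadCohort()]).
#' @export
cohortFixture <- function() {
  loadCohort(system.file("extdata", "reference_cohort.csv",
                         package = "lesionload", mustWork = TRUE))
}

#' Validate cohort invariants
#'
#' Checks per-patient record rules and returns violation messages rather
#' than erroring, so a whole table can be audited in one pass. Rules:
#' unique patient ids; gender in \{F, M\}; CIUs/min less than or equal to
#' Words/min (a correct information unit is a counted word); BNT in 0..15;
#' nonnegative outcomes and loads; positive lesion volume; AF and fGM
#' lesion loads bounded by the lesion volume. The combined AF+fGM load is
#' deliberately not checked against any function of the AF and fGM columns
#' (capped probability summation makes it sub-additive, and reference
#' tables are not consistently reproducible from their own columns).
#'
#' @param cohort a cohort `data.frame` from [loadCohort()].
#' @return Character vector of violations, empty when all rules hold; each
#'   message names the patient and the rule.
#' @export
validateCohort <- function(cohort) {
  v <- character()
  note <- function(id, rule) sprintf("patient %s: %s", id, rule)
  dup <- cohort$patient_id[duplicated(cohort$patient_id)]
  if (length(dup))
    v <- c(v, sprintf("duplicate patient_id: %s",
                      paste(unique(dup), collapse = ", ")))
  for (i in seq_len(nrow(cohort))) {
    r <- cohort[i, ]
    if (!r$gender %in% c("F", "M"))
      v <- c(v, note(r$patient_id, "gender must be F or M"))
    if (r$cius_per_min > r$words_per_min)
      v <- c(v, note(r$patient_id,
                     "cius_per_min exceeds words_per_min"))
    if (r$bnt < 0 || r$bnt > 15 || r$bnt != round(r$bnt))
      v <- c(v, note(r$patient_id, "bnt must be an integer in 0..15"))
    if (r$lesion_volume_cc <= 0)
      v <- c(v, note(r$patient_id, "lesion_volume_cc must be positive"))
    for (col in c("af_ll_cc", "fgm_ll_cc", "af_fgm_ll_cc", "emc_ll_cc",
                  "uf_ll_cc"))
      if (r[[col]] < 0)
        v <- c(v, note(r$patient_id, paste(col, "is negative")))
    for (col in c("af_ll_cc", "fgm_ll_cc"))
      if (r[[col]] > r$lesion_volume_cc + 1e-9)
        v <- c(v, note(r$patient_id,
                       paste(col, "exceeds lesion_volume_cc")))
    if (r$words_per_min < 0 || r$cius_per_min < 0)
      v <- c(v, note(r$patient_id, "fluency measures must be nonnegative"))
  }
  v
}
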