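#' Patient-level cohort schema
#'
#' A cohort is a tibble with one row per patient carrying the demographic,
#' echocardiographic and laboratory covariates needed by all seven recurrence
#' scores, plus the landmark follow-up outcome. `cohort_columns()` returns the
#' canonical column order used by [read_cohort()] and [write_cohort()].
#'
#' Columns (units in the name where they matter): `id`, `age_years`, `sex`
#' (`"M"`/`"F"`), `bmi_kg_m2`, `af_type` (`"paroxysmal"`, `"persistent"`,
#' `"longstanding_persistent"`), `af_history_years`, `bbb`, `lad_mm`,
#' `lad_index_mm_m2`, `lvef_pct`, `egfr_ml_min` (absolute scale),
#' `egfr_ml_min_1p73m2` (body-surface normalised scale), `chf`,
#' `hypertension`, `diabetes`, `stroke_tia`, `vascular_disease`, `copd`,
#' `smoker`, `metabolic_syndrome`, `eraf`, `followup_months`, `vlraf_event`.
#' Flags are logical in memory and `0`/`1` on disk.
#'
#' @return Character vector of column names.
#' @export
cohort_columns <- function() {
  c("id", "age_years", "sex", "bmi_kg_m2", "af_type", "af_history_years",
    "bbb", "lad_mm", "lad_index_mm_m2", "lvef_pct", "egfr_ml_min",
    "egfr_ml_min_1p73m2", "chf", "hypertension", "diabetes", "stroke_tia",
    "vascular_disease", "copd", "smoker", "metabolic_syndrome", "eraf",
    "followup_months", "vlraf_event")
}

af_types <- function() c("paroxysmal", "persistent", "longstanding_persistent")

flag_columns <- function() {
  c("bbb", "chf", "hypertension", "diabetes", "stroke_tia",
    "vascular_disease", "copd", "smoker", "metabolic_syndrome", "eraf",
    "vlraf_event")
}

#' Validate a patient cohort
#'
#' Checks the schema (all columns present, no extras required), value domains
#' (`sex`, `af_type`, flags), completeness (no missing values anywhere; the
#' scoring functions are complete-case by design) and physiological ranges
#' (positive age/BMI/LA diameter/eGFR, ejection fraction in (0, 100]).
#' Failures are reported with the offending column and, where applicable, the
#' first offending row.
#'
#' @param cohort A data frame following the [cohort_columns()] schema.
#' @param outcome Require the outcome columns (`followup_months`,
#'   `vlraf_event`)? Set `FALSE` to validate covariate-only tables.
#' @return The cohort as a tibble with flags coerced to logical, invisibly
#'   usable in a pipe.
#' @export
validate_cohort <- function(cohort, outcome = TRUE) {
  if (!is.data.frame(cohort)) abort("`cohort` must be a data frame.")
  cohort <- as_tibble(cohort)
  needed <- cohort_columns()
  if (!outcome) needed <- setdiff(needed, c("followup_months", "vlraf_event"))
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (col in needed) {
    bad <- which(is.na(cohort[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("missing value in column '%s' (first at row %d)",
                    col, bad[1]))
    }
  }
  bad_sex <- which(!cohort$sex %in% c("M", "F"))
  if (length(bad_sex) > 0) {
    abort(sprintf("invalid value '%s' in column 'sex' at row %d (expected M or F)",
                  cohort$sex[bad_sex[1]], bad_sex[1]))
  }
  bad_af <- which(!cohort$af_type %in% af_types())
  if (length(bad_af) > 0) {
    abort(sprintf(
      "invalid value '%s' in column 'af_type' at row %d (expected %s)",
      cohort$af_type[bad_af[1]], bad_af[1],
      paste(af_types(), collapse = ", ")))
  }
  flags <- intersect(flag_columns(), needed)
  for (col in flags) {
    v <- cohort[[col]]
    if (is.numeric(v)) {
      bad <- which(!v %in% c(0, 1))
      if (length(bad) > 0) {
        abort(sprintf("invalid value in column '%s' at row %d (expected 0/1)",
                      col, bad[1]))
      }
      cohort[[col]] <- as.logical(v)
    } else if (!is.logical(v)) {
      abort(sprintf("column '%s' must be logical or 0/1", col))
    }
  }
  check_range <- function(col, ok, what) {
    bad <- which(!ok(cohort[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("column '%s' %s violated at row %d (value %s)",
                    col, what, bad[1], format(cohort[[col]][bad[1]])))
    }
  }
  check_range("age_years", function(x) x > 0, "must be > 0")
  check_range("bmi_kg_m2", function(x) x > 0, "must be > 0")
  check_range("lad_mm", function(x) x > 0, "must be > 0")
  check_range("egfr_ml_min", function(x) x > 0, "must be > 0")
  check_range("lvef_pct", function(x) x > 0 & x <= 100, "must be in (0, 100]")
  if (outcome) {
    check_range("followup_months", function(x) x > 0, "must be > 0")
  }
  cohort
}

#' Read or write a cohort CSV
#'
#' `read_cohort()` parses a cohort CSV (flags encoded `0`/`1`), validates it
#' with [validate_cohort()] and returns a tibble; malformed rows are rejected
#' with the row and column named. `write_cohort()` writes the complementary
#' format so that a write/read round trip is the identity.
#'
#' @param path File path.
#' @param cohort A validated cohort tibble.
#' @return `read_cohort()` returns the cohort tibble; `write_cohort()` returns
#'   `cohort` invisibly.
#' @export
read_cohort <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      sex = readr::col_character(),
      af_type = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    abort(sprintf("malformed cohort CSV: row %d, column %d (%s)",
                  prob$row[1], prob$col[1], prob$expected[1]))
  }
  validate_cohort(raw)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  out <- cohort
  for (col in intersect(flag_columns(), names(out))) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out[, cohort_columns()], path, progress = FALSE)
  invisible(cohort)
}

# Internal: require columns for a scorer, naming any missing field.
need_columns <- function(cohort, cols, score) {
  missing_cols <- setdiff(cols, names(cohort))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s score requires missing field(s): %s",
                  score, paste(missing_cols, collapse = ", ")))
  }
  for (col in cols) {
    bad <- which(is.na(cohort[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("%s score: missing value in field '%s' (row %d)",
                    score, col, bad[1]))
    }
  }
  invisible(TRUE)
}
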