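#' Clinical risk scores for AF recurrence
#'
#' Each scorer maps a patient cohort to integer points. All are pure,
#' vectorised functions of the named covariates only; every other column is
#' ignored. Inequality directions and strictness follow the published
#' definitions: the left-atrial thresholds of MB-LATER (>= 47 mm) and APPLE
#' (>= 43 mm) are inclusive, while APPLE age (> 65), ALARMc LA index (> 23),
#' and all BASE-AF2 thresholds (BMI > 28, LA > 40, history > 6 years) are
#' strict.
#'
#' * `score_mb_later()`: male 1, bundle branch block 1, LA diameter >= 47 mm 1,
#'   AF type 0/1/2 (paroxysmal / persistent / long-standing persistent),
#'   early recurrence during the 3-month blanking period 1. Range 0-6.
#' * `score_apple()`: age > 65, non-paroxysmal AF, LA >= 43 mm, LVEF < 50%,
#'   eGFR < 60 ml/min/1.73 m2. Range 0-5.
#' * `score_alarmc()`: non-paroxysmal AF, LA diameter index > 23 mm/m2,
#'   eGFR < 68 ml/min (absolute scale), metabolic syndrome, cardiomyopathy
#'   (LVEF < 50%). Range 0-5.
#' * `score_base_af2()`: BMI > 28 kg/m2, LA > 40 mm, current smoking, early
#'   recurrence, AF history > 6 years, non-paroxysmal AF. Range 0-6.
#' * `score_chads2()`: CHF 1, hypertension 1, age >= 75 1, diabetes 1,
#'   stroke/TIA 2. Range 0-6.
#' * `score_cha2ds2_vasc()`: CHF 1, hypertension 1, age >= 75 2, diabetes 1,
#'   stroke/TIA 2, vascular disease 1, age 65-74 1, female sex 1. Range 0-9.
#' * `score_hatch()`: hypertension 1, age > 75 1, stroke/TIA 2, COPD 1,
#'   CHF 2. Range 0-7.
#'
#' The two eGFR fields are deliberately separate: ALARMc thresholds absolute
#' eGFR (ml/min) while APPLE thresholds the body-surface normalised scale
#' (ml/min/1.73 m2); no conversion is attempted inside a scorer. Likewise the
#' LA diameter index is a stored field, not derived from `lad_mm`.
#'
#' Missing fields or missing values are rejected with the field named; there
#' is no imputation.
#'
#' @param cohort A data frame following the cohort schema (see
#'   [cohort_columns()]); outcome columns are not required.
#' @param components Keep the per-component point columns alongside the
#'   total? If `FALSE` (default) only `id` and the total are returned.
#' @return A tibble with `id`, optionally one integer column per component,
#'   and an integer `total` column named after the score.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_candidates = 20), seed = 1)
#' score_mb_later(cohort, components = TRUE)
#' score_all(cohort)
#' @name scores
NULL

score_tibble <- function(cohort, score, parts, components) {
  total <- Reduce(`+`, parts)
  out <- tibble(id = as.character(cohort$id))
  if (components) {
    for (nm in names(parts)) out[[nm]] <- as.integer(parts[[nm]])
  }
  out[[score]] <- as.integer(total)
  out
}

npaf_flag <- function(cohort) {
  cohort$af_type %in% c("persistent", "longstanding_persistent")
}

#' @rdname scores
#' @export
score_mb_later <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "sex", "bbb", "lad_mm", "af_type", "eraf"),
               "MB-LATER")
  parts <- list(
    male = cohort$sex == "M",
    bbb = cohort$bbb,
    la_ge_47 = cohort$lad_mm >= 47,
    af_type = c(paroxysmal = 0L, persistent = 1L,
                longstanding_persistent = 2L)[cohort$af_type],
    eraf = cohort$eraf
  )
  score_tibble(cohort, "mb_later", parts, components)
}

#' @rdname scores
#' @export
score_apple <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "age_years", "af_type", "lad_mm", "lvef_pct",
                         "egfr_ml_min_1p73m2"), "APPLE")
  parts <- list(
    age_gt_65 = cohort$age_years > 65,
    npaf = npaf_flag(cohort),
    la_ge_43 = cohort$lad_mm >= 43,
    lvef_lt_50 = cohort$lvef_pct < 50,
    egfr_lt_60 = cohort$egfr_ml_min_1p73m2 < 60
  )
  score_tibble(cohort, "apple", parts, components)
}

#' @rdname scores
#' @export
score_alarmc <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "af_type", "lad_index_mm_m2", "egfr_ml_min",
                         "metabolic_syndrome", "lvef_pct"), "ALARMc")
  parts <- list(
    npaf = npaf_flag(cohort),
    la_index_gt_23 = cohort$lad_index_mm_m2 > 23,
    egfr_lt_68 = cohort$egfr_ml_min < 68,
    metabolic_syndrome = cohort$metabolic_syndrome,
    cardiomyopathy = cohort$lvef_pct < 50
  )
  score_tibble(cohort, "alarmc", parts, components)
}

#' @rdname scores
#' @export
score_base_af2 <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "bmi_kg_m2", "lad_mm", "smoker", "eraf",
                         "af_history_years", "af_type"), "BASE-AF2")
  parts <- list(
    bmi_gt_28 = cohort$bmi_kg_m2 > 28,
    la_gt_40 = cohort$lad_mm > 40,
    smoker = cohort$smoker,
    eraf = cohort$eraf,
    history_gt_6 = cohort$af_history_years > 6,
    npaf = npaf_flag(cohort)
  )
  score_tibble(cohort, "base_af2", parts, components)
}

#' @rdname scores
#' @export
score_chads2 <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "chf", "hypertension", "age_years", "diabetes",
                         "stroke_tia"), "CHADS2")
  parts <- list(
    chf = cohort$chf,
    hypertension = cohort$hypertension,
    age_ge_75 = cohort$age_years >= 75,
    diabetes = cohort$diabetes,
    stroke_tia = 2L * cohort$stroke_tia
  )
  score_tibble(cohort, "chads2", parts, components)
}

#' @rdname scores
#' @export
score_cha2ds2_vasc <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "chf", "hypertension", "age_years", "diabetes",
                         "stroke_tia", "vascular_disease", "sex"),
               "CHA2DS2-VASc")
  parts <- list(
    chf = cohort$chf,
    hypertension = cohort$hypertension,
    age_ge_75 = 2L * (cohort$age_years >= 75),
    diabetes = cohort$diabetes,
    stroke_tia = 2L * cohort$stroke_tia,
    vascular_disease = cohort$vascular_disease,
    age_65_74 = cohort$age_years >= 65 & cohort$age_years < 75,
    female = cohort$sex == "F"
  )
  score_tibble(cohort, "cha2ds2_vasc", parts, components)
}

#' @rdname scores
#' @export
score_hatch <- function(cohort, components = FALSE) {
  need_columns(cohort, c("id", "hypertension", "age_years", "stroke_tia",
                         "copd", "chf"), "HATCH")
  parts <- list(
    hypertension = cohort$hypertension,
    age_gt_75 = cohort$age_years > 75,
    stroke_tia = 2L * cohort$stroke_tia,
    copd = cohort$copd,
    chf = 2L * cohort$chf
  )
  score_tibble(cohort, "hatch", parts, components)
}

#' Names and ranges of the implemented scores
#'
#' @return A tibble with one row per score: machine name, display label,
#'   minimum and maximum attainable total.
#' @export
score_catalog <- function() {
  tibble(
    score = c("mb_later", "apple", "alarmc", "base_af2", "chads2",
              "cha2ds2_vasc", "hatch"),
    label = c("MB-LATER", "APPLE", "ALARMc", "BASE-AF2", "CHADS2",
              "CHA2DS2-VASc", "HATCH"),
    min = 0L,
    max = c(6L, 5L, 5L, 6L, 6L, 9L, 7L)
  )
}

#' Score a cohort with every implemented system
#'
#' @inheritParams scores
#' @param scores Character vector of score machine names (see
#'   [score_catalog()]); defaults to all seven.
#' @return A tibble with `id` and one integer total column per score.
#' @export
score_all <- function(cohort, scores = score_catalog()$score) {
  scorers <- list(
    mb_later = score_mb_later, apple = score_apple, alarmc = score_alarmc,
    base_af2 = score_base_af2, chads2 = score_chads2,
    cha2ds2_vasc = score_cha2ds2_vasc, hatch = score_hatch
  )
  unknown <- setdiff(scores, names(scorers))
  if (length(unknown) > 0) {
    abort(paste0("unknown score(s): ", paste(unknown, collapse = ", ")))
  }
  out <- tibble(id = as.character(cohort$id))
  for (s in scores) out <- dplyr::left_join(out, scorers[[s]](cohort), by = "id")
  out
}
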