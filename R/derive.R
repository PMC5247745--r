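#' Default candidate predictors for score derivation
#'
#' The candidate list mirrors the baseline clinical variables screened in
#' the derivation analysis and available in the cohort schema: binary
#' comorbidity/demographic flags (including non-paroxysmal AF derived from
#' `af_type`) and the continuous covariates that are dichotomized at a
#' ROC-derived cutoff before entering a score. Procedural covariates are out
#' of scope for the simulator, so the `clinical` allow-list column is `TRUE`
#' throughout; user-supplied catalogs can mark non-clinical candidates
#' `FALSE` to exclude them from score assembly.
#'
#' @return A tibble with columns `variable`, `type` (`"binary"` or
#'   `"continuous"`), `clinical`.
#' @export
candidate_catalog <- function() {
  tibble(
    variable = c("male", "npaf", "bbb", "chf", "hypertension", "diabetes",
                 "stroke_tia", "vascular_disease", "copd", "smoker",
                 "metabolic_syndrome", "eraf",
                 "age_years", "bmi_kg_m2", "af_history_years", "lvef_pct",
                 "lad_mm", "lad_index_mm_m2", "egfr_ml_min"),
    type = c(rep("binary", 12), rep("continuous", 7)),
    clinical = TRUE
  )
}

candidate_values <- function(cohort, variable) {
  switch(variable,
         male = as.numeric(cohort$sex == "M"),
         npaf = as.numeric(npaf_flag(cohort)),
         {
           if (!variable %in% names(cohort)) {
             abort(sprintf("candidate '%s' is not a cohort column", variable))
           }
           as.numeric(cohort[[variable]])
         })
}

#' Univariate Cox screen of candidate predictors
#'
#' Screens each candidate with a univariate Cox proportional-hazards fit.
#' Continuous candidates are screened twice: on the continuous scale, and
#' after dichotomization at their Youden-optimal cutoff (direction taken
#' from the sign of the continuous coefficient: an indicator of high values
#' when the coefficient is positive, of low values otherwise). A candidate
#' is selected when it is on the clinical allow-list and its usable form
#' (binary, or dichotomized for continuous variables) has a Wald p-value
#' below `p_threshold`.
#'
#' @param cohort A validated cohort with outcome columns.
#' @param candidates A candidate table as from [candidate_catalog()].
#' @param p_threshold Selection threshold on the Wald p-value (default 0.05).
#' @return An object of class `derivation_screen`: a tibble with one row per
#'   screened form (`variable`, `form`, `cutoff`, `direction`, `hr`,
#'   `conf_low`, `conf_high`, `p_value`, `converged`, `clinical`,
#'   `selected`), carrying the threshold as an attribute.
#' @export
screen_candidates <- function(cohort, candidates = candidate_catalog(),
                              p_threshold = 0.05) {
  cohort <- validate_cohort(cohort)
  if (nrow(candidates) == 0) abort("candidate list is empty")
  if (sum(cohort$vlraf_event) == 0) abort("no events in cohort: cannot screen")
  rows <- list()
  for (k in seq_len(nrow(candidates))) {
    v <- candidates$variable[k]
    x <- candidate_values(cohort, v)
    fit_row <- function(xv, form, cutoff = NA_real_, direction = NA_character_) {
      fit <- tryCatch(cox_engine(xv, cohort$followup_months,
                                 cohort$vlraf_event),
                      error = function(e) NULL)
      if (is.null(fit)) {
        return(tibble(variable = v, form = form, cutoff = cutoff,
                      direction = direction, hr = NA_real_,
                      conf_low = NA_real_, conf_high = NA_real_,
                      p_value = NA_real_, converged = FALSE,
                      clinical = candidates$clinical[k]))
      }
      tibble(variable = v, form = form, cutoff = cutoff,
             direction = direction, hr = fit$hr, conf_low = fit$conf_low,
             conf_high = fit$conf_high, p_value = fit$p_value,
             converged = fit$converged, clinical = candidates$clinical[k])
    }
    if (candidates$type[k] == "binary") {
      rows[[length(rows) + 1]] <- fit_row(x, "binary")
    } else {
      cont <- fit_row(x, "continuous")
      rows[[length(rows) + 1]] <- cont
      sgn <- if (!is.na(cont$hr) && cont$hr < 1) -1 else 1
      yc <- youden_cutoff(tibble(s = sgn * x, y = cohort$vlraf_event),
                          .data$s, .data$y)
      cutoff <- sgn * yc$cutoff
      xd <- if (sgn > 0) as.numeric(x >= cutoff) else as.numeric(x <= cutoff)
      if (length(unique(xd)) < 2) next
      rows[[length(rows) + 1]] <-
        fit_row(xd, "dichotomized", cutoff = cutoff,
                direction = if (sgn > 0) ">=" else "<=")
    }
  }
  out <- dplyr::bind_rows(rows)
  usable <- out$form %in% c("binary", "dichotomized")
  out$selected <- usable & out$clinical & out$converged &
    !is.na(out$p_value) & out$p_value < p_threshold
  structure(out, class = c("derivation_screen", class(out)),
            p_threshold = p_threshold)
}

#' Assemble a point score from a screening result
#'
#' Builds an additive integer score from the selected candidates: one point
#' per selected binary component, with the AF-type component upgraded to an
#' ordinal 0/1/2 assignment (paroxysmal / persistent / long-standing
#' persistent) when non-paroxysmal AF is among the selected variables,
#' following the convention of the derived score. Continuous candidates
#' enter through their dichotomized indicator at the screened cutoff.
#'
#' @param screen A [screen_candidates()] result.
#' @return An object of class `score_definition`: a tibble with `component`,
#'   `variable`, `type` (`"binary"`, `"threshold"`, `"af_type"`), `cutoff`,
#'   `direction`, `points` (maximum points of the component); total maximum
#'   as attribute `max_points`.
#' @export
assemble_score <- function(screen) {
  stopifnot(inherits(screen, "derivation_screen"))
  sel <- screen[screen$selected, , drop = FALSE]
  if (nrow(sel) == 0) abort("no variables selected: cannot assemble a score")
  comp <- list()
  for (k in seq_len(nrow(sel))) {
    v <- sel$variable[k]
    if (v == "npaf") {
      comp[[length(comp) + 1]] <- tibble(
        component = "af_type", variable = "af_type", type = "af_type",
        cutoff = NA_real_, direction = NA_character_, points = 2L)
    } else if (sel$form[k] == "dichotomized") {
      comp[[length(comp) + 1]] <- tibble(
        component = sprintf("%s %s %.4g", v, sel$direction[k], sel$cutoff[k]),
        variable = v, type = "threshold", cutoff = sel$cutoff[k],
        direction = sel$direction[k], points = 1L)
    } else {
      comp[[length(comp) + 1]] <- tibble(
        component = v, variable = v, type = "binary", cutoff = NA_real_,
        direction = NA_character_, points = 1L)
    }
  }
  def <- dplyr::bind_rows(comp)
  structure(def, class = c("score_definition", class(def)),
            max_points = sum(def$points))
}

#' Apply an assembled score definition to a cohort
#'
#' @param cohort A cohort tibble.
#' @param definition A [assemble_score()] result.
#' @return A tibble with `id` and the integer `total`.
#' @export
apply_score_definition <- function(cohort, definition) {
  stopifnot(inherits(definition, "score_definition"))
  total <- rep(0L, nrow(cohort))
  for (k in seq_len(nrow(definition))) {
    total <- total + switch(
      definition$type[k],
      af_type = c(paroxysmal = 0L, persistent = 1L,
                  longstanding_persistent = 2L)[cohort$af_type],
      binary = as.integer(candidate_values(cohort, definition$variable[k])),
      threshold = {
        x <- candidate_values(cohort, definition$variable[k])
        if (definition$direction[k] == ">=") {
          as.integer(x >= definition$cutoff[k])
        } else {
          as.integer(x <= definition$cutoff[k])
        }
      })
  }
  tibble(id = as.character(cohort$id), total = as.integer(unname(total)))
}
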