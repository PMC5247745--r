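#' Configure the synthetic cohort generator
#'
#' Builds the configuration for a seeded simulation of an ablation cohort:
#' covariate marginals matching the derivation study's baseline table, an
#' exponential (optionally Weibull) proportional-hazards recurrence process
#' driven by the MB-LATER components, administrative censoring uniform over
#' the follow-up window, and the landmark selection flow (3-month blanking
#' period, exclusion of late recurrences between 3 and 12 months, inclusion
#' only beyond the 12-month landmark).
#'
#' Default marginals: 63.9% male, 4.4% bundle branch block, AF type
#' proportions 92/32/9 out of 133 (paroxysmal / persistent / long-standing
#' persistent), 18.8% early recurrence, LA diameter Normal(40.2, 5.2) mm, and
#' the remaining comorbidity prevalences and continuous moments of the study
#' cohort. Default log hazard ratios are the logs of the univariate hazard
#' ratios of the five MB-LATER components: male 3.37, BBB 6.08, LA >= 47 mm
#' 4.27, non-paroxysmal AF 6.63, early recurrence 3.00. The default baseline
#' rate (0.00115 events/month for a zero-score patient, counted from the end
#' of the blanking period) is calibrated so that the selected cohort
#' experiences very late recurrence in about 15% of patients, and the default
#' candidate count (150) yields about 133 selected patients.
#'
#' @param n_candidates Number of patients drawn before the selection flow.
#' @param seed Default seed used by [simulate_cohort()] when none is given.
#' @param marginals Named list of covariate marginals; see defaults in the
#'   function signature. Prevalences must lie in \[0, 1\]. Continuous entries
#'   are `c(mean, sd)` pairs (plus truncation bounds where given).
#' @param log_hr Named numeric vector of log hazard ratios for the five
#'   MB-LATER component indicators (`male`, `bbb`, `la_ge_47`, `npaf`,
#'   `eraf`).
#' @param baseline_rate Events per month for a patient with all components
#'   absent.
#' @param weibull_shape Shape of the Weibull recurrence hazard; `1` (default)
#'   gives the constant-hazard exponential model.
#' @param followup_min,followup_max Administrative censoring window in months
#'   since ablation; `followup_min` must exceed `landmark_months`.
#' @param blanking_months Blanking period length (months).
#' @param landmark_months Landmark defining very late recurrence (months).
#' @param correlation Optional correlation matrix (Gaussian copula) across a
#'   subset of the covariates named in `marginals`; `NULL` (default) samples
#'   all covariates independently.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_candidates = 150,
                          seed = 1L,
                          marginals = list(),
                          log_hr = c(male = log(3.37), bbb = log(6.08),
                                     la_ge_47 = log(4.27), npaf = log(6.63),
                                     eraf = log(3.00)),
                          baseline_rate = 0.00115,
                          weibull_shape = 1,
                          followup_min = 13,
                          followup_max = 48,
                          blanking_months = 3,
                          landmark_months = 12,
                          correlation = NULL) {
  defaults <- list(
    male = 0.639, bbb = 0.044,
    af_type = c(paroxysmal = 92, persistent = 32,
                longstanding_persistent = 9) / 133,
    eraf = 0.188, chf = 0.135, hypertension = 0.511, diabetes = 0.098,
    stroke_tia = 0.075, vascular_disease = 0.053, copd = 0.030,
    smoker = 0.150, metabolic_syndrome = 0.353,
    age = c(mean = 56.9, sd = 11.8, min = 18, max = 75),
    bmi = c(mean = 27.5, sd = 4.1, min = 15, max = 50),
    af_history = c(mean = 7.2, sd = 6.9, min = 0.5, max = 40),
    lad = c(mean = 40.2, sd = 5.2, min = 25, max = 60),
    lvef = c(mean = 60.5, sd = 8.1, min = 20, max = 80),
    egfr = c(mean = 81.8, sd = 20.4, min = 15, max = 160),
    bsa = c(mean = 1.95, sd = 0.2, min = 1.3, max = 2.6)
  )
  unknown <- setdiff(names(marginals), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown marginal(s): ", paste(unknown, collapse = ", ")))
  }
  marginals <- utils::modifyList(defaults, marginals)
  prev <- c(marginals[c("male", "bbb", "eraf", "chf", "hypertension",
                        "diabetes", "stroke_tia", "vascular_disease", "copd",
                        "smoker", "metabolic_syndrome")],
            as.list(marginals$af_type))
  bad <- names(prev)[!vapply(prev, function(p)
    is.numeric(p) && length(p) == 1 && p >= 0 && p <= 1, logical(1))]
  if (length(bad) > 0) {
    abort(paste0("prevalence out of [0, 1] for: ", paste(bad, collapse = ", ")))
  }
  if (abs(sum(marginals$af_type) - 1) > 1e-8) {
    abort("af_type proportions must sum to 1")
  }
  if (n_candidates < 0) abort("n_candidates must be >= 0")
  if (followup_min <= landmark_months) {
    abort("followup_min must exceed landmark_months")
  }
  if (baseline_rate <= 0) abort("baseline_rate must be > 0")
  if (weibull_shape <= 0) abort("weibull_shape must be > 0")
  expected_hr <- c("male", "bbb", "la_ge_47", "npaf", "eraf")
  if (!setequal(names(log_hr), expected_hr)) {
    abort(paste0("log_hr must be named: ", paste(expected_hr, collapse = ", ")))
  }
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || nrow(correlation) != ncol(correlation) ||
        is.null(rownames(correlation)) ||
        !identical(rownames(correlation), colnames(correlation))) {
      abort("correlation must be a square named matrix")
    }
    if (any(!rownames(correlation) %in% setdiff(names(defaults), "af_type"))) {
      abort("correlation names must be covariate marginal names (not af_type)")
    }
  }
  structure(
    list(n_candidates = as.integer(n_candidates), seed = as.integer(seed),
         marginals = marginals, log_hr = log_hr[expected_hr],
         baseline_rate = baseline_rate, weibull_shape = weibull_shape,
         followup_min = followup_min, followup_max = followup_max,
         blanking_months = blanking_months,
         landmark_months = landmark_months, correlation = correlation),
    class = "cohort_config")
}

# Truncated-normal draw via inverse CDF; u is Uniform(0,1).
rtnorm_u <- function(u, par) {
  lo <- pnorm(par[["min"]], par[["mean"]], par[["sd"]])
  hi <- pnorm(par[["max"]], par[["mean"]], par[["sd"]])
  qnorm(lo + u * (hi - lo), par[["mean"]], par[["sd"]])
}

#' Draw candidate patients with latent recurrence times
#'
#' Samples `n_candidates` covariate vectors from the configured marginals
#' (independently, or through a Gaussian copula when a correlation matrix is
#' configured), then draws each patient's latent recurrence time from the
#' proportional-hazards model whose linear predictor is the sum of the
#' configured log hazard ratios over the patient's MB-LATER component
#' indicators. Time is counted from the end of the blanking period; the
#' returned `latent_months` column is on the months-since-ablation scale. An
#' administrative censoring time (`censor_months`, uniform over the follow-up
#' window) is drawn here too, so that [apply_selection_flow()] is
#' deterministic.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to the seed stored in `config`. All
#'   randomness flows from this one seed and the caller's RNG state is left
#'   untouched.
#' @return A tibble of candidates: the covariate columns of the cohort schema
#'   plus `latent_months` and `censor_months`.
#' @export
simulate_candidates <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_candidates
  m <- config$marginals
  cont <- c("age", "bmi", "af_history", "lad", "lvef", "egfr", "bsa")
  bin <- c("male", "bbb", "eraf", "chf", "hypertension", "diabetes",
           "stroke_tia", "vascular_disease", "copd", "smoker",
           "metabolic_syndrome")
  withr::with_seed(seed, {
    # Uniform deviates per covariate; the copula correlates them if requested.
    u <- matrix(runif(n * (length(cont) + length(bin))), nrow = n,
                ncol = length(cont) + length(bin),
                dimnames = list(NULL, c(cont, bin)))
    if (!is.null(config$correlation) && n > 0) {
      vars <- rownames(config$correlation)
      z <- matrix(qnorm(u[, vars, drop = FALSE]), nrow = n)
      ch <- chol(config$correlation)
      # re-whiten then correlate: u columns are already independent
      u[, vars] <- pnorm(z %*% ch)
    }
    draw_bin <- function(nm) u[, nm] < m[[nm]]
    cand <- tibble(
      id = if (n > 0) sprintf("P%04d", seq_len(n)) else character(0),
      age_years = rtnorm_u(u[, "age"], m$age),
      sex = ifelse(draw_bin("male"), "M", "F"),
      bmi_kg_m2 = rtnorm_u(u[, "bmi"], m$bmi),
      af_type = if (n > 0) sample(af_types(), n, replace = TRUE,
                                  prob = m$af_type[af_types()])
                else character(0),
      af_history_years = rtnorm_u(u[, "af_history"], m$af_history),
      bbb = draw_bin("bbb"),
      lad_mm = rtnorm_u(u[, "lad"], m$lad),
      lvef_pct = rtnorm_u(u[, "lvef"], m$lvef),
      egfr_ml_min = rtnorm_u(u[, "egfr"], m$egfr),
      chf = draw_bin("chf"),
      hypertension = draw_bin("hypertension"),
      diabetes = draw_bin("diabetes"),
      stroke_tia = draw_bin("stroke_tia"),
      vascular_disease = draw_bin("vascular_disease"),
      copd = draw_bin("copd"),
      smoker = draw_bin("smoker"),
      metabolic_syndrome = draw_bin("metabolic_syndrome"),
      eraf = draw_bin("eraf")
    )
    bsa <- rtnorm_u(u[, "bsa"], m$bsa)
    cand$lad_index_mm_m2 <- cand$lad_mm / bsa
    cand$egfr_ml_min_1p73m2 <- cand$egfr_ml_min * 1.73 / bsa
    lp <- config$log_hr[["male"]] * (cand$sex == "M") +
      config$log_hr[["bbb"]] * cand$bbb +
      config$log_hr[["la_ge_47"]] * (cand$lad_mm >= 47) +
      config$log_hr[["npaf"]] * (cand$af_type != "paroxysmal") +
      config$log_hr[["eraf"]] * cand$eraf
    rate <- config$baseline_rate * exp(lp)
    # Weibull PH: cumulative hazard rate * exp(lp) * t^shape
    t_latent <- (rexp(n) / rate)^(1 / config$weibull_shape)
    cand$latent_months <- config$blanking_months + t_latent
    cand$censor_months <- runif(n, config$followup_min, config$followup_max)
    cand
  })
}

#' Apply the landmark selection flow
#'
#' Reproduces the study's inclusion flow: candidates whose latent recurrence
#' falls after the blanking period but at or before the 12-month landmark
#' (late recurrence, LRAF) are excluded; recurrences inside the blanking
#' period never exclude (early recurrence is a covariate, not an endpoint).
#' Survivors receive `followup_months = min(latent, censoring)` and the very
#' late recurrence indicator `vlraf_event`. All emitted event times exceed
#' the landmark by construction.
#'
#' @param candidates Output of [simulate_candidates()].
#' @param config The same [cohort_config()].
#' @return A validated cohort tibble (schema of [cohort_columns()]).
#' @export
apply_selection_flow <- function(candidates, config) {
  stopifnot(inherits(config, "cohort_config"))
  need <- c("latent_months", "censor_months")
  if (!all(need %in% names(candidates))) {
    abort("candidates must carry latent_months and censor_months")
  }
  keep <- candidates$latent_months > config$landmark_months
  cohort <- candidates[keep, , drop = FALSE]
  cohort$followup_months <- pmin(cohort$latent_months, cohort$censor_months)
  cohort$vlraf_event <- cohort$latent_months <= cohort$censor_months
  cohort <- cohort[, cohort_columns()]
  if (nrow(cohort) == 0) return(as_tibble(cohort))
  validate_cohort(cohort)
}

#' Simulate a selected ablation cohort
#'
#' Convenience wrapper: [simulate_candidates()] followed by
#' [apply_selection_flow()].
#'
#' @inheritParams simulate_candidates
#' @return A validated cohort tibble.
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_candidates = 200), seed = 7)
#' mean(cohort$vlraf_event)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = config$seed) {
  apply_selection_flow(simulate_candidates(config, seed = seed), config)
}
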