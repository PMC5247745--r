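# Fixture builder: a cohort of healthy-baseline patients with overrides.
make_cohort <- function(n = 1, ...) {
  base <- tibble::tibble(
    id = sprintf("T%03d", seq_len(n)),
    age_years = 50, sex = "F", bmi_kg_m2 = 25, af_type = "paroxysmal",
    af_history_years = 3, bbb = FALSE, lad_mm = 40, lad_index_mm_m2 = 20,
    lvef_pct = 60, egfr_ml_min = 90, egfr_ml_min_1p73m2 = 90,
    chf = FALSE, hypertension = FALSE, diabetes = FALSE, stroke_tia = FALSE,
    vascular_disease = FALSE, copd = FALSE, smoker = FALSE,
    metabolic_syndrome = FALSE, eraf = FALSE,
    followup_months = 24, vlraf_event = FALSE
  )
  overrides <- list(...)
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  base
}

# Independent product-limit oracle: redistribute-to-the-right. Each censored
# subject's probability mass is passed on, in time order, to all subjects
# observed strictly later; survival at an event time is one minus the event
# mass at or before it.
km_rttr <- function(time, event) {
  n <- length(time)
  ord <- order(time, !event)
  t <- time[ord]
  e <- as.logical(event)[ord]
  w <- rep(1 / n, n)
  for (i in seq_len(n)) {
    if (!e[i]) {
      later <- which(t > t[i])
      if (length(later) > 0) {
        w[later] <- w[later] + w[i] / length(later)
        w[i] <- 0
      }
    }
  }
  ts <- sort(unique(t[e]))
  surv <- vapply(ts, function(u) 1 - sum(w[e & t <= u]), numeric(1))
  list(time = ts, surv = surv)
}

# Brute-force AUC: average pairwise indicator over all event/non-event
# pairs, ties counted one half.
auc_brute <- function(score, label) {
  label <- as.logical(label)
  x <- score[label]
  y <- score[!label]
  ps <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(ps)
}

# Independent Efron partial log-likelihood (naive loops) and its
# grid-search maximizer.
efron_loglik <- function(beta, x, t, d) {
  d <- as.logical(d)
  ll <- 0
  for (u in unique(t[d])) {
    D <- which(t == u & d)
    R <- which(t >= u)
    dd <- length(D)
    wR <- sum(exp(beta * x[R]))
    wD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(dd) - 1) ll <- ll - log(wR - (l / dd) * wD)
  }
  ll
}

cox_grid_beta <- function(x, t, d, lower = -8, upper = 8) {
  stats::optimize(efron_loglik, c(lower, upper), x = x, t = t, d = d,
                  maximum = TRUE, tol = 1e-10)$maximum
}

# Exhaustive Youden search over every observed threshold.
youden_brute <- function(score, label) {
  label <- as.logical(label)
  cand <- sort(unique(score))
  j <- vapply(cand, function(c) {
    mean(score[label] >= c) + mean(score[!label] < c) - 1
  }, numeric(1))
  list(cutoff = cand[which(j == max(j))[1]], youden = max(j))
}
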