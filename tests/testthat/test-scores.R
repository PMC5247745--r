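# Exhaustive component-sum oracle: enumerate every combination of component
# levels, build the matching patient, and compare the scorer's total against
# the independently computed sum of points.
enum_check <- function(scorer, total_col, comps) {
  idx <- do.call(expand.grid, lapply(comps, function(cp) seq_along(cp$pts)))
  for (r in seq_len(nrow(idx))) {
    ov <- list()
    expected <- 0L
    for (j in seq_along(comps)) {
      lev <- idx[r, j]
      ov <- utils::modifyList(ov, comps[[j]]$levels[[lev]])
      expected <- expected + comps[[j]]$pts[lev]
    }
    p <- do.call(make_cohort, c(list(n = 1), ov))
    res <- scorer(p)
    expect_identical(res[[total_col]], as.integer(expected))
  }
}

bin2 <- function(off, on, pts = c(0L, 1L)) {
  list(levels = list(off, on), pts = pts)
}

test_that("MB-LATER points match the published definition on worked examples", {
  expect_identical(score_mb_later(make_cohort())$mb_later, 0L)
  expect_identical(
    score_mb_later(make_cohort(sex = "M", lad_mm = 45))$mb_later, 1L)
  expect_identical(
    score_mb_later(make_cohort(sex = "M", bbb = TRUE, lad_mm = 48,
                               af_type = "longstanding_persistent",
                               eraf = TRUE))$mb_later, 6L)
  # LA threshold is inclusive at exactly 47 mm
  expect_identical(
    score_mb_later(make_cohort(lad_mm = 47, af_type = "persistent",
                               eraf = TRUE))$mb_later, 3L)
  br <- score_mb_later(make_cohort(sex = "M", af_type = "persistent"),
                       components = TRUE)
  expect_identical(br$male, 1L)
  expect_identical(br$af_type, 1L)
  expect_identical(br$mb_later, br$male + br$bbb + br$la_ge_47 +
                     br$af_type + br$eraf)
})

test_that("APPLE respects its strict and inclusive boundaries", {
  expect_identical(score_apple(make_cohort())$apple, 0L)
  expect_identical(
    score_apple(make_cohort(age_years = 70, af_type = "persistent",
                            lad_mm = 43, lvef_pct = 45,
                            egfr_ml_min_1p73m2 = 55))$apple, 5L)
  # boundary audit: age 65 (strict >), lvef 50 (strict <), egfr 60 (strict <)
  # do not score; lad 44 (>= 43) does
  expect_identical(
    score_apple(make_cohort(age_years = 65, lad_mm = 44, lvef_pct = 50,
                            egfr_ml_min_1p73m2 = 60))$apple, 1L)
  # long-standing persistent counts as non-paroxysmal
  expect_identical(
    score_apple(make_cohort(af_type = "longstanding_persistent"))$apple, 1L)
})

test_that("ALARMc respects its strict boundaries", {
  expect_identical(score_alarmc(make_cohort())$alarmc, 0L)
  expect_identical(
    score_alarmc(make_cohort(af_type = "persistent", lad_index_mm_m2 = 24,
                             egfr_ml_min = 60, metabolic_syndrome = TRUE,
                             lvef_pct = 45))$alarmc, 5L)
  expect_identical(
    score_alarmc(make_cohort(lad_index_mm_m2 = 23))$alarmc, 0L)
})

test_that("BASE-AF2 thresholds are all strict", {
  expect_identical(score_base_af2(make_cohort())$base_af2, 0L)
  expect_identical(
    score_base_af2(make_cohort(bmi_kg_m2 = 29, lad_mm = 41, smoker = TRUE,
                               eraf = TRUE, af_history_years = 7,
                               af_type = "persistent"))$base_af2, 6L)
  expect_identical(
    score_base_af2(make_cohort(bmi_kg_m2 = 28, lad_mm = 40,
                               af_history_years = 6))$base_af2, 0L)
})

test_that("CHADS2, CHA2DS2-VASc and HATCH follow their standard definitions", {
  healthy40 <- make_cohort(age_years = 40, sex = "M")
  expect_identical(score_chads2(healthy40)$chads2, 0L)
  expect_identical(score_cha2ds2_vasc(healthy40)$cha2ds2_vasc, 0L)
  expect_identical(score_hatch(healthy40)$hatch, 0L)
  expect_identical(
    score_chads2(make_cohort(age_years = 80, stroke_tia = TRUE))$chads2, 3L)
  expect_identical(
    score_cha2ds2_vasc(make_cohort(sex = "F", age_years = 76,
                                   hypertension = TRUE))$cha2ds2_vasc, 4L)
  expect_identical(
    score_hatch(make_cohort(age_years = 80, stroke_tia = TRUE,
                            chf = TRUE))$hatch, 5L)
  # age band boundaries: 65-74 scores 1 on CHA2DS2-VASc only; 75 scores the
  # elderly point on CHADS2/CHA2DS2-VASc but not HATCH (strict > 75)
  expect_identical(
    score_cha2ds2_vasc(make_cohort(age_years = 65, sex = "M"))$cha2ds2_vasc, 1L)
  expect_identical(score_chads2(make_cohort(age_years = 75))$chads2, 1L)
  expect_identical(score_hatch(make_cohort(age_years = 75))$hatch, 0L)
})

test_that("every score equals its brute-force component sum over all combinations", {
  enum_check(score_mb_later, "mb_later", list(
    male = bin2(list(sex = "F"), list(sex = "M")),
    bbb = bin2(list(bbb = FALSE), list(bbb = TRUE)),
    la = bin2(list(lad_mm = 40), list(lad_mm = 48)),
    af = list(levels = list(list(af_type = "paroxysmal"),
                            list(af_type = "persistent"),
                            list(af_type = "longstanding_persistent")),
              pts = c(0L, 1L, 2L)),
    eraf = bin2(list(eraf = FALSE), list(eraf = TRUE))
  ))
  enum_check(score_apple, "apple", list(
    age = bin2(list(age_years = 50), list(age_years = 70)),
    af = bin2(list(af_type = "paroxysmal"), list(af_type = "persistent")),
    la = bin2(list(lad_mm = 40), list(lad_mm = 43)),
    ef = bin2(list(lvef_pct = 60), list(lvef_pct = 45)),
    egfr = bin2(list(egfr_ml_min_1p73m2 = 90), list(egfr_ml_min_1p73m2 = 55))
  ))
  enum_check(score_alarmc, "alarmc", list(
    af = bin2(list(af_type = "paroxysmal"), list(af_type = "persistent")),
    lai = bin2(list(lad_index_mm_m2 = 20), list(lad_index_mm_m2 = 24)),
    egfr = bin2(list(egfr_ml_min = 90), list(egfr_ml_min = 60)),
    mes = bin2(list(metabolic_syndrome = FALSE), list(metabolic_syndrome = TRUE)),
    cm = bin2(list(lvef_pct = 60), list(lvef_pct = 45))
  ))
  enum_check(score_base_af2, "base_af2", list(
    bmi = bin2(list(bmi_kg_m2 = 25), list(bmi_kg_m2 = 29)),
    la = bin2(list(lad_mm = 40), list(lad_mm = 41)),
    smoke = bin2(list(smoker = FALSE), list(smoker = TRUE)),
    eraf = bin2(list(eraf = FALSE), list(eraf = TRUE)),
    hist = bin2(list(af_history_years = 3), list(af_history_years = 7)),
    af = bin2(list(af_type = "paroxysmal"), list(af_type = "persistent"))
  ))
  enum_check(score_chads2, "chads2", list(
    chf = bin2(list(chf = FALSE), list(chf = TRUE)),
    htn = bin2(list(hypertension = FALSE), list(hypertension = TRUE)),
    age = bin2(list(age_years = 50), list(age_years = 80)),
    dm = bin2(list(diabetes = FALSE), list(diabetes = TRUE)),
    stroke = bin2(list(stroke_tia = FALSE), list(stroke_tia = TRUE), c(0L, 2L))
  ))
  enum_check(score_cha2ds2_vasc, "cha2ds2_vasc", list(
    chf = bin2(list(chf = FALSE), list(chf = TRUE)),
    htn = bin2(list(hypertension = FALSE), list(hypertension = TRUE)),
    age = list(levels = list(list(age_years = 50), list(age_years = 70),
                             list(age_years = 80)),
               pts = c(0L, 1L, 2L)),
    dm = bin2(list(diabetes = FALSE), list(diabetes = TRUE)),
    stroke = bin2(list(stroke_tia = FALSE), list(stroke_tia = TRUE), c(0L, 2L)),
    vasc = bin2(list(vascular_disease = FALSE), list(vascular_disease = TRUE)),
    sex = bin2(list(sex = "M"), list(sex = "F"))
  ))
  enum_check(score_hatch, "hatch", list(
    htn = bin2(list(hypertension = FALSE), list(hypertension = TRUE)),
    age = bin2(list(age_years = 50), list(age_years = 80)),
    stroke = bin2(list(stroke_tia = FALSE), list(stroke_tia = TRUE), c(0L, 2L)),
    copd = bin2(list(copd = FALSE), list(copd = TRUE)),
    chf = bin2(list(chf = FALSE), list(chf = TRUE), c(0L, 2L))
  ))
})

test_that("totals stay within documented ranges and are monotone in components", {
  cat <- score_catalog()
  maxed <- make_cohort(sex = "M", age_years = 80, bmi_kg_m2 = 30,
                       af_type = "longstanding_persistent",
                       af_history_years = 10, bbb = TRUE, lad_mm = 50,
                       lad_index_mm_m2 = 25, lvef_pct = 40, egfr_ml_min = 50,
                       egfr_ml_min_1p73m2 = 50, chf = TRUE,
                       hypertension = TRUE, diabetes = TRUE,
                       stroke_tia = TRUE, vascular_disease = TRUE,
                       copd = TRUE, smoker = TRUE, metabolic_syndrome = TRUE,
                       eraf = TRUE)
  # a maximal patient: age 80 loses the female point of CHA2DS2-VASc, so
  # check documented maxima per score where this patient attains them
  tot <- score_all(maxed)
  expect_identical(tot$mb_later, 6L)
  expect_identical(tot$apple, 5L)
  expect_identical(tot$alarmc, 5L)
  expect_identical(tot$base_af2, 6L)
  expect_identical(tot$chads2, 6L)
  expect_identical(tot$hatch, 7L)
  maxed_f <- make_cohort(sex = "F", age_years = 80, chf = TRUE,
                         hypertension = TRUE, diabetes = TRUE,
                         stroke_tia = TRUE, vascular_disease = TRUE)
  expect_identical(score_cha2ds2_vasc(maxed_f)$cha2ds2_vasc, 9L)
  # monotonicity: turning any single flag on never lowers any total
  base <- make_cohort()
  base_tot <- as.integer(score_all(base)[, cat$score])
  for (flag in c("bbb", "chf", "hypertension", "diabetes", "stroke_tia",
                 "vascular_disease", "copd", "smoker", "metabolic_syndrome",
                 "eraf")) {
    ov <- list(n = 1)
    ov[[flag]] <- TRUE
    flipped <- as.integer(score_all(do.call(make_cohort, ov))[, cat$score])
    expect_true(all(flipped >= base_tot))
  }
})

test_that("totals ignore fields outside the score's definition", {
  p <- make_cohort(sex = "M", af_type = "persistent", eraf = TRUE)
  q <- dplyr::mutate(p, egfr_ml_min = 40, egfr_ml_min_1p73m2 = 40,
                     bmi_kg_m2 = 35, chf = TRUE, diabetes = TRUE)
  expect_identical(score_mb_later(p)$mb_later, score_mb_later(q)$mb_later)
  r <- dplyr::mutate(p, lad_mm = 55, bbb = TRUE, eraf = FALSE)
  expect_identical(score_chads2(p)$chads2, score_chads2(r)$chads2)
})

test_that("missing fields and missing values are rejected with the field named", {
  p <- make_cohort()
  expect_error(score_mb_later(dplyr::select(p, -"lad_mm")), "lad_mm")
  p$eraf <- NA
  expect_error(score_mb_later(p), "eraf")
})
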