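test_that("AUC handles separation, pure ties and the midrank example", {
  perfect <- tibble::tibble(s = c(1, 2, 9, 10), y = c(0, 0, 1, 1))
  expect_equal(eval_auc(perfect, s, y)$auc, 1)
  ties <- tibble::tibble(s = rep(3, 6), y = c(0, 0, 0, 1, 1, 1))
  expect_equal(eval_auc(ties, s, y)$auc, 0.5)
  mid <- tibble::tibble(s = c(1, 2, 2, 3), y = c(0, 0, 1, 1))
  expect_equal(eval_auc(mid, s, y)$auc, 0.875)
  expect_error(eval_auc(tibble::tibble(s = 1:3, y = c(1, 1, 1)), s, y),
               "both classes")
})

test_that("AUC equals the brute-force pairwise probability on small instances", {
  withr::local_seed(81)
  for (rep in 1:80) {
    n <- sample(3:12, 1)
    s <- sample(0:4, n, replace = TRUE)
    y <- stats::runif(n) < 0.5
    if (all(y) || !any(y)) next
    expect_equal(eval_auc(tibble::tibble(s = s, y = y), s, y)$auc,
                 auc_brute(s, y), tolerance = 1e-12)
  }
})

test_that("DeLong interval agrees with pROC", {
  skip_if_not_installed("pROC")
  withr::local_seed(91)
  s <- c(stats::rnorm(40), stats::rnorm(25, 1))
  y <- rep(c(FALSE, TRUE), c(40, 25))
  ours <- eval_auc(tibble::tibble(s = s, y = y), s, y)
  ref <- suppressMessages(pROC::ci.auc(pROC::roc(y, s), method = "delong"))
  expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ours$conf_low, as.numeric(ref[1]), tolerance = 1e-10)
  expect_equal(ours$conf_high, as.numeric(ref[3]), tolerance = 1e-10)
})

test_that("Youden cutoff matches exhaustive search and flags non-discrimination", {
  sep <- tibble::tibble(s = c(1, 2, 5, 6), y = c(0, 0, 1, 1))
  expect_equal(youden_cutoff(sep, s, y)$cutoff, 5)
  expect_equal(youden_cutoff(sep, s, y)$sensitivity, 100)
  withr::local_seed(101)
  for (rep in 1:40) {
    s <- sample(0:6, 8, replace = TRUE)
    y <- stats::runif(8) < 0.5
    if (all(y) || !any(y)) next
    got <- youden_cutoff(tibble::tibble(s = s, y = y), s, y)
    want <- youden_brute(s, y)
    expect_equal(got$cutoff, want$cutoff)
    expect_equal(got$youden, want$youden, tolerance = 1e-12)
  }
  anti <- tibble::tibble(s = c(5, 6, 1, 2), y = c(0, 0, 1, 1))
  expect_false(youden_cutoff(anti, s, y)$discriminates)
  # ties in J break toward the lower (more sensitive) threshold
  tie <- tibble::tibble(s = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
  expect_equal(youden_cutoff(tie, s, y)$cutoff, 3)
})

test_that("confusion rates are exact percents with undefined cells as NA", {
  expect_equal(unlist(confusion_metrics(tp = 4, fp = 0, fn = 0, tn = 6)),
               c(sensitivity = 100, specificity = 100, ppv = 100, npv = 100))
  expect_equal(unlist(confusion_metrics(tp = 1, fp = 1, fn = 1, tn = 1)),
               c(sensitivity = 50, specificity = 50, ppv = 50, npv = 50))
  no_pos <- confusion_metrics(tp = 0, fp = 0, fn = 3, tn = 7)
  expect_true(is.na(no_pos$ppv))
  expect_equal(no_pos$sensitivity, 0)
  expect_error(confusion_metrics(tp = -1, fp = 0, fn = 0, tn = 1),
               "non-negative")
})

test_that("risk mapping recovers closed-form logits and falls back under separation", {
  flat <- tibble::tibble(s = c(1, 2, 1, 2), y = c(0, 1, 1, 0))
  fit <- fit_risk_mapping(flat, s, y)
  expect_equal(fit$slope, 0, tolerance = 1e-8)
  expect_equal(predict(fit, 5), 0.5, tolerance = 1e-8)
  # two-point score: the saturated logistic equals the stratum event rates
  two <- tibble::tibble(s = rep(c(0, 1), c(10, 10)),
                        y = rep(c(0, 1, 0, 1), c(8, 2, 4, 6)))
  fit2 <- fit_risk_mapping(two, s, y)
  expect_equal(predict(fit2, c(0, 1)), c(0.2, 0.6), tolerance = 1e-6)
  expect_equal(fit2$slope, qlogis(0.6) - qlogis(0.2), tolerance = 1e-6)
  sep <- tibble::tibble(s = c(0, 0, 5, 5), y = c(0, 0, 1, 1))
  fit3 <- fit_risk_mapping(sep, s, y)
  expect_true(fit3$separated)
  expect_identical(fit3$method, "empirical")
  p <- predict(fit3, c(0, 5))
  expect_true(all(p > 0 & p < 1) && p[2] > p[1])
})

test_that("IDI matches hand arithmetic and is antisymmetric", {
  d <- tibble::tibble(new = c(0.6, 0.8, 0.2, 0.2),
                      old = c(0.5, 0.5, 0.3, 0.3),
                      y = c(1, 1, 0, 0))
  expect_equal(idi(d, new, old, y)$idi, 0.3)
  expect_equal(idi(d, old, new, y)$idi, -0.3)
  expect_equal(idi(d, new, new, y)$idi, 0)
  expect_error(idi(dplyr::mutate(d, new = new + 1), new, old, y), "(0, 1)")
})

test_that("continuous NRI counts movers correctly", {
  d <- tibble::tibble(new = c(0.6, 0.8, 0.2, 0.2),
                      old = c(0.5, 0.5, 0.3, 0.3),
                      y = c(1, 1, 0, 0))
  # every event up, every non-event down: the maximum of 200%
  expect_equal(nri(d, new, old, y)$nri, 200)
  expect_equal(nri(d, new, new, y)$nri, 0)
  expect_equal(nri(d, old, new, y)$nri, -200)
  # brute-force counting on a mixed toy
  m <- tibble::tibble(new = c(0.6, 0.4, 0.5, 0.2, 0.35, 0.3),
                      old = c(0.5, 0.5, 0.5, 0.3, 0.30, 0.3),
                      y = c(1, 1, 1, 0, 0, 0))
  # events: up, down, tie -> net 0; non-events: down, up, tie -> net 0
  got <- nri(m, new, old, y)
  expect_equal(got$event_component, 0)
  expect_equal(got$nonevent_component, 0)
  expect_equal(got$nri, 0)
})

test_that("categorical NRI only counts category changes", {
  d <- tibble::tibble(new = c(0.32, 0.28, 0.08, 0.08),
                      old = c(0.28, 0.22, 0.09, 0.11),
                      y = c(1, 1, 0, 0))
  # cut at 0.1 and 0.3: event 1 crosses up, non-event 2 crosses down,
  # the others move within a category
  got <- nri(d, new, old, y, cutpoints = c(0.1, 0.3))
  expect_equal(got$event_component, 50)
  expect_equal(got$nonevent_component, 50)
  expect_equal(got$nri, 100)
})

test_that("net benefit reproduces closed forms and stays below prevalence", {
  d <- tibble::tibble(r = c(0.9, 0.6, 0.1, 0.3, 0.3, 0.1, 0.1, 0.1, 0.1, 0.1),
                      y = c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  # at pt = 0.2: the model flags 2 TP and 2 FP out of 10
  dc <- decision_curve(d, r, y, thresholds = 0.2)
  nb <- dc$net_benefit[dc$strategy == "model"]
  expect_equal(nb, 0.2 - 0.05)
  expect_equal(dc$net_benefit[dc$strategy == "treat_none"], 0)
  prev <- 0.3
  expect_equal(dc$net_benefit[dc$strategy == "treat_all"],
               prev - (1 - prev) * 0.2 / 0.8)
  # treat-all tends to prevalence as the threshold vanishes
  tiny <- decision_curve(d, r, y, thresholds = 1e-9)
  expect_equal(tiny$net_benefit[tiny$strategy == "treat_all"], prev,
               tolerance = 1e-6)
  # no model exceeds the prevalence bound; a perfect model attains it below
  # the smallest event risk
  grid <- decision_curve(d, r, y, thresholds = seq(0.05, 0.5, 0.05))
  expect_true(all(grid$net_benefit <= prev + 1e-12))
  perf <- tibble::tibble(r = ifelse(d$y == 1, 0.999, 0.001), y = d$y)
  pc <- decision_curve(perf, r, y, thresholds = c(0.1, 0.5, 0.9))
  expect_equal(pc$net_benefit[pc$strategy == "model"], rep(prev, 3))
  expect_error(decision_curve(d, r, y, thresholds = 1), "\\(0, 1\\)")
})
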