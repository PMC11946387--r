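test_that("the curve enumerates confusion counts exactly on a worked example", {
  probs <- c(0.9, 0.8, 0.7, 0.2)
  labels <- c(1, 1, 0, 0)
  curve <- ppv_sensitivity_curve(probs, labels)
  expect_equal(curve$threshold, c(0, 0.2, 0.7, 0.8, 0.9))
  # at t = 0 everyone is predicted positive: sensitivity 100, PPV = prevalence
  expect_equal(curve$sensitivity_pct[1], 100)
  expect_equal(curve$ppv_pct[1], 50)
  # t = 0.8 keeps the two true pCRs only
  r <- curve[curve$threshold == 0.8, ]
  expect_equal(r$ppv_pct, 100)
  expect_equal(r$sensitivity_pct, 100)
  # t = 0.7 admits one false positive
  r <- curve[curve$threshold == 0.7, ]
  expect_equal(r$ppv_pct, 200 / 3)
  expect_equal(r$sensitivity_pct, 100)
  expect_true(all(curve$ppv_pct == 100 * curve$tp / (curve$tp + curve$fp),
                  na.rm = TRUE))
  expect_true(all(curve$sensitivity_pct == 100 * curve$tp / (curve$tp + curve$fn)))
  expect_error(ppv_sensitivity_curve(c(0.5, 1.5), c(1, 0)), "\\[0, 1\\]")
  expect_error(ppv_sensitivity_curve(c(0.5, 0.6), c(1, 1)), "both outcome")
})

test_that("sensitivity is non-increasing and PPV at zero equals prevalence on random cohorts", {
  set.seed(55)
  for (i in 1:50) {
    s <- random_scored_cohort(sample(10:300, 1), runif(1, 0.1, 0.9))
    curve <- ppv_sensitivity_curve(s$probs, s$labels)
    expect_true(all(diff(curve$sensitivity_pct) <= 1e-12))
    expect_equal(curve$ppv_pct[1], 100 * mean(s$labels))
    expect_equal(curve$sensitivity_pct[1], 100)
  }
})

test_that("threshold selection agrees with a brute-force scan on 200 random cohorts", {
  set.seed(99)
  for (i in 1:200) {
    s <- random_scored_cohort(sample(8:300, 1), runif(1, 0.05, 0.95))
    curve <- ppv_sensitivity_curve(s$probs, s$labels)
    level <- sample(c(30, 50, 70, 90, 99), 1)
    sel <- select_threshold(curve, level)
    bf <- brute_force_select(s$probs, s$labels, level)
    expect_equal(sel$threshold, bf$threshold, info = paste("case", i))
    expect_equal(sel$sensitivity_pct, bf$sensitivity, info = paste("case", i))
    if (is.finite(sel$threshold)) {
      expect_gte(sel$ppv_pct, level)
      # maximal sensitivity among all qualifying thresholds
      ok <- !is.na(curve$ppv_pct) & curve$ppv_pct >= level
      expect_equal(sel$sensitivity_pct, max(curve$sensitivity_pct[ok]))
    }
  }
})

test_that("raising the PPV level never raises the selected sensitivity", {
  set.seed(123)
  for (i in 1:30) {
    s <- random_scored_cohort(150, runif(1, 0.2, 0.7))
    curve <- ppv_sensitivity_curve(s$probs, s$labels)
    sens <- vapply(c(30, 50, 70, 90),
                   function(l) select_threshold(curve, l)$sensitivity_pct, 1)
    expect_true(all(diff(sens) <= 1e-12))
  }
})

test_that("threshold selection reproduces the clinical table semantics", {
  # prevalence 66%: the level-50 constraint is already met by treating
  # everyone as predicted pCR, so the chosen threshold is 0 at sensitivity 100
  set.seed(41)
  labels <- rep(c(TRUE, FALSE), times = c(66, 34))
  probs <- runif(100, 0.2, 0.8)
  sel <- select_threshold(ppv_sensitivity_curve(probs, labels), 50)
  expect_equal(sel$threshold, 0)
  expect_equal(sel$sensitivity_pct, 100)
  expect_equal(sel$ppv_pct, 66)
  # a curve whose maximum PPV is 67% cannot attain level 70: +Inf, sensitivity 0
  probs2 <- c(0.24, 0.24, 0.24, 0.1, 0.1)
  labels2 <- c(1, 1, 0, 0, 0)          # best PPV = 2/3
  sel2 <- select_threshold(ppv_sensitivity_curve(probs2, labels2), 70)
  expect_identical(sel2$threshold, Inf)
  expect_equal(sel2$sensitivity_pct, 0)
  expect_true(is.na(sel2$ppv_pct))
  # level 100 with a uniquely top-scored positive record
  probs3 <- c(0.9, 0.6, 0.5, 0.3)
  labels3 <- c(1, 0, 1, 0)
  sel3 <- select_threshold(ppv_sensitivity_curve(probs3, labels3), 100)
  expect_equal(sel3$threshold, 0.9)
  expect_error(select_threshold(ppv_sensitivity_curve(probs3, labels3), 0),
               "\\(0, 100\\]")
})

test_that("Wald sensitivity interval matches plug-in arithmetic and clips", {
  expect_equal(sensitivity_ci(66, 66), c(100, 100))
  ci <- sensitivity_ci(13, 66)
  expect_equal(ci, c(10.10186, 29.29208), tolerance = 1e-5)
  expect_equal(round(ci), c(10, 29))
  expect_equal(sensitivity_ci(50, 100), c(40.2, 59.8), tolerance = 1e-3)
  expect_equal(sensitivity_ci(0, 20)[1], 0)
  expect_error(sensitivity_ci(5, 0), "positive")
  expect_error(sensitivity_ci(7, 5), "\\[0, n\\]")
})

test_that("the decision rule applies threshold and biopsy confirmation", {
  curve <- ppv_sensitivity_curve(c(0.24, 0.62, 0.1, 0.7), c(1, 1, 0, 0))
  sel50 <- list(ppv_level = 50, threshold = 0.24, ppv_pct = 50,
                sensitivity_pct = 100, ci_lo_pct = 0, ci_hi_pct = 100,
                tp = 2L, fp = 2L, fn = 0L, tn = 0L)
  class(sel50) <- "threshold_selection"
  sel70 <- sel50; sel70$threshold <- 0.62; sel70$ppv_level <- 70
  inf_sel <- sel50; inf_sel$threshold <- Inf
  # probability below the subtype threshold: continue NAC
  expect_equal(recommend(0.18, sel50), "continue_NAC")
  # probability above the threshold, biopsy clear: proceed to surgery early
  expect_equal(recommend(0.70, sel70, biopsy_no_invasive = TRUE),
               "early_surgery_recommended")
  expect_equal(recommend(0.70, sel70), "early_surgery_candidate")
  expect_equal(recommend(0.70, sel70, biopsy_no_invasive = FALSE),
               "early_surgery_candidate")
  # an unattainable (+Inf) threshold never sends anyone to surgery
  expect_equal(recommend(0.99, inf_sel), "continue_NAC")
})

test_that("threshold and implication reports lay out one row per scope and level", {
  set.seed(61)
  labels <- runif(120) < 0.5
  labels[1] <- TRUE; labels[2] <- FALSE
  probs <- plogis(rnorm(120, ifelse(labels, 1, -1)))
  curve <- ppv_sensitivity_curve(probs, labels)
  sels <- lapply(c(50, 70, 90), function(l) select_threshold(curve, l))
  names(sels) <- c("50", "70", "90")
  rep <- threshold_report(list(full = sels, "TN" = sels))
  expect_equal(nrow(rep), 6)
  expect_equal(names(rep),
               c("cohort", "ppv_level", "threshold", "sensitivity",
                 "ci_lo", "ci_hi"))
  imp <- implication_report(list("TN" = sels[["50"]]))
  expect_equal(imp$pct_pcr_early_surgery + imp$pct_pcr_continue_nac, 100)
  # +Inf serializes as the literal string
  inf_curve <- ppv_sensitivity_curve(c(0.3, 0.3, 0.3, 0.2), c(1, 0, 0, 0))
  inf_sel <- select_threshold(inf_curve, 90)
  rep2 <- threshold_report(list(x = list("90" = inf_sel)))
  expect_identical(rep2$threshold, "+Inf")
})
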