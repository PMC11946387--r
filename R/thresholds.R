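#' PPV and sensitivity versus probability threshold
#'
#' For the classification rule "predicted pCR iff probability >= t",
#' evaluated at every distinct predicted probability plus t = 0, computes
#' the confusion counts, PPV = TP/(TP+FP) and sensitivity = TP/(TP+FN)
#' (both in percent). At t = 0 every patient is predicted positive, so
#' sensitivity is 100% and PPV equals the pCR prevalence.
#'
#' @param probabilities Predicted pCR probabilities in \[0, 1\].
#' @param labels True outcomes (logical or 0/1).
#' @return data.frame of class `threshold_curve` with columns `threshold`,
#'   `tp`, `fp`, `fn`, `tn`, `ppv_pct`, `sensitivity_pct`, ordered by
#'   increasing threshold.
#' @export
ppv_sensitivity_curve <- function(probabilities, labels) {
  labels <- as.logical(labels)
  stopifnot(length(probabilities) == length(labels),
            !anyNA(probabilities), !anyNA(labels))
  if (any(probabilities < 0 | probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (all(labels) || !any(labels))
    stop("both outcome classes must be present", call. = FALSE)
  thr <- sort(unique(c(0, probabilities)))
  rows <- lapply(thr, function(t) {
    pred <- probabilities >= t
    tp <- sum(pred & labels); fp <- sum(pred & !labels)
    fn <- sum(!pred & labels); tn <- sum(!pred & !labels)
    data.frame(threshold = t, tp = tp, fp = fp, fn = fn, tn = tn,
               ppv_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
               sensitivity_pct = 100 * tp / (tp + fn))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Select a probability threshold at a minimum PPV level
#'
#' Returns the smallest candidate threshold whose PPV meets or exceeds
#' `ppv_level`; because sensitivity is non-increasing in the threshold,
#' this maximizes sensitivity subject to the PPV constraint. When no
#' candidate attains the level, the threshold is the `+Inf` sentinel: no
#' patient is ever predicted pCR and sensitivity is 0.
#'
#' @param curve A `threshold_curve` from [ppv_sensitivity_curve()].
#' @param ppv_level Required minimum PPV in percent, in (0, 100].
#' @return List of class `threshold_selection`: `ppv_level`, `threshold`
#'   (probability or `Inf`), `ppv_pct` (achieved, `NA` when `Inf`),
#'   `sensitivity_pct`, `ci_lo_pct`, `ci_hi_pct` (95% Wald), and the
#'   confusion counts at the chosen threshold.
#' @export
select_threshold <- function(curve, ppv_level) {
  stopifnot(inherits(curve, "threshold_curve"))
  if (length(ppv_level) != 1L || !is.finite(ppv_level) ||
      ppv_level <= 0 || ppv_level > 100)
    stop("ppv_level must lie in (0, 100]", call. = FALSE)
  n_pos <- curve$tp[1] + curve$fn[1]
  ok <- which(!is.na(curve$ppv_pct) & curve$ppv_pct >= ppv_level)
  if (!length(ok)) {
    sel <- list(ppv_level = ppv_level, threshold = Inf, ppv_pct = NA_real_,
                sensitivity_pct = 0,
                ci_lo_pct = 0, ci_hi_pct = 0,
                tp = 0L, fp = 0L, fn = n_pos, tn = sum(curve[1, c("fp", "tn")]))
  } else {
    i <- ok[1]                        # smallest qualifying threshold
    ci <- sensitivity_ci(curve$tp[i], n_pos)
    sel <- list(ppv_level = ppv_level, threshold = curve$threshold[i],
                ppv_pct = curve$ppv_pct[i],
                sensitivity_pct = curve$sensitivity_pct[i],
                ci_lo_pct = ci[1], ci_hi_pct = ci[2],
                tp = curve$tp[i], fp = curve$fp[i],
                fn = curve$fn[i], tn = curve$tn[i])
  }
  class(sel) <- "threshold_selection"
  sel
}

#' @export
print.threshold_selection <- function(x, ...) {
  thr <- if (is.infinite(x$threshold)) "+Inf" else sprintf("%.3f", x$threshold)
  cat(sprintf(
    "<threshold_selection> PPV level %g%%: threshold %s, sensitivity %.0f%% (95%% CI %.0f-%.0f)\n",
    x$ppv_level, thr, x$sensitivity_pct, x$ci_lo_pct, x$ci_hi_pct))
  invisible(x)
}

#' Wald 95% confidence interval for sensitivity
#'
#' `p +- 1.96 sqrt(p(1-p)/n)`, clipped to \[0, 100\] and reported in
#' percent. Degenerate at the boundaries (zero width when p is 0 or 1).
#'
#' @param successes Number of captured true pCRs (0..n).
#' @param n Number of true pCRs (> 0).
#' @return Numeric `(lo, hi)` in percent.
#' @export
sensitivity_ci <- function(successes, n) {
  if (length(n) != 1L || n <= 0)
    stop("n must be a positive count", call. = FALSE)
  if (successes < 0 || successes > n)
    stop("successes must lie in [0, n]", call. = FALSE)
  p <- successes / n
  half <- 1.96 * sqrt(p * (1 - p) / n)
  100 * c(max(0, p - half), min(1, p + half))
}

#' Early-surgery recommendation for one patient
#'
#' Applies the subtype's selected probability threshold: below it (or when
#' the threshold is the `+Inf` sentinel) the patient continues NAC; at or
#' above it the patient is an early-surgery candidate, upgraded to a
#' recommendation only when core biopsy confirms no invasive disease.
#'
#' @param probability Predicted pCR probability.
#' @param selection A `threshold_selection` for the patient's subtype.
#' @param biopsy_no_invasive `TRUE` (biopsy negative for invasive disease),
#'   `FALSE`, or `NA` (biopsy not available).
#' @return One of `"continue_NAC"`, `"early_surgery_candidate"`,
#'   `"early_surgery_recommended"`.
#' @export
recommend <- function(probability, selection, biopsy_no_invasive = NA) {
  stopifnot(inherits(selection, "threshold_selection"))
  if (is.infinite(selection$threshold) || probability < selection$threshold)
    return("continue_NAC")
  if (isTRUE(biopsy_no_invasive)) "early_surgery_recommended"
  else "early_surgery_candidate"
}

#' Threshold report across cohorts and PPV levels
#'
#' One row per (cohort scope x PPV level), mirroring the clinical summary
#' table: the selected probability threshold (the string `"+Inf"` when the
#' level is unattainable), the achieved sensitivity, and its 95% CI.
#'
#' @param selections Named list (by scope) of lists of
#'   `threshold_selection` objects.
#' @return data.frame with columns `cohort`, `ppv_level`, `threshold`,
#'   `sensitivity`, `ci_lo`, `ci_hi`.
#' @export
threshold_report <- function(selections) {
  rows <- lapply(names(selections), function(scope) {
    do.call(rbind, lapply(selections[[scope]], function(s) {
      data.frame(cohort = scope, ppv_level = s$ppv_level,
                 threshold = if (is.infinite(s$threshold)) "+Inf"
                             else format(s$threshold, digits = 6),
                 sensitivity = s$sensitivity_pct,
                 ci_lo = s$ci_lo_pct, ci_hi = s$ci_hi_pct,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Clinical implication report at one PPV level
#'
#' Per subtype, the share of true pCR patients who proceed to surgery
#' early (the sensitivity at the selected threshold) versus the share who
#' continue NAC as planned (its complement).
#'
#' @param selections Named list (by subtype) of `threshold_selection`
#'   objects at a single PPV level.
#' @return data.frame with columns `subtype`, `ppv_level`,
#'   `pct_pcr_early_surgery`, `pct_pcr_continue_nac`.
#' @export
implication_report <- function(selections) {
  do.call(rbind, lapply(names(selections), function(scope) {
    s <- selections[[scope]]
    data.frame(subtype = scope, ppv_level = s$ppv_level,
               pct_pcr_early_surgery = s$sensitivity_pct,
               pct_pcr_continue_nac = 100 - s$sensitivity_pct,
               stringsAsFactors = FALSE)
  }))
}
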