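#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value by the probability-mass ordering: the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, no larger than the observed table's probability.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L)))
    stop("fisher_exact_2x2 requires a 2x2 table", call. = FALSE)
  check_contingency(table)
  stats::fisher.test(table)$p.value
}

#' Fisher's exact test for an r x c table
#'
#' Exact mode sums the null hypergeometric mass of all tables with the
#' observed margins whose probability does not exceed the observed
#' table's (network algorithm). For tables too large to enumerate, the
#' Monte Carlo mode estimates the same tail probability by sampling
#' tables under fixed margins, and attaches a Monte Carlo standard error.
#'
#' @param table r x c matrix of non-negative integer counts.
#' @param mode `"exact"` or `"monte_carlo"`.
#' @param reps Monte Carlo replicates (default 1e5).
#' @param seed Integer seed for Monte Carlo sampling.
#' @return List `(test, p, mode, reps, seed, mc_se)`; `mc_se` is `NA` in
#'   exact mode.
#' @export
fisher_exact_rxc <- function(table, mode = c("exact", "monte_carlo"),
                             reps = 1e5, seed = 1L) {
  table <- as.matrix(table)
  check_contingency(table)
  mode <- match.arg(mode)
  if (mode == "exact") {
    p <- tryCatch(
      stats::fisher.test(table, workspace = 2e7)$p.value,
      error = function(e)
        stop("exact enumeration infeasible for this table; ",
             "call with mode = \"monte_carlo\"", call. = FALSE))
    mc_se <- NA_real_
    reps <- NA_integer_
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    p <- stats::fisher.test(table, simulate.p.value = TRUE,
                            B = as.integer(reps))$p.value
    # simulate.p.value uses (1 + #{extreme}) / (1 + B)
    mc_se <- sqrt(p * (1 - p) / reps)
  }
  list(test = "fisher_exact_rxc", p = p, mode = mode,
       reps = reps, seed = as.integer(seed), mc_se = mc_se)
}

check_contingency <- function(table) {
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("table needs at least 2 rows and 2 columns", call. = FALSE)
  if (sum(table) <= 0)
    stop("table must have a positive grand total", call. = FALSE)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("empty margin", call. = FALSE)
  invisible(table)
}

#' Welch two-sample t-test from summary statistics
#'
#' The unequal-variance t statistic with Satterthwaite degrees of freedom,
#' computed from group means, sds and sizes (raw data not required), with
#' a two-sided p-value.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @return List `(t, df, p)`.
#' @export
welch_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("need n >= 2 in each group", call. = FALSE)
  if (sd1 <= 0 || sd2 <= 0) stop("sds must be positive", call. = FALSE)
  v1 <- sd1^2 / n1; v2 <- sd2^2 / n2
  t <- (mean1 - mean2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Audit cohort exclusions
#'
#' Applies the cohort filter chain in fixed order — first drop records
#' missing the pathological outcome or HR/HER2 receptor status, then drop
#' records missing an FTV measurement at any of T0/T1/T2 — and reports
#' per-reason counts alongside the analysis cohort.
#'
#' @param records data.frame with columns `pcr`, `subtype`, `ftv_t0_cc`,
#'   `dftv_t1_pct`, `dftv_t2_pct`; missing values as `NA`.
#' @return List `(n_input, n_missing_outcome_or_receptor, n_missing_ftv,
#'   n_analysis, records)` where `records` is the filtered analysis set.
#' @export
exclusion_audit <- function(records) {
  n0 <- nrow(records)
  miss_clinical <- is.na(records$pcr) | is.na(records$subtype)
  r1 <- records[!miss_clinical, , drop = FALSE]
  miss_ftv <- is.na(r1$ftv_t0_cc) | is.na(r1$dftv_t1_pct) |
    is.na(r1$dftv_t2_pct)
  r2 <- r1[!miss_ftv, , drop = FALSE]
  list(n_input = n0,
       n_missing_outcome_or_receptor = sum(miss_clinical),
       n_missing_ftv = sum(miss_ftv),
       n_analysis = nrow(r2),
       records = r2)
}
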