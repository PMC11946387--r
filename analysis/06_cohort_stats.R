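#!/usr/bin/env Rscript
# Stage 6: cohort-comparison statistics from the published counts of the
# I-SPY 2 analysis and MRI-excluded cohorts.

library(ftvresponse)

# subtype distribution: MRI-excluded (n = 77) vs analysis (n = 814)
subtype_tab <- matrix(c(26, 328, 8, 132, 7, 71, 36, 283),
                      nrow = 4, byrow = TRUE,
                      dimnames = list(c("HR+/HER2-", "HR+/HER2+",
                                        "HR-/HER2+", "TN"),
                                      c("excluded", "analysis")))
fs <- fisher_exact_rxc(subtype_tab)
cat(sprintf("subtype distribution, Fisher exact p = %.2f\n", fs$p))

# pCR rate: 22/77 excluded vs 289/814 analyzed
pcr_tab <- matrix(c(22, 55, 289, 525), nrow = 2, byrow = TRUE)
fp <- fisher_exact_2x2(pcr_tab)
cat(sprintf("pCR rate 22/77 (%.0f%%) vs 289/814 (%.0f%%), Fisher exact p = %.2f\n",
            100 * 22 / 77, 100 * 289 / 814, fp))

# age comparison from summary statistics
w <- welch_t_from_summary(49.1, 10.5, 814, 48.8, 10.6, 990)
cat(sprintf("age, Welch t = %.3f (df %.0f), p = %.2f\n", w$t, w$df, w$p))

jsonlite::write_json(
  list(fisher_subtype = list(test = fs$test, p = fs$p, mode = fs$mode),
       fisher_pcr = list(test = "fisher_exact_2x2", p = fp),
       welch_age = w),
  "results/cohort_stats.json", auto_unbox = TRUE, digits = NA)
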