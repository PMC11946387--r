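#!/usr/bin/env Rscript
# Stage 5: per-patient early-surgery recommendations, plus the two
# published worked cases replayed through the decision rule.

library(ftvresponse)

decisions <- read.csv("results/decisions.csv")
cat("decision mix across the cohort:\n")
print(table(decisions$subtype, decisions$decision))

sel_from <- function(threshold, level)
  structure(list(ppv_level = level, threshold = threshold, ppv_pct = level,
                 sensitivity_pct = NA_real_, ci_lo_pct = NA_real_,
                 ci_hi_pct = NA_real_, tp = 0L, fp = 0L, fn = 0L, tn = 0L),
            class = "threshold_selection")

# slow HR+/HER2- responder: 150 cc -> 44 cc, predicted probability 0.18
# against the subtype's level-50 threshold of 0.24
cat(sprintf("\nslow responder: FTV change %.1f%%, decision: %s\n",
            percent_change(150, 44), recommend(0.18, sel_from(0.24, 50))))
# fast HR-/HER2+ responder: 38 cc -> 3 cc, probability 0.70 against the
# level-70 threshold of 0.62, biopsy clear of invasive disease
cat(sprintf("fast responder: FTV change %.1f%%, decision: %s\n",
            percent_change(38, 3),
            recommend(0.70, sel_from(0.62, 70), biopsy_no_invasive = TRUE)))
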