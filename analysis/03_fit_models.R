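#!/usr/bin/env Rscript
# Stage 3: subtype-specific logistic pCR models.
#
# Audits exclusions, then for the full cohort and each HR/HER2 subtype
# selects the FTV predictor subset (baseline FTV, percent change at T1,
# percent change at T2) maximizing 5-fold cross-validated AUC, and refits
# the winner on all records.

library(ftvresponse)

seed <- 1L
cohort <- read_cohort_csv("results/cohort.csv")
audit <- exclusion_audit(cohort)
cat(sprintf("records: %d in, %d missing outcome/receptor, %d missing FTV, %d analyzed\n",
            audit$n_input, audit$n_missing_outcome_or_receptor,
            audit$n_missing_ftv, audit$n_analysis))
records <- audit$records

scopes <- c("full", sort(unique(records$subtype)))
models <- lapply(scopes, function(scope) {
  sub <- if (scope == "full") records
         else records[records$subtype == scope, , drop = FALSE]
  m <- suppressWarnings(select_model(sub, seed = seed, scope = scope))
  cat(sprintf("%-10s n=%4d  predictors: %-35s cv AUC %.3f\n", scope,
              nrow(sub), paste(m$predictors, collapse = " + "), m$cv_auc))
  m
})
names(models) <- scopes
for (scope in scopes)
  write_model_json(models[[scope]],
                   sprintf("results/model_%s.json",
                           gsub("[^A-Za-z0-9]+", "_", scope)))
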