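#!/usr/bin/env Rscript
# Stage 4: PPV-constrained probability thresholds.
#
# Builds PPV-sensitivity curves over predicted-probability thresholds per
# cohort scope, selects the threshold at minimum PPV levels 50/70/90%
# (+Inf sentinel when a level is unattainable), and writes the
# threshold and clinical-implication reports.

library(ftvresponse)

res <- suppressWarnings(
  run_pipeline(pipeline_config(mode = "cohort_csv",
                               cohort_csv = "results/cohort.csv",
                               seed = 1L, out_dir = "results")))
print(res$report, row.names = FALSE)
cat("\nClinical implications at the PPV 50% threshold:\n")
print(res$implications, row.names = FALSE)
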