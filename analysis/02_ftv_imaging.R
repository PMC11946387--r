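#!/usr/bin/env Rscript
# Stage 2: functional tumor volume from the serial phantom exams.
#
# Reads the NIfTI triplets written by stage 1, applies the baseline VOI
# and enhancement thresholds (PE > 70%, SER > 0) unchanged to all three
# timepoints, and tabulates FTV with serial percent changes.

library(ftvresponse)

cfg <- read_patient_config("scratch/phantoms/phantom01.json")
exams <- lapply(c("T0", "T1", "T2"), function(tp) {
  p <- file.path("scratch/phantoms",
                 sprintf("phantom01_%s_s%d.nii.gz", tp, 0:2))
  read_dce_exam("phantom01", tp, p[1], p[2], p[3])
})
tab <- ftv_table(exams, cfg$voi, cfg$thresholds)
tab$dftv_pct <- percent_change(tab$ftv_cc[1], tab$ftv_cc)
write.csv(tab, "results/ftv_phantom.csv", row.names = FALSE)
print(tab)
cat(sprintf("percent change at T2: %.1f%%\n", tab$dftv_pct[3]))
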