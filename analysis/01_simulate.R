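#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Produces (a) a cohort table with the HR/HER2 subtype mix, per-subtype
# pCR prevalence and FTV trajectories of a large neoadjuvant trial
# population, and (b) a serial DCE phantom (T0/T1/T2) with known
# ground-truth enhancing-voxel counts, written as NIfTI triplets.

library(ftvresponse)

seed <- 1L
dir.create("results", showWarnings = FALSE)
dir.create("scratch/phantoms", recursive = TRUE, showWarnings = FALSE)

cohort <- generate_cohort(cohort_spec(seed = seed))
write_cohort_csv(cohort, "results/cohort.csv")
cat(sprintf("cohort: %d patients, pCR rate %.1f%%\n",
            nrow(cohort), 100 * mean(cohort$pcr)))
print(round(100 * prop.table(table(cohort$subtype)), 1))

# serial phantom: the lesion shrinks across timepoints, emulating response
radii <- list(T0 = c(7, 7, 4), T1 = c(5, 5, 3), T2 = c(3, 3, 2))
truth <- integer(0)
for (tp in names(radii)) {
  spec <- phantom_spec(shape = c(32L, 32L, 16L), voxel_size = c(1, 1, 2),
                       radii = radii[[tp]], noise_sd = 2)
  ph <- generate_phantom(spec, patient_id = "phantom01", timepoint = tp,
                         seed = seed + match(tp, names(radii)))
  write_dce_exam(ph$exam, "scratch/phantoms",
                 prefix = paste0("phantom01_", tp))
  mask <- RNifti::asNifti(array(as.integer(ph$truth), dim = dim(ph$truth)))
  RNifti::pixdim(mask) <- spec$voxel_size
  RNifti::writeNifti(mask, sprintf("scratch/phantoms/phantom01_%s_truth.nii.gz", tp))
  truth[tp] <- sum(ph$truth)
}
jsonlite::write_json(
  list(voi = list(lo = c(4, 4, 2), hi = c(28, 28, 14))),
  "scratch/phantoms/phantom01.json", auto_unbox = TRUE)
cat("phantom ground-truth voxel counts:",
    paste(names(truth), truth, sep = "=", collapse = ", "), "\n")
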