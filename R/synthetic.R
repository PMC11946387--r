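#' Specification of a synthetic DCE phantom
#'
#' Defines an ellipsoidal enhancing lesion on a non-enhancing background so
#' that, before noise, exactly the lattice points inside the ellipsoid
#' satisfy the default segmentation criteria (PE > 70%, SER > 0). The
#' ground-truth voxel count is therefore known, which lets the full FTV
#' chain be validated without real acquisitions.
#'
#' @param shape Integer triple: volume dimensions in voxels (x, y, z).
#' @param voxel_size Numeric triple, voxel edge lengths in mm.
#' @param center Numeric triple, lesion center in 1-based voxel coordinates.
#' @param radii Numeric triple, ellipsoid semi-axes in voxels.
#' @param lesion_pe Lesion percent enhancement (%); must exceed 70.
#' @param lesion_ser Lesion signal enhancement ratio; must be positive.
#' @param background_pe Background percent enhancement (%); must be below 70.
#' @param noise_sd Additive Gaussian noise sd (signal units, >= 0).
#' @param baseline Pre-contrast signal level (arbitrary units, > 0).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 16L), voxel_size = c(1, 1, 2),
                         center = NULL, radii = c(6, 6, 4),
                         lesion_pe = 150, lesion_ser = 1.5,
                         background_pe = 10, noise_sd = 0, baseline = 100) {
  shape <- as.integer(shape)
  if (is.null(center)) center <- (shape + 1) / 2
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(center) == 3L, length(radii) == 3L, all(radii > 0),
            noise_sd >= 0, baseline > 0)
  if (lesion_pe <= 70 || background_pe >= 70)
    stop("lesion_pe must exceed 70 and background_pe stay below 70 so the ",
         "ground-truth mask matches the default thresholds", call. = FALSE)
  if (lesion_ser <= 0)
    stop("lesion_ser must be positive", call. = FALSE)
  if (any(center - radii < 1) || any(center + radii > shape))
    stop("lesion does not fit inside the volume", call. = FALSE)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 center = as.numeric(center), radii = as.numeric(radii),
                 lesion_pe = lesion_pe, lesion_ser = lesion_ser,
                 background_pe = background_pe, noise_sd = noise_sd,
                 baseline = baseline),
            class = "phantom_spec")
}

# lattice points inside the ellipsoid (<= 1 on the normalized quadratic)
ellipsoid_mask <- function(shape, center, radii) {
  ax <- ((seq_len(shape[1]) - center[1]) / radii[1])^2
  ay <- ((seq_len(shape[2]) - center[2]) / radii[2])^2
  az <- ((seq_len(shape[3]) - center[3]) / radii[3])^2
  outer(outer(ax, ay, `+`), az, `+`) <= 1
}

#' Generate a DCE phantom with known ground truth
#'
#' Builds the three dynamic volumes from the spec: constant pre-contrast
#' baseline; early post-contrast raised by the lesion or background PE
#' level; late post-contrast placed so the lesion attains the requested
#' SER. Optional i.i.d. Gaussian noise is added to each volume.
#' Deterministic given `seed`.
#'
#' @param spec A [phantom_spec()].
#' @param patient_id,timepoint Metadata for the returned exam.
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return List with `exam` (a [dce_exam()]) and `truth` (logical array,
#'   the ground-truth enhancing mask).
#' @export
generate_phantom <- function(spec, patient_id = "phantom", timepoint = "T0",
                             seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- ellipsoid_mask(spec$shape, spec$center, spec$radii)
  s0 <- array(spec$baseline, dim = spec$shape)
  pe <- ifelse(truth, spec$lesion_pe, spec$background_pe)
  s1 <- s0 * (1 + pe / 100)
  # background late phase keeps rising (persistent, SER in (0,1)); the
  # lesion's late phase is set from its SER: S2 = S0 + (S1-S0)/SER
  ser <- ifelse(truth, spec$lesion_ser, 0.5)
  s2 <- s0 + (s1 - s0) / ser
  if (spec$noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    n <- length(s0)
    s0 <- s0 + array(stats::rnorm(n, sd = spec$noise_sd), dim = spec$shape)
    s1 <- s1 + array(stats::rnorm(n, sd = spec$noise_sd), dim = spec$shape)
    s2 <- s2 + array(stats::rnorm(n, sd = spec$noise_sd), dim = spec$shape)
  }
  list(exam = dce_exam(patient_id, timepoint, s0, s1, s2, spec$voxel_size),
       truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Specification of a synthetic NAC cohort
#'
#' Encodes the statistical structure of a neoadjuvant breast-cancer cohort:
#' the HR/HER2 subtype mix, per-subtype pCR prevalence, a log-normal
#' baseline FTV, and Gaussian FTV percent changes at T1 and T2 whose group
#' means differ between pCR and non-pCR patients (the configurable effect
#' size driving downstream model performance). Defaults mirror a large
#' neoadjuvant trial population: subtype proportions 40/16/9/35% over
#' HR+/HER2-, HR+/HER2+, HR-/HER2+, triple negative, and pCR rates
#' 20/39/66/45% in the same order.
#'
#' @param n_patients Number of patients.
#' @param subtype_proportions Named numeric vector over the four subtypes;
#'   must sum to 1.
#' @param pcr_rate Named per-subtype pCR probability in \[0, 1\].
#' @param ftv_t0_meanlog,ftv_t0_sdlog Log-scale mean and sd of baseline FTV
#'   (cc), recycled across subtypes if scalar.
#' @param dftv_t1_mean,dftv_t2_mean Length-2 numeric `(pCR, non-pCR)` group
#'   means of percent change at T1 / T2.
#' @param dftv_t1_sd,dftv_t2_sd Group sds of the percent changes, `(pCR,
#'   non-pCR)`, recycled if scalar. The defaults make the responding (pCR)
#'   group's late change tightly concentrated near deep shrinkage while the
#'   non-pCR group is diffuse, which bounds the positive predictive value
#'   attainable in low-prevalence strata the way real low-pCR cohorts
#'   behave.
#' @param seed Integer seed; all randomness flows from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 5000,
                        subtype_proportions = c("HR+/HER2-" = 0.40,
                                                "HR+/HER2+" = 0.16,
                                                "HR-/HER2+" = 0.09,
                                                "TN" = 0.35),
                        pcr_rate = c("HR+/HER2-" = 0.20,
                                     "HR+/HER2+" = 0.39,
                                     "HR-/HER2+" = 0.66,
                                     "TN" = 0.45),
                        ftv_t0_meanlog = log(20), ftv_t0_sdlog = 0.8,
                        dftv_t1_mean = c(pcr = -53, non_pcr = -30),
                        dftv_t1_sd = c(pcr = 16, non_pcr = 35),
                        dftv_t2_mean = c(pcr = -78, non_pcr = -50),
                        dftv_t2_sd = c(pcr = 6, non_pcr = 35),
                        seed = 1L) {
  stopifnot(n_patients >= 1, length(subtype_proportions) == 4L,
            length(pcr_rate) == 4L)
  if (abs(sum(subtype_proportions) - 1) > 1e-8)
    stop("subtype_proportions must sum to 1", call. = FALSE)
  if (any(pcr_rate < 0 | pcr_rate > 1))
    stop("pcr_rate values must lie in [0, 1]", call. = FALSE)
  if (any(c(ftv_t0_sdlog, dftv_t1_sd, dftv_t2_sd) < 0))
    stop("sds must be non-negative", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients),
                 subtype_proportions = subtype_proportions,
                 pcr_rate = pcr_rate,
                 ftv_t0_meanlog = rep_len(ftv_t0_meanlog, 4L),
                 ftv_t0_sdlog = rep_len(ftv_t0_sdlog, 4L),
                 dftv_t1_mean = dftv_t1_mean,
                 dftv_t1_sd = rep_len(dftv_t1_sd, 2L),
                 dftv_t2_mean = dftv_t2_mean,
                 dftv_t2_sd = rep_len(dftv_t2_sd, 2L),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# truncated-normal draw via resampling: percent change cannot fall below
# -100 (FTV cannot go negative)
rnorm_trunc <- function(n, mean, sd, lower = -100) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lower)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), mean[bad], sd[bad])
    bad <- bad[x[bad] < lower]
  }
  x
}

#' Generate a synthetic patient cohort
#'
#' Draws subtype from the spec's proportions, pCR from the per-subtype
#' rate, baseline FTV log-normally, and percent FTV changes at T1/T2 from
#' group-specific Gaussians truncated at -100%. Deterministic given the
#' spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return data.frame with columns `patient_id`, `subtype`, `pcr` (0/1),
#'   `ftv_t0_cc`, `dftv_t1_pct`, `dftv_t2_pct`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  n <- spec$n_patients
  subtypes <- names(spec$subtype_proportions)
  subtype <- sample(subtypes, n, replace = TRUE,
                    prob = spec$subtype_proportions)
  idx <- match(subtype, subtypes)
  pcr <- as.integer(stats::runif(n) < spec$pcr_rate[idx])
  ftv_t0 <- stats::rlnorm(n, spec$ftv_t0_meanlog[idx],
                          spec$ftv_t0_sdlog[idx])
  grp <- ifelse(pcr == 1L, 1L, 2L)           # (pcr, non_pcr) order
  m1 <- spec$dftv_t1_mean[grp]; s1 <- spec$dftv_t1_sd[grp]
  m2 <- spec$dftv_t2_mean[grp]; s2 <- spec$dftv_t2_sd[grp]
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    subtype = subtype, pcr = pcr,
    ftv_t0_cc = ftv_t0,
    dftv_t1_pct = rnorm_trunc(n, m1, s1),
    dftv_t2_pct = rnorm_trunc(n, m2, s2),
    stringsAsFactors = FALSE)
}

#' Write a cohort table to CSV
#'
#' Byte-stable output: numeric columns are written with full precision so
#' identical seeds reproduce identical files.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(format(cohort, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' @param path CSV with columns `patient_id`, `subtype`, `pcr`,
#'   `ftv_t0_cc`, `dftv_t1_pct`, `dftv_t2_pct`.
#' @return data.frame.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "subtype", "pcr", "ftv_t0_cc",
            "dftv_t1_pct", "dftv_t2_pct")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
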