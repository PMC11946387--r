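#' Percent enhancement map
#'
#' PE = (S1 - S0) / S0 x 100%, the early post-contrast signal rise relative
#' to pre-contrast. Voxels with non-positive pre-contrast signal (S0 <= 0)
#' have undefined enhancement and are returned as `NA`; they are excluded
#' from any segmentation.
#'
#' @param exam A [dce_exam()].
#' @return 3-D numeric array of percent enhancement; `NA` where invalid.
#' @export
compute_pe_map <- function(exam) {
  stopifnot(inherits(exam, "dce_exam"))
  pe <- (exam$s1 - exam$s0) / exam$s0 * 100
  pe[exam$s0 <= 0] <- NA_real_
  pe
}

#' Signal enhancement ratio map
#'
#' SER = (S1 - S0) / (S2 - S0), the ratio of early to late enhancement.
#' SER > 1 indicates washout kinetics; SER near 0 indicates persistent
#' enhancement. Voxels with S2 = S0 (zero denominator) or S0 <= 0 are
#' returned as `NA` and excluded from segmentation.
#'
#' @param exam A [dce_exam()].
#' @return 3-D numeric array of SER; `NA` where invalid.
#' @export
compute_ser_map <- function(exam) {
  stopifnot(inherits(exam, "dce_exam"))
  den <- exam$s2 - exam$s0
  ser <- (exam$s1 - exam$s0) / den
  ser[den == 0 | exam$s0 <= 0] <- NA_real_
  ser
}

# logical 3-D mask of the half-open VOI box, checking bounds against the
# volume shape
voi_mask <- function(voi, dims) {
  stopifnot(inherits(voi, "voi_box"))
  if (any(voi$hi > dims))
    stop("VOI extends outside the volume", call. = FALSE)
  m <- array(FALSE, dim = dims)
  m[(voi$lo[1] + 1L):voi$hi[1],
    (voi$lo[2] + 1L):voi$hi[2],
    (voi$lo[3] + 1L):voi$hi[3]] <- TRUE
  m
}

#' Segment enhancing voxels inside the VOI
#'
#' A voxel is enhancing when it lies inside the VOI, its percent
#' enhancement strictly exceeds `thr$pe_min`, its signal enhancement ratio
#' strictly exceeds `thr$ser_min`, and both maps are defined there
#' (pre-contrast signal positive, late-enhancement denominator nonzero).
#' Voxels exactly at a threshold are excluded.
#'
#' @param exam A [dce_exam()].
#' @param voi A [voi_box()]; must fit inside the exam volume.
#' @param thr An [enh_thresholds()].
#' @return Logical 3-D array, `TRUE` at enhancing voxels.
#' @export
segment_enhancing_voxels <- function(exam, voi, thr = enh_thresholds()) {
  stopifnot(inherits(exam, "dce_exam"), inherits(thr, "enh_thresholds"))
  inside <- voi_mask(voi, dim(exam$s0))
  pe <- compute_pe_map(exam)
  ser <- compute_ser_map(exam)
  valid <- !is.na(pe) & !is.na(ser)
  mask <- inside & valid
  mask[mask] <- pe[mask] > thr$pe_min & ser[mask] > thr$ser_min
  mask
}

#' Functional tumor volume
#'
#' FTV (cc) is the summed volume of enhancing voxels inside the VOI:
#' `voxel_count * prod(voxel_size mm) / 1000`.
#'
#' @inheritParams segment_enhancing_voxels
#' @return A list of class `ftv_result` with `ftv_cc`, `voxel_count`,
#'   `thresholds_used`, `voi_used`.
#' @export
compute_ftv <- function(exam, voi, thr = enh_thresholds()) {
  mask <- segment_enhancing_voxels(exam, voi, thr)
  n <- sum(mask)
  structure(
    list(ftv_cc = n * prod(exam$voxel_size) / 1000,
         voxel_count = n, thresholds_used = thr, voi_used = voi),
    class = "ftv_result")
}

#' @export
print.ftv_result <- function(x, ...) {
  cat(sprintf("<ftv_result> %.3f cc (%d voxels, PE > %g%%, SER > %g)\n",
              x$ftv_cc, x$voxel_count,
              x$thresholds_used$pe_min, x$thresholds_used$ser_min))
  invisible(x)
}

#' Serial percent change in FTV
#'
#' `(ftv_t - ftv_ref) / ftv_ref * 100`. A zero reference volume makes the
#' change undefined: the function returns `NA_real_` (never a silent 0),
#' and such records are excluded from downstream modeling.
#'
#' @param ftv_ref Reference (baseline) FTV in cc.
#' @param ftv_t Follow-up FTV in cc.
#' @return Percent change (vectorized); `NA_real_` where `ftv_ref` is 0.
#' @export
percent_change <- function(ftv_ref, ftv_t) {
  if (any(ftv_ref < 0, na.rm = TRUE) || any(ftv_t < 0, na.rm = TRUE))
    stop("FTV values must be non-negative", call. = FALSE)
  out <- (ftv_t - ftv_ref) / ftv_ref * 100
  out[ftv_ref == 0] <- NA_real_
  out
}

#' Tabulate FTV across a patient's serial exams
#'
#' Applies the baseline VOI and thresholds unchanged to every exam of the
#' patient, enforcing the fixed-at-T0 convention.
#'
#' @param exams List of [dce_exam()] objects for one patient (T0/T1/T2).
#' @param voi A [voi_box()] delineated at baseline.
#' @param thr An [enh_thresholds()] set at baseline.
#' @return data.frame with columns `patient_id`, `timepoint`, `ftv_cc`,
#'   `voxel_count`, `pe_min`, `ser_min`.
#' @export
ftv_table <- function(exams, voi, thr = enh_thresholds()) {
  pid <- unique(vapply(exams, `[[`, "", "patient_id"))
  if (length(pid) != 1L)
    stop("exams must belong to a single patient", call. = FALSE)
  rows <- lapply(exams, function(ex) {
    res <- compute_ftv(ex, voi, thr)
    data.frame(patient_id = ex$patient_id, timepoint = ex$timepoint,
               ftv_cc = res$ftv_cc, voxel_count = res$voxel_count,
               pe_min = thr$pe_min, ser_min = thr$ser_min,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
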