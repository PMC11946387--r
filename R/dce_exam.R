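#' Construct a DCE-MRI exam object
#'
#' Bundles the three dynamic volumes of one exam — pre-contrast, early
#' post-contrast (~2 min 30 s after injection) and late post-contrast
#' (~7 min 30 s) — together with the voxel geometry. All downstream FTV
#' computation operates on this container.
#'
#' @param patient_id Opaque patient identifier (character scalar).
#' @param timepoint One of `"T0"`, `"T1"`, `"T2"` (pretreatment,
#'   early-treatment, inter-regimen).
#' @param s0,s1,s2 3-D numeric arrays of identical dimension: signal
#'   intensity (arbitrary units) at pre-contrast, early post-contrast and
#'   late post-contrast.
#' @param voxel_size Numeric triple of positive voxel edge lengths in mm,
#'   ordered (x, y, z) to match the array axes.
#'
#' @return An object of class `dce_exam`.
#' @export
dce_exam <- function(patient_id, timepoint, s0, s1, s2, voxel_size) {
  timepoint <- match.arg(timepoint, c("T0", "T1", "T2"))
  s0 <- as.array(s0); s1 <- as.array(s1); s2 <- as.array(s2)
  if (length(dim(s0)) != 3L)
    stop("volumes must be 3-D arrays", call. = FALSE)
  if (!identical(dim(s0), dim(s1)) || !identical(dim(s0), dim(s2)))
    stop("s0, s1, s2 must have identical dimensions", call. = FALSE)
  if (!all(is.finite(s0)) || !all(is.finite(s1)) || !all(is.finite(s2)))
    stop("signal volumes must be finite", call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)", call. = FALSE)
  structure(
    list(patient_id = as.character(patient_id), timepoint = timepoint,
         s0 = s0, s1 = s1, s2 = s2, voxel_size = voxel_size),
    class = "dce_exam")
}

#' @export
print.dce_exam <- function(x, ...) {
  cat(sprintf("<dce_exam> patient %s, %s, %s voxels, %.2fx%.2fx%.2f mm\n",
              x$patient_id, x$timepoint, paste(dim(x$s0), collapse = "x"),
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Rectangular volume of interest
#'
#' A half-open axis-aligned box `[lo, hi)` in 0-based voxel indices, axis
#' order (x, y, z) matching the exam volumes. The VOI is delineated at
#' baseline (T0) and propagated unchanged to later exams of the same
#' patient.
#'
#' @param lo,hi Integer triples: lower (inclusive) and upper (exclusive)
#'   corner indices per axis, 0-based.
#' @return An object of class `voi_box`.
#' @export
voi_box <- function(lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L)
    stop("lo and hi must be integer triples", call. = FALSE)
  if (any(is.na(lo)) || any(is.na(hi)) || any(lo < 0L))
    stop("corner indices must be non-negative integers", call. = FALSE)
  if (any(lo >= hi))
    stop("voi_box requires lo < hi on every axis", call. = FALSE)
  structure(list(lo = lo, hi = hi), class = "voi_box")
}

#' Enhancement thresholds for FTV segmentation
#'
#' Voxels are counted toward FTV when percent enhancement exceeds `pe_min`
#' and the signal enhancement ratio exceeds `ser_min` (strict inequalities).
#' The defaults, PE > 70% and SER > 0, are the standard empirical settings;
#' both may be adjusted per patient at baseline and are then held fixed
#' across that patient's serial exams.
#'
#' @param pe_min Minimum percent enhancement (%, default 70, must be >= 0).
#' @param ser_min Minimum signal enhancement ratio (dimensionless, default 0).
#' @return An object of class `enh_thresholds`.
#' @export
enh_thresholds <- function(pe_min = 70, ser_min = 0) {
  pe_min <- as.numeric(pe_min); ser_min <- as.numeric(ser_min)
  if (length(pe_min) != 1L || !is.finite(pe_min) || pe_min < 0)
    stop("pe_min must be a finite non-negative percent", call. = FALSE)
  if (length(ser_min) != 1L || !is.finite(ser_min))
    stop("ser_min must be finite", call. = FALSE)
  structure(list(pe_min = pe_min, ser_min = ser_min),
            class = "enh_thresholds")
}

#' Read a DCE exam from NIfTI volumes
#'
#' Reads the three dynamic phases from NIfTI files (`.nii` or `.nii.gz`).
#' Voxel sizes are taken from the header of the pre-contrast image unless
#' overridden.
#'
#' @param patient_id,timepoint Passed to [dce_exam()].
#' @param s0_path,s1_path,s2_path Paths to pre-contrast, early and late
#'   post-contrast NIfTI volumes.
#' @param voxel_size Optional numeric triple (mm) overriding the header.
#' @return A `dce_exam`.
#' @export
read_dce_exam <- function(patient_id, timepoint, s0_path, s1_path, s2_path,
                          voxel_size = NULL) {
  s0 <- RNifti::readNifti(s0_path)
  s1 <- RNifti::readNifti(s1_path)
  s2 <- RNifti::readNifti(s2_path)
  if (is.null(voxel_size))
    voxel_size <- RNifti::pixdim(s0)[1:3]
  dce_exam(patient_id, timepoint,
           s0 = as.array(s0), s1 = as.array(s1), s2 = as.array(s2),
           voxel_size = voxel_size)
}

#' Write a DCE exam to NIfTI volumes
#'
#' @param exam A `dce_exam`.
#' @param dir Output directory (created if absent).
#' @param prefix Filename prefix; files are `<prefix>_s0.nii.gz` etc.
#' @return Invisibly, the three file paths.
#' @export
write_dce_exam <- function(exam, dir, prefix = exam$patient_id) {
  stopifnot(inherits(exam, "dce_exam"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, "_s", 0:2, ".nii.gz"))
  vols <- list(exam$s0, exam$s1, exam$s2)
  for (i in 1:3) {
    img <- RNifti::asNifti(vols[[i]])
    RNifti::pixdim(img) <- exam$voxel_size
    RNifti::writeNifti(img, paths[i])
  }
  invisible(paths)
}

#' Read per-patient VOI and threshold configuration
#'
#' JSON layout per patient:
#' `{"voi": {"lo": [x,y,z], "hi": [x,y,z]}, "pe_min": 70, "ser_min": 0}`.
#' Corner indices are 0-based half-open, axis order (x, y, z). Missing
#' `pe_min`/`ser_min` fall back to the defaults of [enh_thresholds()].
#'
#' @param path Path to the JSON file.
#' @return List with elements `voi` (a `voi_box`) and `thresholds`
#'   (an `enh_thresholds`).
#' @export
read_patient_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$voi))
    stop("patient config must contain a 'voi' entry", call. = FALSE)
  list(voi = voi_box(cfg$voi$lo, cfg$voi$hi),
       thresholds = enh_thresholds(
         pe_min = if (is.null(cfg$pe_min)) 70 else cfg$pe_min,
         ser_min = if (is.null(cfg$ser_min)) 0 else cfg$ser_min))
}
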