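make_exam <- function(s0, s1, s2, vox = c(1, 1, 1)) {
  shape <- c(2L, 2L, 1L)
  dce_exam("p1", "T0",
           array(s0, shape), array(s1, shape), array(s2, shape), vox)
}

test_that("percent enhancement follows (S1-S0)/S0 x 100 with invalid S0 flagged", {
  expect_equal(compute_pe_map(make_exam(100, 200, 150))[1, 1, 1], 100)
  expect_equal(compute_pe_map(make_exam(100, 100, 150))[1, 1, 1], 0)
  expect_equal(compute_pe_map(make_exam(80, 150, 160))[1, 1, 1], 87.5)
  ex <- make_exam(0, 150, 160)
  ex$s0[2, 2, 1] <- -3
  expect_true(all(is.na(compute_pe_map(ex)[cbind(c(1, 2), c(1, 2), 1)])))
})

test_that("signal enhancement ratio follows (S1-S0)/(S2-S0) with zero denominator flagged", {
  expect_equal(compute_ser_map(make_exam(100, 200, 150))[1, 1, 1], 2.0)
  expect_equal(compute_ser_map(make_exam(100, 200, 300))[1, 1, 1], 0.5)
  # washout below baseline: negative SER fails the SER > 0 criterion
  expect_equal(compute_ser_map(make_exam(100, 180, 90))[1, 1, 1], -8.0)
  expect_true(is.na(compute_ser_map(make_exam(100, 180, 100))[1, 1, 1]))
})

test_that("exam construction rejects shape mismatch and bad geometry", {
  s <- array(1, c(2, 2, 2))
  expect_error(dce_exam("p", "T0", s, array(1, c(2, 2, 3)), s, c(1, 1, 1)),
               "identical dimensions")
  expect_error(dce_exam("p", "T0", s, s, s, c(1, 0, 1)), "positive")
  expect_error(voi_box(c(0, 0, 0), c(1, 0, 1)), "lo < hi")
  expect_error(enh_thresholds(pe_min = -1), "non-negative")
})

test_that("uniform non-enhancing volume yields an empty mask and zero FTV", {
  shape <- c(4L, 4L, 3L)
  s <- array(100, shape)
  ex <- dce_exam("p1", "T0", s, s, s + 50, c(1, 1, 1))
  voi <- voi_box(c(0, 0, 0), shape)
  expect_equal(sum(segment_enhancing_voxels(ex, voi)), 0)
  res <- compute_ftv(ex, voi)
  expect_equal(res$ftv_cc, 0)
  expect_equal(res$voxel_count, 0)
})

test_that("segmentation equals the per-voxel brute-force oracle on 100 random phantoms", {
  thrs <- list(enh_thresholds(), enh_thresholds(50, -0.5),
               enh_thresholds(120, 1))
  for (seed in 1:100) {
    ex <- random_exam(seed)
    set.seed(seed + 5000)
    voi <- random_voi(dim(ex$s0))
    thr <- thrs[[(seed %% 3) + 1]]
    expect_identical(segment_enhancing_voxels(ex, voi, thr),
                     brute_force_mask(ex, voi, thr),
                     info = paste("seed", seed))
  }
})

test_that("FTV converts voxel counts with the voxel volume and respects the VOI", {
  shape <- c(12L, 12L, 10L)
  spec <- phantom_spec(shape = shape, voxel_size = c(1, 1, 2),
                       radii = c(4, 4, 3))
  ph <- generate_phantom(spec)
  voi <- voi_box(c(0, 0, 0), shape)
  res <- compute_ftv(ph$exam, voi)
  k <- sum(ph$truth)
  expect_equal(res$voxel_count, k)
  expect_equal(res$ftv_cc, k * 0.002)
  # shrinking the VOI to half the volume matches a brute-force recount
  voi2 <- voi_box(c(0, 0, 0), c(6L, 12L, 10L))
  res2 <- compute_ftv(ph$exam, voi2)
  expect_equal(res2$voxel_count,
               sum(brute_force_mask(ph$exam, voi2, enh_thresholds())))
  expect_lte(res2$voxel_count, res$voxel_count)
  expect_error(compute_ftv(ph$exam, voi_box(c(0, 0, 0), shape + 1L)),
               "outside")
})

test_that("FTV is monotone in thresholds and VOI growth", {
  for (seed in 1:15) {
    ex <- random_exam(seed, shape = c(8L, 8L, 6L))
    voi <- voi_box(c(1, 1, 1), c(7, 7, 5))
    base <- compute_ftv(ex, voi, enh_thresholds(70, 0))$ftv_cc
    expect_lte(compute_ftv(ex, voi, enh_thresholds(90, 0))$ftv_cc, base)
    expect_lte(compute_ftv(ex, voi, enh_thresholds(70, 0.5))$ftv_cc, base)
    grown <- compute_ftv(ex, voi_box(c(0, 0, 0), c(8, 8, 6)),
                         enh_thresholds(70, 0))$ftv_cc
    expect_gte(grown, base)
  }
})

test_that("with PE > 70 the SER > 0 criterion is equivalent to late signal above baseline", {
  for (seed in 1:20) {
    ex <- random_exam(seed)
    voi <- voi_box(c(0, 0, 0), dim(ex$s0))
    mask <- segment_enhancing_voxels(ex, voi, enh_thresholds(70, 0))
    pe <- compute_pe_map(ex); ser <- compute_ser_map(ex)
    valid <- !is.na(pe) & !is.na(ser)
    high_pe <- valid & pe > 70
    # on valid voxels with PE > 70 (so S1 > S0): SER > 0 iff S2 > S0
    expect_identical(mask[high_pe], (ex$s2 > ex$s0)[high_pe])
  }
})

test_that("FTV is invariant under axis permutation with matching voxel sizes", {
  ex <- random_exam(42, shape = c(6L, 5L, 4L))
  voi <- voi_box(c(1, 0, 1), c(5, 5, 3))
  ref <- compute_ftv(ex, voi)$ftv_cc
  perm <- c(3, 1, 2)
  ex_p <- dce_exam("rnd", "T0", aperm(ex$s0, perm), aperm(ex$s1, perm),
                   aperm(ex$s2, perm), ex$voxel_size[perm])
  voi_p <- voi_box(voi$lo[perm], voi$hi[perm])
  expect_equal(compute_ftv(ex_p, voi_p)$ftv_cc, ref)
})

test_that("percent change is exact and flags a zero reference as undefined", {
  expect_equal(round(percent_change(150, 44), 1), -70.7)
  expect_equal(percent_change(38, 38), 0)
  expect_equal(round(percent_change(38, 3), 1), -92.1)
  expect_true(is.na(percent_change(0, 10)))
  expect_error(percent_change(-1, 10), "non-negative")
})

test_that("NIfTI round trip preserves signals and voxel geometry", {
  spec <- phantom_spec(shape = c(10L, 10L, 6L), voxel_size = c(0.9, 0.9, 2),
                       radii = c(3, 3, 2))
  ph <- generate_phantom(spec)
  dir <- withr::local_tempdir()
  write_dce_exam(ph$exam, dir, prefix = "pat1")
  ex2 <- read_dce_exam("pat1", "T0",
                       file.path(dir, "pat1_s0.nii.gz"),
                       file.path(dir, "pat1_s1.nii.gz"),
                       file.path(dir, "pat1_s2.nii.gz"))
  expect_equal(ex2$voxel_size, c(0.9, 0.9, 2), tolerance = 1e-6)
  expect_equal(as.numeric(ex2$s1), as.numeric(ph$exam$s1), tolerance = 1e-6)
  voi <- voi_box(c(0, 0, 0), spec$shape)
  expect_equal(compute_ftv(ex2, voi)$voxel_count, sum(ph$truth))
})

test_that("per-patient JSON config drives VOI and threshold overrides", {
  dir <- withr::local_tempdir()
  cfg_path <- file.path(dir, "pat1.json")
  writeLines('{"voi": {"lo": [0,0,0], "hi": [4,4,2]}, "pe_min": 80}', cfg_path)
  cfg <- read_patient_config(cfg_path)
  expect_s3_class(cfg$voi, "voi_box")
  expect_equal(cfg$voi$hi, c(4L, 4L, 2L))
  expect_equal(cfg$thresholds$pe_min, 80)
  expect_equal(cfg$thresholds$ser_min, 0)
})

test_that("ftv_table applies baseline VOI and thresholds across serial exams", {
  spec0 <- phantom_spec(shape = c(14L, 14L, 8L), radii = c(5, 5, 3))
  spec2 <- phantom_spec(shape = c(14L, 14L, 8L), radii = c(2, 2, 2))
  exams <- list(
    generate_phantom(spec0, "p9", "T0")$exam,
    generate_phantom(spec2, "p9", "T2")$exam)
  tab <- ftv_table(exams, voi_box(c(0, 0, 0), c(14, 14, 8)))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$timepoint, c("T0", "T2"))
  expect_true(tab$ftv_cc[2] < tab$ftv_cc[1])
  expect_equal(unique(tab$pe_min), 70)
  bad <- list(exams[[1]], generate_phantom(spec2, "other", "T1")$exam)
  expect_error(ftv_table(bad, voi_box(c(0, 0, 0), c(14, 14, 8))),
               "single patient")
})
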