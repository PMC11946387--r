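# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (per-voxel loops, all-pairs counts,
# exhaustive scans) and share no code with the implementation paths they
# check.

# per-voxel loop segmentation: inside the half-open VOI, PE and SER
# recomputed scalar-by-scalar with the validity rules applied explicitly
brute_force_mask <- function(exam, voi, thr) {
  d <- dim(exam$s0)
  mask <- array(FALSE, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    i0 <- i - 1L; j0 <- j - 1L; k0 <- k - 1L   # 0-based
    if (i0 < voi$lo[1] || i0 >= voi$hi[1] ||
        j0 < voi$lo[2] || j0 >= voi$hi[2] ||
        k0 < voi$lo[3] || k0 >= voi$hi[3]) next
    s0 <- exam$s0[i, j, k]; s1 <- exam$s1[i, j, k]; s2 <- exam$s2[i, j, k]
    if (s0 <= 0) next
    if (s2 - s0 == 0) next
    pe <- (s1 - s0) / s0 * 100
    ser <- (s1 - s0) / (s2 - s0)
    if (pe > thr$pe_min && ser > thr$ser_min) mask[i, j, k] <- TRUE
  }
  mask
}

# all-pairs AUC with ties counted half
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  total / (length(pos) * length(neg))
}

# exhaustive threshold scan: over all candidate thresholds, recompute PPV
# directly and return the smallest qualifying threshold with its
# sensitivity (Inf when none qualifies)
brute_force_select <- function(probabilities, labels, ppv_level) {
  labels <- as.logical(labels)
  best <- list(threshold = Inf, sensitivity = 0)
  for (t in sort(unique(c(0, probabilities)))) {
    pred <- probabilities >= t
    if (!any(pred)) next
    ppv <- 100 * sum(pred & labels) / sum(pred)
    if (ppv >= ppv_level) {
      best <- list(threshold = t,
                   sensitivity = 100 * sum(pred & labels) / sum(labels))
      break
    }
  }
  best
}

# random exam whose signals hit every validity branch: negative and zero
# pre-contrast voxels, zero SER denominators, values straddling thresholds
random_exam <- function(seed, shape = c(7L, 6L, 5L)) {
  set.seed(seed)
  n <- prod(shape)
  s0 <- array(sample(c(-5, 0, runif(n, 1, 200)), n, replace = TRUE), shape)
  s1 <- array(runif(n, 0, 400), shape)
  s2 <- s0 + array(sample(c(0, runif(n, -120, 250)), n, replace = TRUE), shape)
  dce_exam("rnd", "T0", s0, s1, s2, voxel_size = runif(3, 0.5, 3))
}

random_voi <- function(shape) {
  lo <- vapply(shape, function(s) sample(0:(s - 2L), 1L), 1L)
  hi <- vapply(seq_along(shape),
               function(a) sample((lo[a] + 1L):shape[a], 1L), 1L)
  voi_box(lo, hi)
}

# tiny labelled score set with controllable prevalence
random_scored_cohort <- function(n, prevalence = 0.4) {
  labels <- runif(n) < prevalence
  if (all(labels)) labels[1] <- FALSE
  if (!any(labels)) labels[1] <- TRUE
  # coarse grid of probabilities forces ties between records
  probs <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
  list(probs = probs, labels = labels)
}
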