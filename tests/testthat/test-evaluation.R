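test_that("confusion counts and overlap metrics match hand-worked toys", {
  seg <- array(0L, c(2, 2, 1)); seg[1, 1, 1] <- 1L
  ref <- array(0L, c(2, 2, 1)); ref[1, 1, 1] <- 1L; ref[2, 1, 1] <- 1L
  cc <- confusion_counts(seg, ref, 1)
  expect_equal(cc, list(tp = 1L, fp = 0L, fn = 1L, tn = 2L))
  m <- overlap_metrics(cc)
  expect_equal(m$dice, 2 / 3)
  expect_equal(m$jaccard, 1 / 2)
  expect_equal(m$sensitivity, 1 / 2)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 3 / 4)

  # identical masks: perfect scores; identical implies no errors
  same <- confusion_counts(ref, ref, 1)
  expect_equal(same$fp + same$fn, 0L)
  expect_true(all(unlist(overlap_metrics(same)) == 1))

  # empty prediction: fn = foreground count
  none <- confusion_counts(array(0L, dim(ref)), ref, 1)
  expect_equal(none$fn, 2L); expect_equal(none$tp, 0L)

  # both empty: dice NaN, specificity 1
  be <- overlap_metrics(confusion_counts(array(0L, c(2, 2, 2)),
                                         array(0L, c(2, 2, 2)), 1))
  expect_true(is.nan(be$dice))
  expect_equal(be$specificity, 1)

  expect_error(confusion_counts(array(0, c(2, 2, 2)), array(0, c(3, 2, 2)), 1),
               "shapes differ")
})

test_that("dice and jaccard obey their algebraic identity on random counts", {
  set.seed(25)
  for (i in 1:30) {
    cc <- as.list(setNames(sample(0:50, 4, TRUE), c("tp", "fp", "tn", "fn")))
    if (cc$tp + cc$fp + cc$fn == 0) next
    m <- overlap_metrics(cc)
    expect_equal(m$dice, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
  }
})

test_that("volume metrics use spacing and the stated rvd formula", {
  seg <- array(0L, c(5, 5, 5)); seg[1:10] <- 1L
  expect_equal(volume_metrics(seg, seg, c(2, 2, 2))$volume_mm3, 80)
  expect_equal(volume_metrics(seg, seg)$relative_volume_difference, 0)
  seg2 <- array(0L, c(5, 5, 5)); seg2[1:12] <- 1L
  expect_equal(volume_metrics(seg2, seg)$relative_volume_difference, 0.2)
  expect_true(is.nan(volume_metrics(seg, array(0L, c(5, 5, 5)))$relative_volume_difference))
})

test_that("surface distances match the brute-force all-pairs oracle", {
  # two single-voxel masks 3 voxels apart
  a <- array(FALSE, c(7, 3, 3)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(7, 3, 3)); b[5, 2, 2] <- TRUE
  sd <- surface_distances(a, b, label_value = TRUE)
  expect_equal(sd$mean_absolute_distance, 3)
  expect_equal(sd$hausdorff, 3)
  expect_equal(sd$hausdorff95, 3)

  # identity: zero
  sd0 <- surface_distances(a, a, label_value = TRUE)
  expect_equal(unlist(sd0[1:3]), c(mean_absolute_distance = 0, hausdorff = 0,
                                   hausdorff95 = 0))

  # cube vs shifted cube, and random masks, against the O(n^2) oracle
  cube <- array(FALSE, c(8, 8, 8)); cube[2:5, 2:5, 2:5] <- TRUE
  shifted <- array(FALSE, c(8, 8, 8)); shifted[3:6, 2:5, 2:5] <- TRUE
  for (pair in list(list(cube, shifted, c(1, 1, 1)),
                    list(rand_mask(c(9, 8, 7), 0.3, 26),
                         rand_mask(c(9, 8, 7), 0.3, 27), c(1.5, 1, 2)))) {
    got <- surface_distances(pair[[1]], pair[[2]], pair[[3]], label_value = TRUE)
    want <- bf_surface_distances(pair[[1]], pair[[2]], pair[[3]])
    expect_equal(got$mean_absolute_distance, want$mean_absolute_distance,
                 tolerance = 1e-9)
    expect_equal(got$hausdorff, want$hausdorff, tolerance = 1e-9)
    expect_equal(got$hausdorff95, want$hausdorff95, tolerance = 1e-9)
  }

  # symmetric in (seg, ref)
  fwd <- surface_distances(cube, shifted, label_value = TRUE)
  rev <- surface_distances(shifted, cube, label_value = TRUE)
  expect_equal(fwd, rev)

  expect_true(is.nan(surface_distances(array(FALSE, c(7, 3, 3)), a,
                                       label_value = TRUE)$hausdorff))
})

test_that("metrics are invariant to simultaneous axis permutation", {
  set.seed(28)
  seg <- rand_mask(c(6, 7, 8), 0.3, 29)
  ref <- rand_mask(c(6, 7, 8), 0.3, 30)
  spacing <- c(1, 2, 3)
  base <- surface_distances(seg, ref, spacing, label_value = TRUE)
  perm <- c(3, 1, 2)
  got <- surface_distances(aperm(seg, perm), aperm(ref, perm), spacing[perm],
                           label_value = TRUE)
  expect_equal(base, got, tolerance = 1e-12)
  expect_equal(overlap_metrics(confusion_counts(seg, ref, TRUE)),
               overlap_metrics(confusion_counts(aperm(seg, perm),
                                                aperm(ref, perm), TRUE)))
})

test_that("region metrics count detections and spurious components", {
  ref <- array(0L, c(12, 6, 6))
  ref[2:4, 2:4, 2:4] <- 1L      # component A
  ref[8:10, 2:4, 2:4] <- 1L     # component B
  # seg == ref: all detected, no region FPs
  rm <- region_metrics(ref, ref)
  expect_equal(rm$detection_rate, 1)
  expect_equal(rm$region_specificity, 1)

  # covers A fully, misses B -> detection rate 0.5
  segA <- array(0L, dim(ref)); segA[2:4, 2:4, 2:4] <- 1L
  expect_equal(region_metrics(segA, ref)$detection_rate, 0.5)

  # one spurious extra component
  seg2 <- ref; seg2[6, 6, 6] <- 1L  # isolated voxel, 3 seg components
  rm2 <- region_metrics(seg2, ref)
  expect_equal(rm2$region_specificity, 1 - 1 / 3)
})

test_that("descriptive statistics follow the stated formulas", {
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  img <- array(5, c(3, 3, 3))
  d <- descriptive_stats(one, img)
  expect_equal(d$volume_mm3, 1)
  expect_equal(d$surface_mm2, 6)
  expect_equal(d$surface_volume_ratio, 6)
  expect_equal(d$compactness, 6^1.5)
  expect_equal(d$intensity_mean, 5)
  expect_equal(d$intensity_q25, 5)  # constant: quartiles == mean

  # symmetric intensities: zero skewness
  mask <- array(TRUE, c(4, 4, 4))
  sym <- array(rep(c(-2, -1, 1, 2), 16), c(4, 4, 4))
  expect_lt(abs(descriptive_stats(mask, sym)$intensity_skewness), 1e-9)

  expect_error(descriptive_stats(array(0L, c(2, 2, 2)), img), "empty mask")
})

test_that("evaluate_subjects builds the tidy per-subject report", {
  d <- tempfile("ev"); dir.create(d)
  seg_dir <- file.path(d, "out"); dir.create(seg_dir)
  lab <- array(sample(0:2, 6^3, TRUE), c(6, 6, 6))
  rows <- character(0)
  for (s in c("p1", "p2", "p3")) {
    write_tmp_nifti(lab, dir = d, name = paste0(s, "_seg.nii.gz"), section = "label")
    write_tmp_nifti(array(rnorm(6^3), c(6, 6, 6)), dir = d,
                    name = paste0(s, "_img.nii.gz"))
    write_tmp_nifti(lab, dir = seg_dir, name = paste0(s, "_niftynet_out.nii.gz"),
                    section = "label")
  }
  idx <- discover_dataset(d, list(image = "_img", label = "_seg"))
  rep <- evaluate_subjects(idx, seg_dir,
                           list(metrics = c("dice", "jaccard"),
                                csv_path = file.path(d, "report.csv")))
  expect_s3_class(rep, "tbl_df")
  # subjects x labels x metrics rows plus label x metric median rows
  expect_equal(nrow(rep), 3 * 2 * 2 + 2 * 2)
  expect_true(all(rep$value == 1))
  expect_setequal(unique(rep$metric), c("dice", "jaccard"))
  expect_true(file.exists(file.path(d, "report.csv")))
  expect_equal(unique(rep$subject_id[rep$subject_id != "median"]),
               c("p1", "p2", "p3"))

  unlink(file.path(seg_dir, "p2_niftynet_out.nii.gz"))
  expect_error(evaluate_subjects(idx, seg_dir, list(metrics = "dice")), "p2")
})
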