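test_that("load_volume reads shape, spacing and values from NIfTI headers", {
  aff <- diag(c(2, 2, 2, 1))
  p <- write_tmp_nifti(array(rnorm(10 * 12 * 14), c(10, 12, 14)), affine = aff)
  v <- load_volume(p)
  expect_equal(dim(v$data), c(10L, 12L, 14L, 1L, 1L))
  expect_equal(v$spacing, c(2, 2, 2))

  # 4D file: 4th axis is the channel/modality axis
  p4 <- write_tmp_nifti(array(rnorm(4 * 5 * 6 * 3), c(4, 5, 6, 3)))
  v4 <- load_volume(p4)
  expect_equal(dim(v4$data)[5], 3L)
  expect_length(v4$modality_names, 3)

  # integer labels load without value change
  lab <- array(sample(c(0, 1, 4), 60, TRUE), c(5, 4, 3))
  pl <- write_tmp_nifti(lab, section = "label")
  vl <- load_volume(pl, list(section = "label"))
  expect_identical(sort(unique(as.vector(vl$data))), sort(unique(as.vector(lab))))
  expect_equal(as.vector(vl$data), as.vector(lab))

  expect_error(load_volume(tempfile(fileext = ".nii.gz")), "not found")
})

test_that("write then load is the identity on data and affine", {
  aff <- diag(4); aff[1:3, 4] <- c(3, -2, 7); aff[1, 1] <- 1.5
  lab <- array(sample(0:3, 4 * 4 * 4, TRUE), c(4, 4, 4))
  vol <- image_volume(lab, affine = aff, section = "label")
  d <- tempfile("wv"); dir.create(d)
  path <- file.path(d, "lab.nii.gz")
  write_volume(vol, path)
  re <- load_volume(path, list(section = "label"))
  expect_identical(as.vector(re$data), as.vector(vol$data))
  expect_equal(re$affine, aff)

  flo <- image_volume(array(rnorm(60), c(5, 4, 3)), affine = aff)
  pf <- file.path(d, "img.nii.gz")
  write_volume(flo, pf, reference = flo)
  rf <- load_volume(pf)
  expect_lt(max(abs(rf$data - flo$data)), 1e-6)
  expect_equal(rf$affine, aff)
})

test_that("dataset discovery groups files by pattern and flags problems", {
  d <- tempfile("ds"); dir.create(d)
  for (s in c("a", "b")) {
    write_tmp_nifti(array(rnorm(8), c(2, 2, 2)), dir = d, name = paste0(s, "_T1.nii.gz"))
    write_tmp_nifti(array(0, c(2, 2, 2)), dir = d, name = paste0(s, "_seg.nii.gz"))
  }
  idx <- discover_dataset(d, list(image = "_T1", label = "_seg"))
  expect_named(idx$subjects, c("a", "b"))
  expect_named(idx$subjects$a, c("image", "label"))
  expect_equal(idx$section_specs$label$interpolation, "nearest")

  # empty directory -> zero subjects error
  d2 <- tempfile("ds"); dir.create(d2)
  expect_error(discover_dataset(d2, list(image = "_T1")), "zero subjects")

  # incomplete subjects excluded with a warning listing them
  d3 <- tempfile("ds"); dir.create(d3)
  write_tmp_nifti(array(0, c(2, 2, 2)), dir = d3, name = "a_T1.nii.gz")
  write_tmp_nifti(array(0, c(2, 2, 2)), dir = d3, name = "b_T1.nii.gz")
  expect_error(
    expect_warning(discover_dataset(d3, list(image = "_T1", label = "_seg")),
                   "a, b"),
    "zero subjects")

  # ambiguity: two files for one (subject, section)
  d4 <- tempfile("ds"); dir.create(d4)
  write_tmp_nifti(array(0, c(2, 2, 2)), dir = d4, name = "a_T1.nii.gz")
  write_tmp_nifti(array(0, c(2, 2, 2)), dir = d4, name = "a_T1.nii")
  expect_error(discover_dataset(d4, list(image = "_T1")), "ambiguous")
})

test_that("CSV manifests load subjects in row order and validate", {
  d <- tempfile("mf"); dir.create(d)
  for (s in c("s3", "s1", "s2")) {
    write_tmp_nifti(array(0, c(2, 2, 2)), dir = d, name = paste0(s, "_im.nii.gz"))
    write_tmp_nifti(array(0, c(2, 2, 2)), dir = d, name = paste0(s, "_lb.nii.gz"))
  }
  csv <- file.path(d, "manifest.csv")
  writeLines(c("subject_id,image,label",
               sprintf("%s,%s_im.nii.gz,%s_lb.nii.gz", c("s3", "s1", "s2"),
                       c("s3", "s1", "s2"), c("s3", "s1", "s2"))), csv)
  idx <- load_manifest(csv)
  expect_named(idx$subjects, c("s3", "s1", "s2"))  # file order kept

  writeLines(c("subject_id,image", "s1,s1_im.nii.gz", "s1,s2_im.nii.gz"),
             file.path(d, "dup.csv"))
  expect_error(load_manifest(file.path(d, "dup.csv")), "duplicate")

  writeLines(c("subject_id,image", "s2,missing.nii.gz"), file.path(d, "miss.csv"))
  expect_error(load_manifest(file.path(d, "miss.csv")), "s2,image")
})

test_that("reorientation is a pure permutation/flip with a consistent affine", {
  set.seed(4)
  aff <- diag(4); aff[1:3, 4] <- c(10, 20, 30)
  vol <- image_volume(array(rnorm(3 * 4 * 5), c(3, 4, 5)), affine = aff)
  expect_equal(vol$axcodes, c("R", "A", "S"))

  # identity when already in target orientation
  same <- reorient_volume(vol, c("R", "A", "S"))
  expect_identical(same$data, vol$data)

  # flip + permute, then back: involution on voxels
  las <- reorient_volume(vol, c("L", "S", "A"))
  back <- reorient_volume(las, c("R", "A", "S"))
  expect_equal(back$data, vol$data)
  expect_equal(back$affine, vol$affine)

  # world coordinates of a voxel are preserved under reorientation
  idx <- c(2, 3, 4)  # 1-based
  w0 <- vol$affine %*% c(idx - 1, 1)
  v0 <- vol$data[idx[1], idx[2], idx[3], 1, 1]
  # find the same world point in the reoriented volume
  inv <- solve(las$affine) %*% w0
  ridx <- round(inv[1:3]) + 1
  expect_equal(las$data[ridx[1], ridx[2], ridx[3], 1, 1], v0)

  # channel concatenation
  v1 <- image_volume(array(1, c(2, 2, 2)), modality_names = "t1")
  v2 <- image_volume(array(2, c(2, 2, 2)), modality_names = "t2")
  both <- reorient_and_concat(list(v1, v2), c("R", "A", "S"))
  expect_equal(dim(both$data)[5], 2L)
  expect_equal(both$modality_names, c("t1", "t2"))
  expect_equal(as.vector(both$data[, , , , 1]), rep(1, 8))
  expect_equal(as.vector(both$data[, , , , 2]), rep(2, 8))
})
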