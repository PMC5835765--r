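test_that("mask_volume counts labeled voxels scaled by the affine", {
  img <- make_label_image(rep(1, 10))
  expect_equal(mask_volume(img, 1), 10)
  # anisotropic voxels 0.5 x 0.5 x 1.0 mm
  img2 <- make_label_image(rep(2, 100), dim = c(5, 5, 5),
                           affine = diag(c(0.5, 0.5, 1, 1)))
  expect_equal(mask_volume(img2, 2), 25)
  # multiple target labels are pooled
  img3 <- make_label_image(c(rep(1, 4), rep(2, 6)))
  expect_equal(mask_volume(img3, c(1, 2)), 10)
  expect_warning(res <- mask_volume(img, 99), "no voxels")
  expect_equal(res, 0)
  bad <- make_label_image(rep(1, 5), affine = diag(c(1, 1, 0, 1)))
  expect_error(mask_volume(bad, 1), "non-invertible",
               class = "fcdsre_volumetry_error")
  expect_error(mask_volume(img, integer(0)),
               class = "fcdsre_volumetry_error")
})

test_that("a rotated affine with identical voxel volume leaves the result unchanged", {
  set.seed(11)
  for (i in 1:5) {
    labels <- sample(0:2, 60, replace = TRUE)
    vox <- runif(3, 0.4, 2)
    aff0 <- diag(c(vox, 1))
    aff_rot <- diag(4)
    aff_rot[1:3, 1:3] <- rot_z(runif(1, 0.1, 3)) %*% diag(vox)
    img0 <- make_label_image(labels, dim = c(4, 5, 3), affine = aff0)
    img1 <- make_label_image(labels, dim = c(4, 5, 3), affine = aff_rot)
    # axis-aligned oracle: voxel count times product of voxel sizes
    expect_equal(mask_volume(img0, 1), sum(labels == 1) * prod(vox))
    expect_equal(mask_volume(img1, 1), mask_volume(img0, 1))
  }
})

test_that("mask volumes are additive over a label partition", {
  set.seed(21)
  labels <- sample(1:4, 80, replace = TRUE)
  img <- make_label_image(labels, dim = c(4, 4, 5),
                          affine = diag(c(0.7, 1.3, 1.1, 1)))
  parts <- sum(vapply(1:4, function(l) mask_volume(img, l), numeric(1)))
  expect_equal(parts, mask_volume(img, 1:4))
})

test_that("NIfTI label maps round-trip through read_label_map", {
  f <- withr::local_tempfile(fileext = ".nii.gz")
  arr <- array(0L, dim = c(6, 6, 6))
  arr[1:30] <- 10L
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(0.94, 0.94, 1)
  RNifti::writeNifti(img, f)
  vol <- mask_volume(read_label_map(f), 10)
  expect_equal(vol, 30 * 0.94 * 0.94 * 1, tolerance = 1e-4)
})

test_that("ICV normalization identities and homogeneity hold", {
  # identity when the subject ICV equals the cohort mean
  expect_equal(normalize_volume(1234.5, 1.4e6, 1.4e6), 1234.5)
  expect_equal(normalize_volume(1000, 1.5e6, 1.4e6), 1000 * 1.4 / 1.5)
  # doubling ICV halves the result
  expect_equal(normalize_volume(1000, 2 * 1.5e6, 1.4e6),
               normalize_volume(1000, 1.5e6, 1.4e6) / 2)
  expect_error(normalize_volume(-1, 1e6, 1e6), class = "fcdsre_domain_error")
  expect_error(normalize_volume(1, 0, 1e6), class = "fcdsre_domain_error")
  # normalizing ICV itself: every subject maps to the mean, so the cohort
  # mean normalized ICV equals the mean ICV exactly
  icv <- c(1.3e6, 1.45e6, 1.6e6)
  expect_identical(mean(normalize_volume(icv, icv, mean(icv))), mean(icv))
  # normalization preserves within-subject volume ordering
  raws <- c(500, 1500, 7000)
  norm <- normalize_volume(raws, 1.52e6, 1.44e6)
  expect_identical(order(norm), order(raws))
})

test_that("log10_volume evaluates and is monotone", {
  expect_equal(log10_volume(1000), 3)
  expect_equal(log10_volume(3217), 3.5074512, tolerance = 1e-7)
  v <- sort(runif(20, 1, 1e5))
  expect_true(all(diff(log10_volume(v)) > 0))
  expect_error(log10_volume(0), class = "fcdsre_domain_error")
})

test_that("thalamus side mapping is correct and symmetric", {
  expect_equal(thalamus_sides(7000, 7500, "left"),
               tibble::tibble(ipsi_mm3 = 7000, contra_mm3 = 7500))
  expect_equal(thalamus_sides(7000, 7500, "right"),
               tibble::tibble(ipsi_mm3 = 7500, contra_mm3 = 7000))
  # swapping hemispheres and flipping the side leaves (ipsi, contra) fixed
  expect_equal(thalamus_sides(7500, 7000, "right"),
               thalamus_sides(7000, 7500, "left"))
  expect_error(thalamus_sides(1, 2, NA), class = "fcdsre_domain_error")
})

test_that("cohort mean ICV respects its scope", {
  fx <- paper_fixture()
  expect_equal(cohort_mean_icv(fx, "all"), mean(fx$icv_mm3))
  meas <- !is.na(fx$lesion_volume_mm3)
  expect_equal(cohort_mean_icv(fx, "measurable"), mean(fx$icv_mm3[meas]))
  # the two scopes differ only through the excluded patients
  expect_equal(cohort_mean_icv(fx, "all") * 77 -
                 cohort_mean_icv(fx, "measurable") * 75,
               sum(fx$icv_mm3[!meas]))
  same <- fx; same$icv_mm3 <- 1.45e6
  expect_equal(cohort_mean_icv(same, "all"), 1.45e6)
})

test_that("add_volume_norms derives normalized and log columns", {
  fx <- paper_fixture()
  out <- add_volume_norms(fx, volumes_are = "raw")
  micv <- mean(fx$icv_mm3)
  i <- which(!is.na(fx$lesion_volume_mm3))[1]
  expect_equal(out$lesion_norm_mm3[i],
               fx$lesion_volume_mm3[i] * micv / fx$icv_mm3[i])
  expect_equal(out$lesion_log10[i], log10(out$lesion_norm_mm3[i]))
  # "normalized" mode copies volumes through unchanged
  out2 <- add_volume_norms(fx, volumes_are = "normalized")
  expect_equal(out2$lesion_norm_mm3, fx$lesion_volume_mm3)
  # thalamic ipsi/contra follow the lesion side
  left <- fx$side == "left"
  expect_equal(out2$thal_ipsi_norm_mm3[left], fx$thal_left_mm3[left])
})
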