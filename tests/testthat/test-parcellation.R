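# Volumetric preprocessing: smoothing, grayscale rescale, region extraction,
# whole-brain normalization.

test_that("smoothing leaves a constant volume unchanged", {
  img <- volume_image(array(7, c(8, 8, 8)), voxel_size_mm = c(2, 2, 2))
  out <- smooth_volume(img, c(10, 10, 10))
  expect_equal(out$values, img$values, tolerance = 1e-10)
})

test_that("impulse response matches the discretized separable kernel", {
  # grid large enough that the truncated kernel (radius 9 voxels) stays
  # interior, so total intensity is conserved
  v <- array(0, c(21, 21, 21))
  v[11, 11, 11] <- 1
  img <- volume_image(v, voxel_size_mm = c(2, 2, 2))
  out <- smooth_volume(img, c(10, 10, 10))
  # independent evaluation of the discrete Gaussian central weight
  sigma <- 10 / (2 * sqrt(8 * log(2)))
  x <- (-ceiling(4 * sigma)):ceiling(4 * sigma)
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  w0 <- w[x == 0]
  expect_equal(out$values[11, 11, 11], w0^3, tolerance = 1e-12)
  # total intensity conserved for an interior impulse
  expect_equal(sum(out$values), 1, tolerance = 1e-6)
})

test_that("grayscale rescale maps linearly onto [lo, hi]", {
  v <- array(c(0, 5, 10, 0, 5, 10, 0, 10), c(2, 2, 2))
  out <- rescale_grayscale(volume_image(v))
  expect_setequal(unique(as.numeric(out$values)), c(0, 127.5, 255))
  # already spanning [0, 255]: identity
  v2 <- array(seq(0, 255, length.out = 27), c(3, 3, 3))
  expect_equal(rescale_grayscale(volume_image(v2))$values, v2, tolerance = 1e-12)
  # constant volume maps to lo
  v3 <- array(42, c(3, 3, 3))
  expect_true(all(rescale_grayscale(volume_image(v3))$values == 0))
  # monotone: ordering of voxel intensities is preserved
  set.seed(1)
  v4 <- array(rnorm(27), c(3, 3, 3))
  out4 <- rescale_grayscale(volume_image(v4))
  expect_identical(order(as.numeric(v4)), order(as.numeric(out4$values)))
})

test_that("region means are arithmetic means over labelled voxels", {
  labs <- array(0L, c(2, 2, 2))
  labs[1:4] <- 1L; labs[5:6] <- 2L
  atlas <- atlas_parcellation(labs)
  v <- array(0, c(2, 2, 2))
  v[1:4] <- c(1, 2, 3, 4); v[5:6] <- c(10, 20)
  expect_equal(extract_region_means(volume_image(v), atlas), c(2.5, 15))
  # constant volume: every region mean is the constant
  expect_equal(extract_region_means(volume_image(array(3, c(2, 2, 2))), atlas),
               c(3, 3))
  # shape mismatch is a parameter error
  expect_error(extract_region_means(volume_image(array(0, c(3, 3, 3))), atlas),
               "does not match")
})

test_that("whole-brain normalization is the stated affine map", {
  expect_equal(normalize_subject_signals(c(8, 10, 12), 10, 2), c(-1, 0, 1))
  expect_equal(normalize_subject_signals(c(5, 5, 5), 5, 3), c(0, 0, 0))
  expect_error(normalize_subject_signals(1:3, 0, 0), "brain_sd")
})

test_that("normalized region vectors are invariant to per-subject intensity scale", {
  atlas <- make_toy_atlas(c(12, 12, 12), 10, seed = 1)
  cohort <- sample_region_matrix(build_group_covariance(10, backbone_degree = 4),
                                 6, seed = 2)
  vols <- render_subject_volumes(cohort, atlas, noise_sd = 0.5, seed = 3)
  scaled <- lapply(vols, function(v) volume_image(v$values * 3.7, v$voxel_size_mm))
  for (stats_mode in c("regions", "voxels")) {
    a <- volumes_to_region_matrix(vols, atlas, brain_stats = stats_mode)
    b <- volumes_to_region_matrix(scaled, atlas, brain_stats = stats_mode)
    expect_equal(a$values, b$values, tolerance = 1e-10)
  }
})

test_that("direct and rendered paths give the same group network at zero noise", {
  spec <- build_group_covariance(15, backbone_degree = 4)
  cohort <- sample_region_matrix(spec, 10, seed = 4)
  atlas <- make_toy_atlas(c(12, 12, 12), 15, seed = 5)
  vols <- render_subject_volumes(cohort, atlas, noise_sd = 0, seed = 6)
  direct <- normalize_region_matrix(cohort)
  rendered <- volumes_to_region_matrix(vols, atlas)
  expect_equal(rendered$values, direct$values, tolerance = 1e-10)
  net_d <- partial_correlation_matrix(direct)
  net_r <- partial_correlation_matrix(rendered)
  expect_equal(net_r$R, net_d$R, tolerance = 1e-10)
})

test_that("reference-region scaling yields SUVR-like ratios, normalization unaffected", {
  atlas <- make_toy_atlas(c(12, 12, 12), 8, seed = 9)
  cohort <- sample_region_matrix(build_group_covariance(8, backbone_degree = 4),
                                 5, seed = 10)
  vols <- render_subject_volumes(cohort, atlas, noise_sd = 0, seed = 11)
  raw <- volumes_to_region_matrix(vols, atlas, normalize = FALSE,
                                  reference_region = 3)
  expect_equal(unname(raw$values[, 3]), rep(1, 5))  # reference ratio is 1
  plain <- volumes_to_region_matrix(vols, atlas, normalize = FALSE)
  expect_equal(raw$values, plain$values / plain$values[, 3], tolerance = 1e-12)
  # z-normalization is invariant to the per-subject reference scale
  z_ref <- volumes_to_region_matrix(vols, atlas, reference_region = 3)
  z_plain <- volumes_to_region_matrix(vols, atlas)
  expect_equal(z_ref$values, z_plain$values, tolerance = 1e-10)
  expect_error(volumes_to_region_matrix(vols, atlas, reference_region = 99),
               "not an atlas region")
})

test_that("NIfTI round trip preserves volumes and atlas labels", {
  tmp <- withr::local_tempdir()
  img <- volume_image(array(rnorm(64), c(4, 4, 4)), voxel_size_mm = c(2, 2, 3))
  p <- file.path(tmp, "vol.nii.gz")
  write_volume_nifti(img, p)
  back <- read_volume_nifti(p)
  expect_equal(back$values, img$values, tolerance = 1e-6)
  expect_equal(back$voxel_size_mm, img$voxel_size_mm)
  atlas <- make_toy_atlas(c(10, 10, 10), 5, seed = 1)
  pa <- file.path(tmp, "atlas.nii.gz")
  write_atlas_nifti(atlas, pa)
  expect_identical(read_atlas_nifti(pa)$labels, atlas$labels)
})
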