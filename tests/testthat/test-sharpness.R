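test_that("gradient magnitude matches analytic fields and the loop oracle", {
  # constant slice: zero gradient
  expect_true(all(gradient_magnitude(matrix(7, 5, 5), c(1, 1)) == 0))

  # ramp a*x with x in mm: interior magnitude = a
  sp <- c(0.7, 1.3)
  xs <- (0:9) * sp[1]
  ramp <- outer(xs, rep(1, 8)) * 4.2
  gm <- gradient_magnitude(ramp, sp)
  expect_equal(gm[2:9, ], matrix(4.2, 8, 8), tolerance = 1e-12)

  # random slices equal the brute-force oracle elementwise
  set.seed(5)
  for (i in 1:20) {
    sl <- matrix(rnorm(25, 0, 200), 5, 5)
    expect_equal(gradient_magnitude(sl, sp), oracle_gradmag(sl, sp),
                 tolerance = 1e-12)
  }
  expect_error(gradient_magnitude(matrix(0, 2, 5), c(1, 1)))
})

test_that("significant-edge mask selects the high gradient class", {
  set.seed(8)
  gm <- matrix(0.1, 30, 30)
  hi <- sample(900, 90)
  gm[hi] <- 10
  roi <- matrix(TRUE, 30, 30)
  mask <- significant_edge_mask(gm, roi)
  expect_identical(which(mask), sort(hi))
  expect_true(all(mask <= roi))

  # all-zero gradient: empty mask with a warning, not an error
  expect_warning(m0 <- significant_edge_mask(matrix(0, 10, 10), roi[1:10, 1:10]),
                 "constant")
  expect_false(any(m0))
  expect_error(significant_edge_mask(gm, matrix(FALSE, 30, 30)), "empty ROI")
})

test_that("slice sharpness sums or averages masked gradient magnitudes", {
  gm <- matrix(0, 4, 4)
  gm[1:3] <- c(1, 2, 2)
  mask <- matrix(FALSE, 4, 4)
  mask[1:3] <- TRUE
  expect_equal(slice_sharpness(gm, mask), 5)
  expect_equal(slice_sharpness(gm, mask, normalization = "mean"), 5 / 3)
  expect_equal(slice_sharpness(gm, matrix(FALSE, 4, 4)), 0)
  expect_error(slice_sharpness(gm, mask[1:3, 1:3]), "shape")
})

test_that("full slice metric equals a straight-line brute-force computation", {
  set.seed(13)
  for (i in 1:5) {
    slice <- matrix(rnorm(32 * 32, 0, 100), 32, 32) +
      outer(seq(0, 300, length.out = 32), seq(0, 100, length.out = 32), `+`)
    roi <- matrix(runif(32 * 32) > 0.2, 32, 32)
    sp <- c(0.43, 0.43)
    gm <- gradient_magnitude(slice, sp)
    edge <- significant_edge_mask(gm, roi)
    ours <- slice_sharpness(gm, edge)
    expect_equal(ours, oracle_slice_metric(slice, roi, sp),
                 tolerance = 1e-9)
  }
})

test_that("sharpness is shift-invariant and scale-equivariant", {
  pair <- small_pair(noise_sd = 0, n_slices = 2L)
  vol <- pair$small
  masks <- build_mask_set(vol)
  gm <- fovsharp:::gradient_magnitude_volume(vol)
  edge <- significant_edge_mask(gm, masks$analysis_roi)
  base <- sharpness_profile(vol, edge)

  # constant HU offset: gradients, edges and scores unchanged (exact)
  shifted <- ct_volume(vol$values + 250, vol$geometry)
  gm2 <- fovsharp:::gradient_magnitude_volume(shifted)
  expect_equal(gm, gm2, tolerance = 1e-12)
  expect_identical(significant_edge_mask(gm2, masks$analysis_roi), edge)
  expect_equal(sharpness_profile(shifted, edge)$sharpness, base$sharpness,
               tolerance = 1e-12)

  # positive scaling c: scores scale by c exactly (Otsu scales with the data)
  c0 <- 2.7
  scaled <- ct_volume(vol$values * c0, vol$geometry)
  gm3 <- fovsharp:::gradient_magnitude_volume(scaled)
  edge3 <- significant_edge_mask(gm3, masks$analysis_roi)
  expect_identical(edge3, edge)
  expect_equal(sharpness_profile(scaled, edge3)$sharpness,
               c0 * base$sharpness, tolerance = 1e-12)
})

test_that("sharpness strictly decreases with increasing Gaussian blur", {
  ph <- small_phantom(n_slices = 1L)
  tr <- render_phantom(ph)
  recs <- lapply(c(0.2, 0.5, 1.0, 2.0), function(fw) {
    simulate_reconstruction(
      tr, recon_spec(83.3, matrix = 128, psf_fwhm = fw, aperture_k = 0,
                     noise_sd = 0))
  })
  masks <- build_mask_set(recs[[1]])
  gm1 <- fovsharp:::gradient_magnitude_volume(recs[[1]])
  edge <- significant_edge_mask(gm1, masks$analysis_roi)
  vals <- vapply(recs, function(r) {
    sharpness_profile(r, edge)$sharpness[1]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("pair comparison enforces contracts and flags sharper volumes", {
  pair <- small_pair(noise_sd = 0, n_slices = 3L)
  masks <- build_mask_set(pair$small)
  al <- align_pair(pair$large, pair$small)

  # simulated pair: every slice difference positive, one-sided p small
  cmp <- compare_pair(al$small, al$large_resampled, masks)
  expect_true(all(cmp$per_slice$difference > 0))
  expect_gt(cmp$mean_difference, 0)

  # self-comparison: zero differences, test skipped
  self <- compare_pair(pair$small, pair$small, masks)
  expect_equal(self$mean_difference, 0)
  expect_true(is.na(self$p_value))

  # geometry contract
  expect_error(compare_pair(pair$small, pair$large, masks), "share a grid")

  # tidy/glance accessors
  expect_s3_class(tidy(cmp), "tbl_df")
  expect_named(glance(cmp), c("mean_difference", "small_mean", "large_mean",
                              "statistic", "p_value", "n_slices"))
})
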