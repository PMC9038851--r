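test_that("identity resample reproduces the input", {
  set.seed(21)
  vol <- vol_from_array(array(rnorm(16 * 14 * 2, 100, 300), c(16, 14, 2)),
                        spacing = c(1.5, 2), slice_spacing = 1,
                        origin = c(-3, 5, 0))
  for (ord in c(0L, 1L, 2L, 3L, 4L, 5L)) {
    out <- resample_to_grid(vol, vol$geometry, spline_order = ord)
    expect_equal(out$values, vol$values, tolerance = 1e-6)
  }
  expect_error(resample_to_grid(vol, vol$geometry, spline_order = 7), "0..5")
})

test_that("cubic resampling reproduces polynomials up to total degree 3", {
  g_src <- grid_geometry(c(14, 12), 1, 2, 1, origin = c(0, 0, 0))
  xs <- grid_coords(g_src, 1)
  ys <- grid_coords(g_src, 2)
  poly <- function(x, y) 0.5 * x^3 - 0.02 * x * y^2 + 2 * y^2 - 3 * x * y +
    4 * x - 7 * y + 20
  src <- vol_from_array(outer(xs, ys, poly), spacing = c(2, 2))

  # 2x finer target covering the interior
  g_tgt <- grid_geometry(c(17, 15), 1, 1, 1, origin = c(5, 4, 0))
  out <- resample_to_grid(src, g_tgt, spline_order = 3)
  expected <- outer(grid_coords(g_tgt, 1), grid_coords(g_tgt, 2), poly)
  expect_equal(out$values[, , 1], expected, tolerance = 1e-6)

  # linear interpolation reproduces degree-1 only
  lin <- function(x, y) 3 * x + 2 * y + 1
  src1 <- vol_from_array(outer(xs, ys, lin), spacing = c(2, 2))
  out1 <- resample_to_grid(src1, g_tgt, spline_order = 1)
  expect_equal(out1$values[, , 1],
               outer(grid_coords(g_tgt, 1), grid_coords(g_tgt, 2), lin),
               tolerance = 1e-9)
})

test_that("constant volumes stay constant and out-of-extent voxels are air", {
  src <- vol_from_array(array(100, c(10, 10, 1)), spacing = c(1, 1))
  tgt <- grid_geometry(c(30, 30), 1, 1, 1, origin = c(-10, -10, 0))
  out <- resample_to_grid(src, tgt, spline_order = 3)
  valid <- attr(out, "valid")
  expect_true(all(abs(out$values[valid] - 100) < 1e-6))
  expect_true(all(out$values[!valid] == -1000))
  expect_error(resample_to_grid(
    src, grid_geometry(c(10, 10), 1, 1, 1, origin = c(0, 0, 5))
  ), "slice position")
})

test_that("align_pair puts the large-FOV volume on the small grid", {
  pair <- small_pair(noise_sd = 0, n_slices = 2L)
  al <- align_pair(pair$large, pair$small)
  expect_equal(al$out_of_extent_fraction, 0)
  expect_true(geometry_equal <- identical(
    al$large_resampled$geometry$matrix_size,
    pair$small$geometry$matrix_size
  ))
  # swapped order: permitted (given a tolerant extent bound) but warns about
  # the resolution-losing direction
  w <- testthat::capture_warnings(
    align_pair(pair$small, pair$large, max_out_of_extent = 1)
  )
  expect_match(w, "smaller FOV", all = FALSE)
  # at the default bound the out-of-extent fraction escalates to an error
  expect_error(suppressWarnings(align_pair(pair$small, pair$large)),
               "outside the source extent")
  # identical volumes in, identical values out
  self <- align_pair(pair$small, pair$small)
  expect_equal(self$large_resampled$values, pair$small$values,
               tolerance = 1e-6)
})

test_that("resampling cannot create sharpness beyond the source", {
  # blur-matched, noise-free pair: resampled large-FOV never beats native small
  pair <- small_pair(noise_sd = 0, n_slices = 2L)
  masks <- build_mask_set(pair$small)
  al <- align_pair(pair$large, pair$small)
  cmp <- compare_pair(al$small, al$large_resampled, masks)
  expect_true(all(cmp$per_slice$difference > 0))
})
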