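test_that("body-only phantom renders soft tissue inside, air outside", {
  spec <- phantom_spec(
    body = list(center = c(0, 0), semi_axes = c(20, 15), hu = 40),
    bones = tibble::tibble(cx = numeric(), cy = numeric(), r = numeric(),
                           hu = numeric()),
    vessels = tibble::tibble(cx = numeric(), cy = numeric(), r = numeric(),
                             hu = numeric()),
    calcifications = tibble::tibble(vessel = integer(), theta0 = numeric(),
                                    theta1 = numeric(), thickness = numeric(),
                                    hu = numeric()),
    n_slices = 2L
  )
  tr <- render_phantom(spec)
  inside <- ellipse_mask_on(tr$geometry, c(0, 0), c(20, 15))
  expect_true(all(tr$values[inside] == 40))
  expect_true(all(tr$values[!inside] == -1000))
})

test_that("rendered vessel area matches the analytic circle area", {
  spec <- phantom_spec(
    body = list(center = c(0, 0), semi_axes = c(20, 15), hu = 40),
    bones = tibble::tibble(cx = numeric(), cy = numeric(), r = numeric(),
                           hu = numeric()),
    vessels = tibble::tibble(cx = 3, cy = -5, r = 2, hu = 350),
    calcifications = tibble::tibble(vessel = integer(), theta0 = numeric(),
                                    theta1 = numeric(), thickness = numeric(),
                                    hu = numeric()),
    n_slices = 1L
  )
  sp <- 0.05
  tr <- render_phantom(spec, oversample_spacing = sp)
  n_vessel <- sum(tr$values == 350)
  expect_equal(n_vessel * sp^2, pi * 2^2, tolerance = 0.02)
})

test_that("calcification layer overwrites the vessel lumen where they overlap", {
  spec <- small_phantom(n_slices = 1L)
  tr <- render_phantom(spec)
  # wall band of vessel 1 within the arc: expect 800 HU present
  expect_true(any(tr$values == 800))
  # calcified voxels sit on the vessel wall (within r of the centre)
  xs <- grid_coords(tr$geometry, 1)
  ys <- grid_coords(tr$geometry, 2)
  idx <- which(tr$values[, , 1] == 800, arr.ind = TRUE)
  d <- sqrt((xs[idx[, 1]] - spec$vessels$cx[1])^2 +
              (ys[idx[, 2]] - spec$vessels$cy[1])^2)
  expect_true(all(d <= spec$vessels$r[1] + 1e-9))
  expect_true(all(d >= spec$vessels$r[1] - spec$calcifications$thickness[1] - 1e-9))
})

test_that("invalid phantoms are rejected", {
  expect_error(
    phantom_spec(vessels = tibble::tibble(cx = 0, cy = -38, r = 0.1, hu = 350)),
    "radii"
  )
  expect_error(
    phantom_spec(bones = tibble::tibble(cx = 100, cy = 0, r = 10, hu = 1200)),
    "outside body"
  )
  expect_error(render_phantom(small_phantom(), oversample_spacing = 0.2),
               "0.1 mm")
})

test_that("random phantoms are reproducible and valid", {
  a <- random_phantom_spec(7)
  b <- random_phantom_spec(7)
  expect_identical(a, b)
  expect_false(identical(random_phantom_spec(8), a))
  for (s in 1:5) {
    ph <- random_phantom_spec(s)
    expect_s3_class(ph, "phantom_spec")
    expect_true(all(ph$vessels$r >= 0.3 & ph$vessels$r <= 6))
  }
})
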