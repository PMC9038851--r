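# Small fixtures built in code.

# compact leg phantom for fast segmentation / sharpness tests
small_phantom <- function(n_slices = 3L, calc = TRUE) {
  phantom_spec(
    body = list(center = c(0, 0), semi_axes = c(30, 25), hu = 40),
    bones = tibble::tibble(cx = c(-8, 12), cy = c(3, 5), r = c(6, 3), hu = 1200),
    vessels = tibble::tibble(
      cx = c(0, 7), cy = c(-14, -10), r = c(2.5, 1.2), hu = 350,
      drift_x = c(0.2, -0.15), drift_y = c(0.1, 0.2)
    ),
    calcifications = if (calc) {
      tibble::tibble(vessel = 1L, theta0 = 0.5, theta1 = 1.6,
                     thickness = 0.7, hu = 800)
    } else {
      tibble::tibble(vessel = integer(), theta0 = numeric(),
                     theta1 = numeric(), thickness = numeric(), hu = numeric())
    },
    n_slices = n_slices, slice_spacing = 2
  )
}

# reconstruction pair of the compact phantom at a reduced matrix: FOV ratio
# matches the study (423 : 220 ~ 1.92) at test-friendly sizes
small_pair <- function(noise_sd = 0, n_slices = 3L, matrix = 128L,
                       seed = 1L, calc = TRUE) {
  simulate_recon_pair(
    small_phantom(n_slices = n_slices, calc = calc),
    fov_large = 160, fov_small = 83.3, matrix = matrix,
    noise_sd = noise_sd, seed = seed
  )
}

# volume wrapper for hand-built arrays
vol_from_array <- function(a, spacing = c(1, 1), slice_spacing = 1,
                           origin = c(0, 0, 0), id = "test") {
  if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
  ct_volume(a, grid_geometry(dim(a)[1:2], dim(a)[3], spacing, slice_spacing,
                             origin = origin), id = id)
}

# analytic ellipse mask on a volume's grid
ellipse_mask_on <- function(geom, center, semi_axes) {
  xs <- grid_coords(geom, 1)
  ys <- grid_coords(geom, 2)
  m2 <- outer(((xs - center[1]) / semi_axes[1])^2,
              ((ys - center[2]) / semi_axes[2])^2, `+`) <= 1
  array(rep(m2, geom$n_slices), c(geom$matrix_size, geom$n_slices))
}

# analytic union-of-circles mask on a volume's grid
circles_mask_on <- function(geom, circles) {
  xs <- grid_coords(geom, 1)
  ys <- grid_coords(geom, 2)
  m2 <- matrix(FALSE, length(xs), length(ys))
  for (i in seq_len(nrow(circles))) {
    m2 <- m2 | (outer((xs - circles$cx[i])^2, (ys - circles$cy[i])^2, `+`) <=
                  circles$r[i]^2)
  }
  array(rep(m2, geom$n_slices), c(geom$matrix_size, geom$n_slices))
}
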