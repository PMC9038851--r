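#' Parametric digital leg phantom
#'
#' Describes an axial cross-section of a contrast-enhanced lower-extremity CT:
#' a soft-tissue body ellipse, cortical bone circles (tibia/fibula calibre),
#' contrast-filled vessel circles spanning femoral-to-pedal diameters, and
#' optional mural calcification arcs on vessel walls. Structures are painted
#' in listed order with later structures overwriting earlier ones, so
#' calcifications (listed last) overwrite the vessel lumen where they overlap.
#'
#' Vessels may drift in-plane from slice to slice (`drift_x`/`drift_y`, mm per
#' slice) so that consecutive slices are correlated but not identical, as in a
#' real run-off acquisition.
#'
#' @param body list with `center` (mm, length 2), `semi_axes` (mm, length 2)
#'   and `hu` (default 40, soft tissue).
#' @param bones tibble/data.frame with columns `cx, cy, r, hu` (mm, mm, mm,
#'   HU; default cortical bone 1200 HU).
#' @param vessels tibble with columns `cx, cy, r, hu, drift_x, drift_y`;
#'   radii must lie in [0.3, 6] mm (femoral-to-pedal calibre), enhancement
#'   about 350 HU.
#' @param calcifications tibble with columns `vessel` (row index into
#'   `vessels`), `theta0, theta1` (radians, arc extent on the wall),
#'   `thickness` (mm, radial) and `hu` (default 800).
#' @param n_slices number of axial slices.
#' @param slice_spacing mm between slices.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(body = list(center = c(0, 0), semi_axes = c(80, 70), hu = 40),
                         bones = default_bones(),
                         vessels = default_vessels(),
                         calcifications = default_calcifications(),
                         n_slices = 5L,
                         slice_spacing = 2) {
  bones <- tibble::as_tibble(bones)
  vessels <- tibble::as_tibble(vessels)
  calcifications <- tibble::as_tibble(calcifications)
  if (!all(c("cx", "cy", "r", "hu") %in% names(bones))) {
    stop("`bones` needs columns cx, cy, r, hu")
  }
  if (!all(c("cx", "cy", "r", "hu") %in% names(vessels))) {
    stop("`vessels` needs columns cx, cy, r, hu")
  }
  if (!"drift_x" %in% names(vessels)) vessels$drift_x <- 0
  if (!"drift_y" %in% names(vessels)) vessels$drift_y <- 0
  if (nrow(vessels) > 0 && (any(vessels$r < 0.3) || any(vessels$r > 6))) {
    stop("vessel radii must lie in [0.3, 6] mm")
  }
  spec <- structure(
    list(body = body, bones = bones, vessels = vessels,
         calcifications = calcifications,
         n_slices = as.integer(n_slices),
         slice_spacing = as.numeric(slice_spacing)),
    class = "phantom_spec"
  )
  check_structures_in_body(spec)
  spec
}

default_bones <- function() {
  tibble::tibble(
    cx = c(-22, 32), cy = c(8, 14), r = c(14, 7), hu = 1200
  )
}

default_vessels <- function() {
  tibble::tibble(
    cx = c(0, 18, -16, 8),
    cy = c(-38, -28, -33, 35),
    r = c(3.2, 2.0, 1.3, 0.8),
    hu = 350,
    drift_x = c(0.3, -0.2, 0.25, -0.15),
    drift_y = c(0.2, 0.3, -0.2, 0.1)
  )
}

default_calcifications <- function() {
  tibble::tibble(
    vessel = 1L, theta0 = 0.4, theta1 = 1.8, thickness = 0.8, hu = 800
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "<phantom_spec> body %g x %g mm, %d bones, %d vessels, %d calcifications, %d slices\n",
    2 * x$body$semi_axes[1], 2 * x$body$semi_axes[2],
    nrow(x$bones), nrow(x$vessels), nrow(x$calcifications), x$n_slices
  ))
  invisible(x)
}

# every structure centre + radius must fit inside the body ellipse at every
# slice position (drift included)
check_structures_in_body <- function(spec) {
  b <- spec$body
  inside <- function(cx, cy, r) {
    # conservative: circle centre scaled into the unit disc with radius margin
    dx <- (cx - b$center[1]) / (b$semi_axes[1] - r)
    dy <- (cy - b$center[2]) / (b$semi_axes[2] - r)
    all(b$semi_axes - r > 0) && all(dx^2 + dy^2 <= 1)
  }
  for (i in seq_len(nrow(spec$bones))) {
    with(spec$bones[i, ], if (!inside(cx, cy, r)) stop("bone outside body ellipse"))
  }
  kmax <- spec$n_slices - 1L
  for (i in seq_len(nrow(spec$vessels))) {
    v <- spec$vessels[i, ]
    for (k in c(0L, kmax)) {
      if (!inside(v$cx + k * v$drift_x, v$cy + k * v$drift_y, v$r)) {
        stop("vessel (with drift) outside body ellipse")
      }
    }
  }
  invisible(TRUE)
}

#' Randomised leg phantom
#'
#' Samples vessel count, positions, calibres and per-slice drift inside the
#' body ellipse under a fixed integer seed; bone geometry is jittered
#' slightly. Used to generate independent phantom realisations for
#' population-level checks of the sharpness pipeline.
#'
#' @param seed integer seed; every random draw flows from it.
#' @param n_vessels number of vessels (default 4).
#' @param n_slices,slice_spacing passed to [phantom_spec()].
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, n_vessels = 4L, n_slices = 5L,
                                slice_spacing = 2) {
  with_local_seed(seed, {
    body <- list(center = c(0, 0), semi_axes = c(80, 70), hu = 40)
    bones <- tibble::tibble(
      cx = c(-22, 32) + stats::runif(2, -4, 4),
      cy = c(8, 14) + stats::runif(2, -4, 4),
      r = c(14, 7) * stats::runif(2, 0.9, 1.1),
      hu = 1200
    )
    # vessels in the posterior soft tissue, clear of the bones
    vessels <- tibble::tibble(
      cx = stats::runif(n_vessels, -45, 45),
      cy = stats::runif(n_vessels, -55, -20),
      r = stats::runif(n_vessels, 0.8, 4.0),
      hu = 350,
      drift_x = stats::runif(n_vessels, -0.4, 0.4),
      drift_y = stats::runif(n_vessels, -0.4, 0.4)
    )
    calcifications <- tibble::tibble(
      vessel = 1L,
      theta0 = stats::runif(1, 0, pi),
      theta1 = NA_real_, thickness = 0.8, hu = 800
    )
    calcifications$theta1 <- calcifications$theta0 + stats::runif(1, 0.8, 1.6)
    phantom_spec(body, bones, vessels, calcifications,
                 n_slices = n_slices, slice_spacing = slice_spacing)
  })
}

#' Render a phantom to a high-resolution ground-truth volume
#'
#' Rasterises the phantom onto an oversampled grid (default 0.1 mm) covering
#' the body ellipse plus a margin of air. Each voxel takes the HU of the last
#' listed structure containing its centre. The rendered volume carries the
#' body bounding box as an attribute so that reconstruction coverage can be
#' checked downstream.
#'
#' @param spec a [phantom_spec()].
#' @param oversample_spacing grid spacing in mm, must be <= 0.1 (well above
#'   the target reconstruction resolutions).
#' @param margin_mm width of the air margin around the body (default 10).
#' @return A [ct_volume()] at the oversampled resolution.
#' @export
render_phantom <- function(spec, oversample_spacing = 0.1, margin_mm = 10) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (oversample_spacing > 0.1) {
    stop("`oversample_spacing` must be <= 0.1 mm for a faithful ground truth")
  }
  b <- spec$body
  half <- b$semi_axes + margin_mm
  nx <- ceiling(2 * half[1] / oversample_spacing)
  ny <- ceiling(2 * half[2] / oversample_spacing)
  origin_xy <- b$center - c(nx - 1, ny - 1) / 2 * oversample_spacing
  geom <- grid_geometry(c(nx, ny), spec$n_slices, oversample_spacing,
                        spec$slice_spacing,
                        origin = c(origin_xy, 0))
  xs <- grid_coords(geom, 1)
  ys <- grid_coords(geom, 2)
  vals <- array(-1000, dim = c(nx, ny, spec$n_slices))

  # body ellipse, identical on every slice
  ex <- (xs - b$center[1]) / b$semi_axes[1]
  ey <- (ys - b$center[2]) / b$semi_axes[2]
  body2d <- outer(ex^2, ey^2, `+`) <= 1
  base <- matrix(-1000, nx, ny)
  base[body2d] <- b$hu
  for (i in seq_len(nrow(spec$bones))) {
    base <- paint_circle(base, xs, ys, spec$bones$cx[i], spec$bones$cy[i],
                         spec$bones$r[i], spec$bones$hu[i])
  }

  for (k in seq_len(spec$n_slices)) {
    sl <- base
    vz <- spec$vessels
    if (nrow(vz) > 0) {
      vz$cx <- vz$cx + (k - 1) * vz$drift_x
      vz$cy <- vz$cy + (k - 1) * vz$drift_y
    }
    for (i in seq_len(nrow(vz))) {
      sl <- paint_circle(sl, xs, ys, vz$cx[i], vz$cy[i], vz$r[i], vz$hu[i])
    }
    for (i in seq_len(nrow(spec$calcifications))) {
      cc <- spec$calcifications[i, ]
      v <- vz[cc$vessel, ]
      sl <- paint_arc(sl, xs, ys, v$cx, v$cy, v$r, cc$theta0, cc$theta1,
                      cc$thickness, cc$hu)
    }
    vals[, , k] <- sl
  }

  vol <- ct_volume(vals, geom, id = "phantom-truth")
  attr(vol, "content_bbox") <- c(
    b$center[1] - b$semi_axes[1], b$center[1] + b$semi_axes[1],
    b$center[2] - b$semi_axes[2], b$center[2] + b$semi_axes[2]
  )
  vol
}

# paint a filled circle onto a slice (restricted to its bounding box for speed)
paint_circle <- function(slice, xs, ys, cx, cy, r, hu) {
  ix <- which(xs >= cx - r & xs <= cx + r)
  iy <- which(ys >= cy - r & ys <= cy + r)
  if (length(ix) == 0 || length(iy) == 0) stop("structure outside grid")
  d2 <- outer((xs[ix] - cx)^2, (ys[iy] - cy)^2, `+`)
  sub <- slice[ix, iy, drop = FALSE]
  sub[d2 <= r^2] <- hu
  slice[ix, iy] <- sub
  slice
}

# paint a mural arc: radial band [r - thickness, r], angular range
# [theta0, theta1] on the wall of a vessel of lumen radius r
paint_arc <- function(slice, xs, ys, cx, cy, r, theta0, theta1, thickness, hu) {
  rout <- r
  rin <- max(r - thickness, 0)
  ix <- which(xs >= cx - rout & xs <= cx + rout)
  iy <- which(ys >= cy - rout & ys <= cy + rout)
  if (length(ix) == 0 || length(iy) == 0) stop("structure outside grid")
  dx <- outer(xs[ix] - cx, rep(1, length(iy)))
  dy <- outer(rep(1, length(ix)), ys[iy] - cy)
  d2 <- dx^2 + dy^2
  ang <- atan2(dy, dx) %% (2 * pi)
  t0 <- theta0 %% (2 * pi)
  t1 <- theta1 %% (2 * pi)
  in_arc <- if (t0 <= t1) ang >= t0 & ang <= t1 else ang >= t0 | ang <= t1
  sel <- d2 <= rout^2 & d2 >= rin^2 & in_arc
  sub <- slice[ix, iy, drop = FALSE]
  sub[sel] <- hu
  slice[ix, iy] <- sub
  slice
}
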