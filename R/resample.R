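# Separable B-spline interpolation on regular grids.
#
# Interpolation at arbitrary positions x (in 0-based index units) is
# c %*% beta_n(x - j) where the coefficients c solve a banded collocation
# system, guaranteeing the interpolant reproduces the samples at the grid
# points. For the cubic order (the default) the two free end conditions are
# closed not-a-knot style (vanishing third-derivative jump at the first and
# last interior knots), which makes the interpolant reproduce polynomials up
# to degree 3 exactly over the whole sample hull; other orders use a mirror
# (whole-sample symmetric) boundary.

# centred B-spline basis of integer order n, by the recursive convolution rule
bspline_kernel <- function(x, order) {
  if (order == 0L) return(as.numeric(abs(x) < 0.5) + 0.5 * (abs(x) == 0.5))
  n <- order
  (( x + (n + 1) / 2) * bspline_kernel(x + 0.5, n - 1L) +
   ((n + 1) / 2 - x)  * bspline_kernel(x - 0.5, n - 1L)) / n
}

# reflect 0-based indices into [0, n-1] (whole-sample mirror)
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(0L, length(i)))
  p <- 2L * (n - 1L)
  i <- ((i %% p) + p) %% p
  ifelse(i >= n, p - i, i)
}

# sparse collocation matrix B (n x n) for samples at integers, mirror boundary
bspline_collocation <- function(n, order) {
  half <- floor(order / 2)
  offs <- seq(-half, half)
  w <- bspline_kernel(offs, order)
  ii <- jj <- xx <- list()
  for (m in seq_along(offs)) {
    if (w[m] == 0) next
    i <- 0:(n - 1L)
    j <- mirror_index(i + offs[m], n)
    ii[[m]] <- i + 1L; jj[[m]] <- j + 1L; xx[[m]] <- rep(w[m], n)
  }
  Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx), dims = c(n, n)
  )
}

# sparse evaluation matrix W (length(u) x ncol): row r holds kernel weights
# for evaluating the spline at position u[r] (0-based index units). With
# `extended = TRUE` the coefficient vector is c_{-1}..c_n (not-a-knot cubic,
# ncol = n + 2, no index reflection); otherwise c_0..c_{n-1} with mirror
# reflection. Rows for out-of-extent positions (outside the sample hull
# [0, n-1]) stay all-zero and are reported via attr "valid".
bspline_eval_matrix <- function(u, n, order, extended = FALSE) {
  eps <- 1e-6   # hull membership up to float round-off in coordinate maths
  valid <- u >= -eps & u <= n - 1 + eps
  u <- pmin(pmax(u, 0), n - 1)
  half <- (order + 1) / 2
  ii <- jj <- xx <- list()
  jmin <- ceiling(u - half)
  for (m in 0:order) {
    j <- jmin + m
    w <- bspline_kernel(u - j, order)
    sel <- valid & w != 0
    if (!any(sel)) next
    cols <- if (extended) j[sel] + 2L else mirror_index(j[sel], n) + 1L
    ii[[length(ii) + 1L]] <- which(sel)
    jj[[length(jj) + 1L]] <- cols
    xx[[length(xx) + 1L]] <- w[sel]
  }
  W <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(length(u), if (extended) n + 2L else n)
  )
  attr(W, "valid") <- valid
  W
}

# not-a-knot cubic collocation matrix over coefficients c_{-1}..c_n:
# interpolation rows (1/6, 4/6, 1/6) for every sample plus vanishing
# third-derivative jumps (fourth differences of coefficients) at knots 1 and
# n-2; requires n >= 4
notaknot_collocation <- function(n) {
  ii <- c(rep(1L, 5), rep(2:(n + 1L), each = 3), rep(n + 2L, 5))
  jj <- c(1:5,
          as.vector(t(outer(1:n, 0:2, `+`))),
          (n - 2L):(n + 2L))
  xx <- c(c(1, -4, 6, -4, 1),
          rep(c(1, 4, 1) / 6, n),
          c(1, -4, 6, -4, 1))
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + 2L, n + 2L))
}

#' Resample a CT volume onto a target grid by B-spline interpolation
#'
#' Evaluates the source volume at the physical voxel-centre positions of the
#' target grid using separable B-spline interpolation with a collocation
#' prefilter, so samples taken exactly at source voxel centres reproduce the
#' source values. The default cubic order (3) reproduces polynomial images
#' up to total degree 3 on interior voxels. The z-grids must match: target
#' slice positions must coincide with source slice positions (within
#' `z_tol` mm), as they do for dual reconstructions of one acquisition.
#'
#' Target voxels outside the source in-plane extent are filled with air
#' (-1000 HU) and flagged in the `"valid"` attribute of the result.
#'
#' @param src a [ct_volume()].
#' @param target a [grid_geometry()].
#' @param spline_order integer in 0..5 (default 3, cubic).
#' @param z_tol tolerance (mm) for matching slice positions.
#' @return A [ct_volume()] on `target`; attribute `"valid"` is a logical
#'   array marking in-extent voxels.
#' @export
resample_to_grid <- function(src, target, spline_order = 3L, z_tol = 1e-3) {
  stopifnot(inherits(src, "ct_volume"), inherits(target, "grid_geometry"))
  if (!spline_order %in% 0:5) stop("`spline_order` must be an integer in 0..5")
  spline_order <- as.integer(spline_order)
  sg <- src$geometry

  z_src <- grid_coords(sg, 3)
  z_tgt <- grid_coords(target, 3)
  kmap <- vapply(z_tgt, function(z) {
    d <- abs(z_src - z)
    if (min(d) > z_tol) {
      stop("target slice position not present in source z-grid")
    }
    which.min(d)
  }, integer(1))

  # target centre positions in 0-based source index units
  u <- (grid_coords(target, 1) - sg$origin[1]) / sg$in_plane_spacing[1]
  v <- (grid_coords(target, 2) - sg$origin[2]) / sg$in_plane_spacing[2]
  nx <- sg$matrix_size[1]; ny <- sg$matrix_size[2]
  cubic <- spline_order == 3L && nx >= 4L && ny >= 4L
  Wx <- bspline_eval_matrix(u, nx, spline_order, extended = cubic)
  Wy <- bspline_eval_matrix(v, ny, spline_order, extended = cubic)
  vx <- attr(Wx, "valid"); vy <- attr(Wy, "valid")
  valid2d <- outer(vx, vy, `&`)

  prefilter <- spline_order >= 2L
  if (cubic) {
    Bx <- notaknot_collocation(nx)
    By <- notaknot_collocation(ny)
  } else if (prefilter) {
    Bx <- bspline_collocation(nx, spline_order)
    By <- bspline_collocation(ny, spline_order)
  }

  out <- array(-1000, dim = c(target$matrix_size, target$n_slices))
  for (t in seq_len(target$n_slices)) {
    s <- src$values[, , kmap[t]]
    if (cubic) {
      # coefficients c_{-1}..c_n per axis; the not-a-knot rows have rhs 0
      cx <- as.matrix(Matrix::solve(Bx, rbind(0, s, 0)))
      s <- t(as.matrix(Matrix::solve(By, rbind(0, t(cx), 0))))
    } else if (prefilter) {
      s <- as.matrix(Matrix::solve(Bx, s))
      s <- t(as.matrix(Matrix::solve(By, t(s))))
    }
    r <- as.matrix(Wx %*% s %*% Matrix::t(Wy))
    r[!valid2d] <- -1000
    out[, , t] <- r
  }
  res <- ct_volume(out, target, id = paste0(src$id, "-resampled"))
  attr(res, "valid") <- array(rep(valid2d, target$n_slices),
                              dim = dim(out))
  res
}

#' Align a large-FOV reconstruction onto the small-FOV grid
#'
#' Resamples the large-FOV volume onto the small-FOV volume's voxel
#' positions (the small grid is the analysis grid: masks are computed on the
#' small-FOV volume and applied to both). In valid use the large FOV
#' physically contains the small FOV, so no target voxel falls outside the
#' source; the out-of-extent fraction is checked and an error is raised
#' above 1%.
#'
#' @param large,small [ct_volume()]s of the same acquisition.
#' @param spline_order interpolation order, default cubic.
#' @param max_out_of_extent largest tolerated fraction of target voxels
#'   outside the source extent before the alignment warning escalates to an
#'   error (default 0.01).
#' @return list with `large_resampled` (on the small grid), `small`, and
#'   `out_of_extent_fraction`.
#' @export
align_pair <- function(large, small, spline_order = 3L,
                       max_out_of_extent = 0.01) {
  stopifnot(inherits(large, "ct_volume"), inherits(small, "ct_volume"))
  fov_l <- fov_diameter(large$geometry)
  fov_s <- fov_diameter(small$geometry)
  if (any(fov_l < fov_s)) {
    warning("first argument has the smaller FOV; resampling in this ",
            "direction discards resolution")
  }
  res <- resample_to_grid(large, small$geometry, spline_order = spline_order)
  frac_out <- mean(!attr(res, "valid"))
  if (frac_out > max_out_of_extent) {
    stop(sprintf("%.1f%% of target voxels outside the source extent",
                 100 * frac_out))
  }
  if (frac_out > 0) {
    warning(sprintf("%.3f%% of target voxels outside the source extent",
                    100 * frac_out))
  }
  list(large_resampled = res, small = small, out_of_extent_fraction = frac_out)
}
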