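#' Grid geometry of a reconstructed CT volume
#'
#' Describes the physical sampling grid of an axial CT reconstruction: matrix
#' size, in-plane voxel spacing, slice spacing and the physical position of the
#' first voxel centre. The package uses the voxel-centre convention throughout:
#' the physical coordinate of voxel `(i, j, k)` (0-based) is
#' `origin + c(i, j, k) * spacing`. The slice axis is the third array index;
#' all in-plane operations act on the first two.
#'
#' @param matrix_size integer vector of length 2, in-plane matrix `(nx, ny)`.
#' @param n_slices integer, number of axial slices.
#' @param in_plane_spacing numeric length 1 or 2, in-plane voxel size in mm.
#' @param slice_spacing numeric, slice-to-slice distance in mm.
#' @param origin numeric length 3, physical coordinates (mm) of the centre of
#'   voxel `(0, 0, 0)`.
#'
#' @return An object of class `grid_geometry` (a named list).
#' @export
#' @examples
#' grid_geometry(c(512, 512), 10, 0.43, 2)
grid_geometry <- function(matrix_size, n_slices, in_plane_spacing,
                          slice_spacing, origin = c(0, 0, 0)) {
  matrix_size <- as.integer(rep_len(matrix_size, 2L))
  in_plane_spacing <- rep_len(as.numeric(in_plane_spacing), 2L)
  n_slices <- as.integer(n_slices)
  stopifnot(
    all(matrix_size >= 2L), n_slices >= 1L,
    all(in_plane_spacing > 0), slice_spacing > 0,
    length(origin) == 3L, all(is.finite(origin))
  )
  structure(
    list(
      matrix_size = matrix_size,
      n_slices = n_slices,
      in_plane_spacing = in_plane_spacing,
      slice_spacing = as.numeric(slice_spacing),
      origin = as.numeric(origin)
    ),
    class = "grid_geometry"
  )
}

#' @export
print.grid_geometry <- function(x, ...) {
  cat(sprintf(
    "<grid_geometry> %d x %d x %d | spacing %.4g x %.4g x %.4g mm | FOV %.4g x %.4g mm\n",
    x$matrix_size[1], x$matrix_size[2], x$n_slices,
    x$in_plane_spacing[1], x$in_plane_spacing[2], x$slice_spacing,
    fov_diameter(x)[1], fov_diameter(x)[2]
  ))
  invisible(x)
}

#' Field-of-view diameter of a grid
#'
#' With a fixed reconstruction matrix the FOV diameter and the in-plane voxel
#' size determine each other: `fov = matrix * spacing`.
#'
#' @param geometry a [grid_geometry()].
#' @return numeric length 2, FOV extent (mm) along x and y.
#' @export
fov_diameter <- function(geometry) {
  stopifnot(inherits(geometry, "grid_geometry"))
  geometry$matrix_size * geometry$in_plane_spacing
}

#' In-plane voxel size from FOV diameter and matrix size
#'
#' A reconstruction of a circular FOV of diameter `fov_diameter` onto a square
#' matrix yields square in-plane voxels of size `fov_diameter / matrix`. This
#' is the arithmetic behind the resolution advantage of side-specific
#' small-FOV reconstructions: at a 512 matrix, a 422.67 mm whole-body FOV
#' gives 0.83 mm voxels while a 220.19 mm single-leg FOV gives 0.43 mm.
#'
#' @param fov_diameter FOV diameter in mm, > 0.
#' @param matrix reconstruction matrix size (voxels per row), >= 1.
#' @return voxel size in mm.
#' @export
#' @examples
#' in_plane_voxel_size(422.67, 512)
#' in_plane_voxel_size(220.19, 512)
in_plane_voxel_size <- function(fov_diameter, matrix) {
  if (any(fov_diameter <= 0)) stop("`fov_diameter` must be positive")
  if (any(matrix < 1)) stop("`matrix` must be >= 1")
  fov_diameter / matrix
}

#' Physical voxel-centre coordinates along one axis
#'
#' @param geometry a [grid_geometry()].
#' @param axis 1 (x), 2 (y) or 3 (z/slice).
#' @return numeric vector of voxel-centre coordinates in mm.
#' @export
grid_coords <- function(geometry, axis) {
  stopifnot(inherits(geometry, "grid_geometry"), axis %in% 1:3)
  if (axis == 3L) {
    geometry$origin[3] + (seq_len(geometry$n_slices) - 1) * geometry$slice_spacing
  } else {
    geometry$origin[axis] +
      (seq_len(geometry$matrix_size[axis]) - 1) * geometry$in_plane_spacing[axis]
  }
}

geometry_equal <- function(a, b, tol = 1e-6) {
  identical(a$matrix_size, b$matrix_size) &&
    identical(a$n_slices, b$n_slices) &&
    all(abs(a$in_plane_spacing - b$in_plane_spacing) <= tol) &&
    abs(a$slice_spacing - b$slice_spacing) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}
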