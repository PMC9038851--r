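#' CT volume: Hounsfield-valued voxel array with physical grid geometry
#'
#' @param values 3-D numeric array of Hounsfield units, dimensions
#'   `(nx, ny, n_slices)` matching `geometry`.
#' @param geometry a [grid_geometry()].
#' @param id free-text identifier carried through reports.
#'
#' @return An object of class `ct_volume` with fields `values`, `geometry`,
#'   `id`.
#' @export
ct_volume <- function(values, geometry, id = "volume") {
  stopifnot(inherits(geometry, "grid_geometry"))
  values <- as.array(values)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  expected <- c(geometry$matrix_size, geometry$n_slices)
  if (!identical(dim(values), as.integer(expected))) {
    stop(sprintf(
      "value array is %s but geometry expects %s",
      paste(dim(values), collapse = "x"), paste(expected, collapse = "x")
    ))
  }
  if (!all(is.finite(values))) stop("HU values must be finite")
  structure(list(values = values, geometry = geometry, id = as.character(id)),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> '%s' ", x$id))
  print(x$geometry)
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' @export
as.array.ct_volume <- function(x, ...) x$values

#' Extract one axial slice as a matrix
#'
#' @param vol a [ct_volume()].
#' @param k slice index (1-based).
#' @return numeric matrix `(nx, ny)`.
#' @export
volume_slice <- function(vol, k) {
  stopifnot(inherits(vol, "ct_volume"), k >= 1, k <= vol$geometry$n_slices)
  vol$values[, , k]
}

stop_if_geometry_mismatch <- function(a_geom, b_geom, what = "volumes") {
  if (!geometry_equal(a_geom, b_geom)) {
    stop(sprintf("%s do not share a grid geometry", what))
  }
  invisible(TRUE)
}

# Run `expr` under a private RNG stream seeded by `seed`, restoring the
# caller's RNG state afterwards. All stochastic simulator code funnels
# through here so no function touches global RNG state.
with_local_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
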