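#' Per-voxel gradient magnitude of an axial slice
#'
#' Computes `sqrt(gx^2 + gy^2)` with `gx`, `gy` central finite differences in
#' physical units (HU/mm); one-sided differences at the borders. Expressing
#' the gradient per mm makes the metric comparable across grids with
#' different voxel sizes — essential when a large-FOV volume has been
#' resampled onto a small-FOV grid.
#'
#' @param slice numeric matrix, at least 3x3.
#' @param spacing numeric length 2, in-plane voxel size (mm).
#' @return non-negative matrix of the same dimensions.
#' @export
gradient_magnitude <- function(slice, spacing) {
  stopifnot(is.matrix(slice), all(dim(slice) >= 3L), length(spacing) >= 2L,
            all(spacing[1:2] > 0))
  n <- nrow(slice); m <- ncol(slice)
  gx <- matrix(0, n, m)
  gx[2:(n - 1), ] <- (slice[3:n, ] - slice[1:(n - 2), ]) / (2 * spacing[1])
  gx[1, ] <- (slice[2, ] - slice[1, ]) / spacing[1]
  gx[n, ] <- (slice[n, ] - slice[n - 1, ]) / spacing[1]
  gy <- matrix(0, n, m)
  gy[, 2:(m - 1)] <- (slice[, 3:m] - slice[, 1:(m - 2)]) / (2 * spacing[2])
  gy[, 1] <- (slice[, 2] - slice[, 1]) / spacing[2]
  gy[, m] <- (slice[, m] - slice[, m - 1]) / spacing[2]
  sqrt(gx^2 + gy^2)
}

gradient_magnitude_volume <- function(vol) {
  g <- array(0, dim(vol$values))
  for (k in seq_len(dim(g)[3])) {
    g[, , k] <- gradient_magnitude(vol$values[, , k],
                                   vol$geometry$in_plane_spacing)
  }
  g
}

#' Significant-edge mask via Otsu on the gradient magnitude
#'
#' Noise produces a low but nonzero gradient everywhere; genuine structural
#' boundaries form the upper mode of the gradient-magnitude distribution.
#' An Otsu threshold on the gradient magnitudes inside the analysis ROI
#' separates the two, and only the "significant edges" above it enter the
#' sharpness score. With `scope = "per-volume"` (default) one pooled
#' threshold is used for all slices so they are scored on a common scale;
#' `"per-slice"` recomputes it per slice.
#'
#' @param gradmag 3-D array of gradient magnitudes (or a matrix for a single
#'   slice).
#' @param roi logical array of the same shape (analysis ROI).
#' @param scope `"per-volume"` or `"per-slice"`.
#' @return logical array: `roi & gradmag >= threshold`. If the ROI gradient
#'   is constant the mask is empty and a warning is raised.
#' @export
significant_edge_mask <- function(gradmag, roi,
                                  scope = c("per-volume", "per-slice")) {
  scope <- match.arg(scope)
  was_matrix <- is.matrix(gradmag)
  if (is.matrix(gradmag)) dim(gradmag) <- c(dim(gradmag), 1L)
  if (is.matrix(roi)) dim(roi) <- c(dim(roi), 1L)
  stopifnot(identical(dim(gradmag), dim(roi)))
  if (!any(roi)) stop("empty ROI")
  mask <- array(FALSE, dim(gradmag))
  thr_for <- function(vals) {
    if (length(unique(vals)) < 2L) {
      warning("constant gradient magnitude in ROI: empty edge mask")
      return(Inf)
    }
    otsu_threshold(vals)
  }
  if (scope == "per-volume") {
    thr <- thr_for(gradmag[roi])
    mask <- roi & gradmag >= thr
  } else {
    for (k in seq_len(dim(gradmag)[3])) {
      rk <- roi[, , k]
      if (!any(rk)) next
      thr <- thr_for(gradmag[, , k][rk])
      mask[, , k] <- rk & gradmag[, , k] >= thr
    }
  }
  if (was_matrix) dim(mask) <- dim(mask)[1:2]
  mask
}

#' Sharpness score of one slice
#'
#' Sums the gradient-magnitude values over the significant-edge voxels of
#' the slice (default), or averages them (`normalization = "mean"`). An
#' empty edge mask scores 0.
#'
#' @param gradmag numeric matrix of gradient magnitudes.
#' @param edge_mask logical matrix of the same shape.
#' @param normalization `"sum"` (default) or `"mean"`.
#' @return scalar >= 0.
#' @export
slice_sharpness <- function(gradmag, edge_mask,
                            normalization = c("sum", "mean")) {
  normalization <- match.arg(normalization)
  if (!identical(dim(gradmag), dim(edge_mask))) stop("shape mismatch")
  n <- sum(edge_mask)
  if (n == 0) return(0)
  s <- sum(gradmag[edge_mask])
  if (normalization == "mean") s / n else s
}

#' Per-slice sharpness profile of a volume under a mask set
#'
#' @param vol a [ct_volume()].
#' @param edge_mask logical 3-D array of significant-edge voxels (shared
#'   between compared volumes).
#' @param normalization passed to [slice_sharpness()].
#' @param mask_provenance identifier of the mask source recorded in the
#'   profile.
#' @return A tibble of class `sharpness_profile` with columns `slice`,
#'   `sharpness`, `n_edge_voxels`; attribute `volume_mean` is the mean over
#'   slices with at least one edge voxel.
#' @export
sharpness_profile <- function(vol, edge_mask, normalization = "sum",
                              mask_provenance = "unspecified") {
  stopifnot(inherits(vol, "ct_volume"),
            identical(dim(edge_mask), dim(vol$values)))
  gm <- gradient_magnitude_volume(vol)
  rows <- purrr::map(seq_len(dim(gm)[3]), function(k) {
    em <- edge_mask[, , k]
    tibble::tibble(
      slice = k,
      sharpness = slice_sharpness(gm[, , k], em, normalization),
      n_edge_voxels = sum(em)
    )
  })
  prof <- dplyr::bind_rows(rows)
  scored <- prof$n_edge_voxels > 0
  structure(
    prof,
    volume_mean = if (any(scored)) mean(prof$sharpness[scored]) else NA_real_,
    volume_id = vol$id,
    mask_provenance = mask_provenance,
    normalization = normalization,
    class = c("sharpness_profile", class(prof))
  )
}

#' Compare the sharpness of a geometrically matched reconstruction pair
#'
#' Applies the identical-mask contract: both volumes must live on one grid
#' (the small-FOV grid, after [align_pair()]), and a single significant-edge
#' mask — derived from the small-FOV volume's gradient by default, or from
#' the union of both volumes' edges — is used for both. Reports per-slice
#' scores and differences (small - large), the mean difference, and a
#' one-sided unpaired t-test of whether the small-FOV slices are sharper.
#'
#' @param small [ct_volume()], the small-FOV reconstruction.
#' @param large_resampled [ct_volume()], the large-FOV reconstruction on the
#'   same grid.
#' @param masks a `mask_set` from [build_mask_set()] on the same grid.
#' @param edge_source `"small"` (default) or `"union"`.
#' @param edge_scope Otsu scope for the edge threshold, see
#'   [significant_edge_mask()].
#' @param normalization per-slice score normalisation, see
#'   [slice_sharpness()].
#' @param var_equal use the classical equal-variance t-test (default TRUE).
#' @return An object of class `pair_comparison`: list with `per_slice`
#'   (tibble: slice, small, large, difference, n_edge_voxels),
#'   `mean_difference`, `statistic`, `p_value`, `n_slices` and the
#'   configuration used.
#' @export
compare_pair <- function(small, large_resampled, masks,
                         edge_source = c("small", "union"),
                         edge_scope = "per-volume",
                         normalization = "sum",
                         var_equal = TRUE) {
  edge_source <- match.arg(edge_source)
  stopifnot(inherits(small, "ct_volume"), inherits(large_resampled, "ct_volume"),
            inherits(masks, "mask_set"))
  stop_if_geometry_mismatch(small$geometry, large_resampled$geometry,
                            "paired volumes")
  stop_if_geometry_mismatch(small$geometry, masks$geometry,
                            "volume and masks")

  gm_small <- gradient_magnitude_volume(small)
  edge <- significant_edge_mask(gm_small, masks$analysis_roi, edge_scope)
  if (edge_source == "union") {
    gm_large <- gradient_magnitude_volume(large_resampled)
    edge <- edge | significant_edge_mask(gm_large, masks$analysis_roi,
                                         edge_scope)
  }
  valid <- attr(large_resampled, "valid")
  if (!is.null(valid)) edge <- edge & valid

  ps <- sharpness_profile(small, edge, normalization,
                          mask_provenance = masks$source_id)
  pl <- sharpness_profile(large_resampled, edge, normalization,
                          mask_provenance = masks$source_id)
  per_slice <- tibble::tibble(
    slice = ps$slice,
    small = ps$sharpness,
    large = pl$sharpness,
    difference = ps$sharpness - pl$sharpness,
    n_edge_voxels = ps$n_edge_voxels
  )
  scored <- per_slice$n_edge_voxels > 0
  test <- if (sum(scored) >= 2 &&
              stats::sd(per_slice$difference[scored]) > 0) {
    stats::t.test(per_slice$small[scored], per_slice$large[scored],
                  alternative = "greater", var.equal = var_equal)
  } else {
    NULL
  }
  structure(
    list(
      per_slice = per_slice,
      mean_difference = mean(per_slice$difference[scored]),
      small_mean = attr(ps, "volume_mean"),
      large_mean = attr(pl, "volume_mean"),
      statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
      p_value = if (is.null(test)) NA_real_ else test$p.value,
      n_slices = sum(scored),
      config = list(edge_source = edge_source, edge_scope = edge_scope,
                    normalization = normalization, var_equal = var_equal,
                    mask_provenance = masks$source_id)
    ),
    class = "pair_comparison"
  )
}

#' @export
print.pair_comparison <- function(x, ...) {
  cat(sprintf(
    "<pair_comparison> %d slices | mean difference (small - large) %.3g | one-sided p = %.3g\n",
    x$n_slices, x$mean_difference, x$p_value
  ))
  invisible(x)
}
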