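#' Automated body mask: Otsu threshold + largest connected volume
#'
#' Separates the patient from surrounding air by a global Otsu threshold on
#' the full HU volume, keeps the single largest 3-D connected component
#' (26-connectivity) of the above-threshold voxels, and fills fully enclosed
#' holes slice-wise, so internal low-HU regions stay inside the body.
#'
#' @param vol a [ct_volume()] containing both air and tissue.
#' @return logical 3-D array (the body mask).
#' @export
body_mask <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  thr <- otsu_threshold(as.vector(vol$values))
  above <- vol$values >= thr
  if (!any(above)) stop("segmentation error: nothing above the Otsu threshold")
  body <- largest_component_3d(above)
  for (k in seq_len(dim(body)[3])) {
    filled <- EBImage::fillHull(body[, , k] * 1)
    body[, , k] <- matrix(as.numeric(filled) > 0, dim(body)[1], dim(body)[2])
  }
  body
}

#' Bone mask: second-stage Otsu within the body
#'
#' Separates cortical bone (and other very high HU structures) from soft
#' tissue by a second Otsu threshold computed on HU values inside the body
#' mask, then drops components smaller than `min_voxels` to suppress
#' speckle. A fixed HU cutoff is available as an escape hatch for volumes
#' where contrast-filled vessels contaminate the upper Otsu class.
#'
#' @param vol a [ct_volume()].
#' @param body logical body mask from [body_mask()].
#' @param min_voxels minimum 3-D component size kept (default 50).
#' @param method `"otsu"` (default) or `"fixed"`.
#' @param fixed_hu HU cutoff used when `method = "fixed"` (default 300).
#' @return logical 3-D array, a subset of `body`.
#' @export
bone_mask <- function(vol, body, min_voxels = 50L, method = c("otsu", "fixed"),
                      fixed_hu = 300) {
  stopifnot(inherits(vol, "ct_volume"), identical(dim(body), dim(vol$values)))
  method <- match.arg(method)
  inside <- vol$values[body]
  if (length(inside) == 0) stop("no in-body voxels")
  thr <- if (method == "otsu") otsu_threshold(inside) else fixed_hu
  bone <- body & vol$values >= thr
  if (any(bone)) {
    labs <- label_components_3d(bone)
    sizes <- tabulate(labs[labs > 0L])
    keep <- which(sizes >= min_voxels)
    bone <- array(labs %in% keep, dim(bone))
  }
  bone
}

#' Analysis ROI: body minus dilated bone minus the air boundary
#'
#' Restricts the sharpness analysis to soft tissue by excluding (a) all
#' voxels within `dilation_radius_mm` of bone and (b) the body rim of the
#' same width, so that the trivially sharp object-to-air and tissue-to-bone
#' edges cannot dominate the metric. Distances are Euclidean in physical mm,
#' evaluated in-plane per slice (at typical geometries the slice spacing
#' equals or exceeds the margin, so through-plane dilation adds nothing).
#' Contrast-filled vessels and their mural calcifications are deliberately
#' retained: they are the structures whose sharpness is under study.
#'
#' @param body,bone logical 3-D masks sharing one grid.
#' @param geometry the shared [grid_geometry()].
#' @param dilation_radius_mm exclusion margin in mm (default 2).
#' @return logical 3-D array: `body & !dilate(bone) & !rim(body)`.
#' @export
analysis_roi <- function(body, bone, geometry, dilation_radius_mm = 2) {
  stopifnot(identical(dim(body), dim(bone)), dilation_radius_mm >= 0)
  dx <- geometry$in_plane_spacing[1]
  if (abs(diff(geometry$in_plane_spacing)) > 1e-9) {
    stop("analysis_roi requires isotropic in-plane spacing")
  }
  roi <- body & !bone
  if (dilation_radius_mm == 0) return(roi)
  r_px <- dilation_radius_mm / dx
  for (k in seq_len(dim(body)[3])) {
    b <- body[, , k]
    bn <- bone[, , k]
    # distance from each voxel to nearest bone voxel: distmap of !bone
    near_bone <- if (any(bn)) {
      d_to_bone <- EBImage::distmap((!bn) * 1)
      matrix(as.numeric(d_to_bone), nrow(bn)) <= r_px
    } else {
      matrix(FALSE, nrow(bn), ncol(bn))
    }
    # erode the body rim: keep voxels farther than r from non-body
    d_in_body <- matrix(as.numeric(EBImage::distmap(b * 1)), nrow(b))
    roi[, , k] <- b & !near_bone & d_in_body > r_px
  }
  roi
}

#' Automated proxy for bone-removal quality control
#'
#' The clinical workflow kept only datasets with visually near-perfect bone
#' removal. As an automated stand-in, this scores the fraction of
#' very-high-HU voxels (>= `high_hu`, in-body) belonging to large components
#' (> `vessel_max_voxels` voxels, i.e. bone-calibre rather than
#' calcification-calibre) that the bone mask captures.
#'
#' @param bone logical bone mask.
#' @param vol the source [ct_volume()].
#' @param body logical body mask.
#' @param high_hu HU floor defining "certainly bone or calcification"
#'   (default 700).
#' @param vessel_max_voxels components at most this size are treated as
#'   vessel features (calcifications), not bone (default 200).
#' @param cutoff eligibility cutoff on the score (default 0.98).
#' @return A one-row tibble with `score`, `n_reference`, `n_captured`,
#'   `eligible`.
#' @export
bone_removal_quality <- function(bone, vol, body, high_hu = 700,
                                 vessel_max_voxels = 200L, cutoff = 0.98) {
  stopifnot(inherits(vol, "ct_volume"))
  high <- body & vol$values >= high_hu
  if (any(high)) {
    labs <- label_components_3d(high)
    sizes <- tabulate(labs[labs > 0L])
    big <- which(sizes > vessel_max_voxels)
    ref <- array(labs %in% big, dim(high))
  } else {
    ref <- high
  }
  n_ref <- sum(ref)
  n_cap <- sum(ref & bone)
  score <- if (n_ref == 0) 1.0 else n_cap / n_ref
  tibble::tibble(
    score = score, n_reference = n_ref, n_captured = n_cap,
    eligible = score >= cutoff
  )
}

#' Build the full mask set for a volume
#'
#' Runs the automated segmentation chain (body, bone, analysis ROI) on one
#' volume — by convention the small-FOV (sharper) reconstruction — and
#' returns the aligned masks to be applied identically to both members of a
#' reconstruction pair.
#'
#' @param vol a [ct_volume()].
#' @param dilation_radius_mm exclusion margin around bone and the body rim.
#' @param bone_method,bone_fixed_hu,min_bone_voxels see [bone_mask()].
#' @return An object of class `mask_set`: list with logical arrays `body`,
#'   `bone`, `analysis_roi`, the shared `geometry` and `source_id`.
#' @export
build_mask_set <- function(vol, dilation_radius_mm = 2,
                           bone_method = "otsu", bone_fixed_hu = 300,
                           min_bone_voxels = 50L) {
  body <- body_mask(vol)
  bone <- bone_mask(vol, body, min_voxels = min_bone_voxels,
                    method = bone_method, fixed_hu = bone_fixed_hu)
  roi <- analysis_roi(body, bone, vol$geometry, dilation_radius_mm)
  structure(
    list(body = body, bone = bone, analysis_roi = roi,
         geometry = vol$geometry, source_id = vol$id),
    class = "mask_set"
  )
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf(
    "<mask_set> from '%s': body %d vx, bone %d vx, analysis ROI %d vx\n",
    x$source_id, sum(x$body), sum(x$bone), sum(x$analysis_roi)
  ))
  invisible(x)
}
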