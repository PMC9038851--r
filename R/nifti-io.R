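#' Read a CT volume from a NIfTI file
#'
#' NIfTI-1 is the package's canonical interchange format: voxel spacing is
#' taken from the pixel dimensions and the origin from the translation column
#' of the stored affine. 2-D images are promoted to single-slice volumes.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param format currently only `"nifti"`. DICOM series are not supported;
#'   convert series to NIfTI upstream (e.g. with `dcm2niix`) before analysis.
#' @param id identifier for the returned volume; defaults to the file name.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, format = c("nifti", "dicom"), id = NULL) {
  format <- match.arg(format)
  if (format == "dicom") {
    stop("DICOM series input is not supported; convert to NIfTI first")
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("unreadable NIfTI '%s': %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L) stop("expected a 2-D or 3-D image")
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  if (any(sp[1:3] <= 0)) stop("non-positive voxel spacing in NIfTI header")
  aff <- RNifti::xform(img)
  origin <- as.numeric(aff[1:3, 4])
  geom <- grid_geometry(dim(arr)[1:2], dim(arr)[3], sp[1:2], sp[3],
                        origin = origin)
  ct_volume(arr, geom, id = if (is.null(id)) basename(path) else id)
}

#' Write a CT volume to a NIfTI file
#'
#' Values are stored as float32; geometry (spacing and origin) is stored in
#' the header so that [read_volume()] round-trips the volume exactly up to
#' float32 value precision.
#'
#' @param vol a [ct_volume()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ct_volume"))
  RNifti::writeNifti(as_nifti_image(vol), path, datatype = "float")
  invisible(path)
}

# nifti image carrying the volume's grid geometry (pixdim must be set before
# the xforms or RNifti renormalises the spacing out of them)
as_nifti_image <- function(vol) {
  g <- vol$geometry
  aff <- diag(c(g$in_plane_spacing, g$slice_spacing, 1))
  aff[1:3, 4] <- g$origin
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- c(g$in_plane_spacing, g$slice_spacing)
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::`sform<-`(img, structure(aff, code = 2L))
}

#' Write a boolean mask volume as uint8 NIfTI on its source grid
#'
#' @param mask logical 3-D array.
#' @param geometry the [grid_geometry()] shared with the source volume.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, geometry, path) {
  vol <- ct_volume(array(as.numeric(mask), dim(mask)), geometry, id = "mask")
  RNifti::writeNifti(as_nifti_image(vol), path, datatype = "uint8")
  invisible(path)
}
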