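#' Reconstruction parameters for a simulated FOV
#'
#' Models the resolution consequence of the reconstruction field of view at a
#' fixed matrix: the in-plane voxel size is `fov_diameter / matrix`, and the
#' in-plane point-spread function combines a FOV-independent detector term
#' with a voxel-aperture term in quadrature,
#' `FWHM_total = sqrt(psf_fwhm^2 + (aperture_k * voxel)^2)`. A larger FOV
#' therefore yields a blurrier reconstruction of the same anatomy — the
#' physical premise that small side-specific FOVs recover resolution the
#' whole-body FOV cannot use.
#'
#' @param fov_diameter reconstruction FOV diameter in mm.
#' @param matrix reconstruction matrix (default 512).
#' @param psf_fwhm detector-limited intrinsic resolution, FWHM in mm
#'   (FOV-independent, default 0.6).
#' @param aperture_k weight of the voxel-aperture blur term (default 1;
#'   set 0 to disable FOV-dependent blur, e.g. in limiting-case checks).
#' @param noise_sd HU standard deviation of additive Gaussian noise
#'   (default 10).
#' @param seed integer seed for the noise draw.
#' @return An object of class `recon_spec`.
#' @export
recon_spec <- function(fov_diameter, matrix = 512L, psf_fwhm = 0.6,
                       aperture_k = 1.0, noise_sd = 10, seed = 1L) {
  stopifnot(fov_diameter > 0, matrix >= 2, psf_fwhm >= 0, aperture_k >= 0,
            noise_sd >= 0)
  if (psf_fwhm == 0 && aperture_k == 0) {
    # permitted: pure area-average reconstruction
  } else if (psf_fwhm <= 0 && aperture_k <= 0) {
    stop("psf_fwhm and aperture_k cannot both be negative")
  }
  structure(
    list(fov_diameter = as.numeric(fov_diameter), matrix = as.integer(matrix),
         psf_fwhm = as.numeric(psf_fwhm), aperture_k = as.numeric(aperture_k),
         noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
    class = "recon_spec"
  )
}

#' Total in-plane blur of a simulated reconstruction
#'
#' @param spec a [recon_spec()].
#' @return FWHM in mm of the combined Gaussian PSF.
#' @export
total_psf_fwhm <- function(spec) {
  voxel <- spec$fov_diameter / spec$matrix
  sqrt(spec$psf_fwhm^2 + (spec$aperture_k * voxel)^2)
}

#' Simulate a CT reconstruction of a ground-truth volume at a given FOV
#'
#' Three stages, per axial slice: (1) blur the oversampled ground truth with
#' an isotropic Gaussian PSF whose FWHM is [total_psf_fwhm()]; (2)
#' area-average down-sample onto the reconstruction grid (each reconstruction
#' voxel averages the truth voxels whose centres fall in its footprint),
#' centred on the truth volume; (3) add zero-mean Gaussian noise with
#' `noise_sd`, drawn under the spec's seed. Reconstruction voxels whose
#' footprint lies outside the truth extent are filled with air (-1000 HU).
#'
#' @param truth a high-resolution [ct_volume()] (e.g. from
#'   [render_phantom()]); its spacing must be much finer than the target
#'   voxel size.
#' @param spec a [recon_spec()].
#' @return A [ct_volume()] on the reconstruction grid (same z-grid as
#'   `truth`).
#' @export
simulate_reconstruction <- function(truth, spec) {
  stopifnot(inherits(truth, "ct_volume"), inherits(spec, "recon_spec"))
  tg <- truth$geometry
  voxel <- spec$fov_diameter / spec$matrix
  if (max(tg$in_plane_spacing) > voxel / 2) {
    stop("truth resolution too coarse for the requested reconstruction")
  }
  bbox <- attr(truth, "content_bbox")
  if (is.null(bbox)) {
    bbox <- c(range(grid_coords(tg, 1)), range(grid_coords(tg, 2)))
  }
  if ((bbox[2] - bbox[1]) > spec$fov_diameter ||
      (bbox[4] - bbox[3]) > spec$fov_diameter) {
    stop("reconstruction FOV does not cover the phantom")
  }

  # reconstruction grid centred on the truth grid centre, shared z-grid
  centre <- c(
    mean(range(grid_coords(tg, 1))),
    mean(range(grid_coords(tg, 2)))
  )
  nx <- spec$matrix
  origin_xy <- centre - (nx - 1) / 2 * voxel
  geom <- grid_geometry(c(nx, nx), tg$n_slices, voxel, tg$slice_spacing,
                        origin = c(origin_xy, tg$origin[3]))

  fwhm <- total_psf_fwhm(spec)
  sigma_px <- fwhm / 2.35482 / tg$in_plane_spacing[1]

  # footprint binning: truth voxel centres -> reconstruction voxel index
  bin_of <- function(coords, o) {
    edges <- o - voxel / 2 + (0:nx) * voxel
    b <- findInterval(coords, edges)
    b[b < 1 | b > nx] <- NA_integer_
    b
  }
  bx <- bin_of(grid_coords(tg, 1), origin_xy[1])
  by <- bin_of(grid_coords(tg, 2), origin_xy[2])
  keep_x <- !is.na(bx)
  keep_y <- !is.na(by)

  counts <- tcrossprod(
    tabulate(bx[keep_x], nx),
    tabulate(by[keep_y], nx)
  )
  empty <- counts == 0

  out <- array(-1000, dim = c(nx, nx, tg$n_slices))
  for (k in seq_len(tg$n_slices)) {
    sl <- truth$values[, , k]
    if (sigma_px > 0.05) sl <- EBImage::gblur(sl, sigma = sigma_px)
    sl <- sl[keep_x, keep_y, drop = FALSE]
    acc <- rowsum(sl, bx[keep_x], reorder = TRUE)
    acc <- rowsum(t(acc), by[keep_y], reorder = TRUE)
    acc <- t(acc)
    sums <- matrix(0, nx, nx)
    sums[sort(unique(bx[keep_x])), sort(unique(by[keep_y]))] <- acc
    sl_out <- sums / pmax(counts, 1)
    sl_out[empty] <- -1000
    out[, , k] <- sl_out
  }

  if (spec$noise_sd > 0) {
    noise <- with_local_seed(spec$seed,
                             stats::rnorm(length(out), 0, spec$noise_sd))
    out <- out + array(noise, dim = dim(out))
  }

  ct_volume(out, geom, id = sprintf("fov%.0f", spec$fov_diameter))
}

#' Simulate a paired large/small-FOV reconstruction of one phantom
#'
#' Renders the phantom once and reconstructs it at the two study FOVs
#' (defaults: 422.67 mm whole-body and 220.19 mm side-specific, both at a
#' 512 matrix). The two reconstructions share the raw data (the rendered
#' truth) and the z-grid, differing only in FOV/voxel size, mirroring dual
#' reconstructions of one CT acquisition.
#'
#' @param phantom a [phantom_spec()].
#' @param fov_large,fov_small FOV diameters in mm.
#' @param matrix reconstruction matrix size (default 512).
#' @param psf_fwhm,noise_sd,aperture_k shared reconstruction physics, see
#'   [recon_spec()].
#' @param seed integer seed; the two noise draws use `seed` and `seed + 1`.
#' @param oversample_spacing truth rendering resolution (mm).
#' @return list with elements `small` and `large` ([ct_volume()]s).
#' @export
simulate_recon_pair <- function(phantom, fov_large = 422.67, fov_small = 220.19,
                                matrix = 512L,
                                psf_fwhm = 0.6, noise_sd = 10, aperture_k = 1.0,
                                seed = 1L, oversample_spacing = 0.1) {
  truth <- render_phantom(phantom, oversample_spacing = oversample_spacing)
  large <- simulate_reconstruction(
    truth, recon_spec(fov_large, matrix = matrix, psf_fwhm = psf_fwhm,
                      noise_sd = noise_sd, aperture_k = aperture_k, seed = seed)
  )
  small <- simulate_reconstruction(
    truth, recon_spec(fov_small, matrix = matrix, psf_fwhm = psf_fwhm,
                      noise_sd = noise_sd, aperture_k = aperture_k,
                      seed = seed + 1L)
  )
  list(small = small, large = large)
}
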