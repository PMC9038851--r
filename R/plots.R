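#' Box plot of pooled image-quality ratings by segment and FOV
#'
#' Reproduces the reader-study summary figure: pooled (reader-averaged)
#' Likert scores per vessel segment, small vs large FOV, as box plots with
#' jittered points showing score frequency.
#'
#' @param pooled pooled rating table from [pool_readers()].
#' @param jitter_seed seed for the point jitter.
#' @return a ggplot object.
#' @export
plot_rating_scores <- function(pooled, jitter_seed = 1L) {
  stopifnot(all(c("level", "fov", "score") %in% names(pooled)))
  pooled$level <- factor(pooled$level,
                         levels = c("femoral", "popliteal", "crural", "pedal"))
  pooled$fov <- factor(pooled$fov, levels = c("large", "small"))
  ggplot2::ggplot(pooled, ggplot2::aes(x = .data$level, y = .data$score,
                                       fill = .data$fov)) +
    ggplot2::geom_boxplot(outlier.shape = NA,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(
      position = ggplot2::position_jitterdodge(
        jitter.width = 0.15, jitter.height = 0.08, dodge.width = 0.8,
        seed = jitter_seed
      ),
      alpha = 0.25, size = 0.6
    ) +
    ggplot2::scale_y_continuous(limits = c(1, 5)) +
    ggplot2::labs(x = "vessel segment", y = "pooled image-quality score",
                  fill = "FOV") +
    ggplot2::theme_minimal()
}

#' @method autoplot sharpness_profile
#' @export
autoplot.sharpness_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$sharpness)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "slice", y = "sharpness (summed |gradient|, HU/mm)",
                  title = attr(object, "volume_id")) +
    ggplot2::theme_minimal()
}

#' @method autoplot pair_comparison
#' @export
autoplot.pair_comparison <- function(object, ...) {
  df <- tidyr::pivot_longer(object$per_slice, c("small", "large"),
                            names_to = "fov", values_to = "sharpness")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slice, y = .data$sharpness,
                                   colour = .data$fov)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "slice", y = "sharpness (summed |gradient|, HU/mm)") +
    ggplot2::theme_minimal()
}

#' Line profile across a volume slice
#'
#' Extracts image values along a horizontal line of one slice for the two
#' volumes of an aligned pair — the classic visual check that the small-FOV
#' reconstruction resolves a vessel boundary more steeply.
#'
#' @param small,large_resampled aligned [ct_volume()]s on one grid.
#' @param slice slice index.
#' @param y_mm physical y position (mm) of the line.
#' @return tibble with `x_mm`, `fov`, `hu`.
#' @export
line_profile <- function(small, large_resampled, slice, y_mm) {
  stop_if_geometry_mismatch(small$geometry, large_resampled$geometry,
                            "paired volumes")
  ys <- grid_coords(small$geometry, 2)
  j <- which.min(abs(ys - y_mm))
  xs <- grid_coords(small$geometry, 1)
  dplyr::bind_rows(
    tibble::tibble(x_mm = xs, fov = "small",
                   hu = small$values[, j, slice]),
    tibble::tibble(x_mm = xs, fov = "large",
                   hu = large_resampled$values[, j, slice])
  )
}
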