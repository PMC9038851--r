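#' End-to-end objective sharpness analysis on simulated phantom pairs
#'
#' For each dataset: draw a random leg phantom, reconstruct it at the large
#' and small FOV, segment the small-FOV volume (body, bone, analysis ROI),
#' resample the large-FOV volume onto the small-FOV grid, and score both
#' under the identical significant-edge mask. Deterministic given `seed`.
#'
#' @param n_pairs number of simulated datasets.
#' @param seed master integer seed; dataset `i` uses `seed + 1000 * i`
#'   derived streams.
#' @param fov_large,fov_small FOV diameters (mm).
#' @param matrix reconstruction matrix size (default 512).
#' @param psf_fwhm,noise_sd reconstruction physics, see [recon_spec()].
#' @param n_slices,slice_spacing phantom extent along z.
#' @param dilation_radius_mm bone/air exclusion margin, see [analysis_roi()].
#' @param spline_order resampling order, see [resample_to_grid()].
#' @param edge_scope,normalization metric options, see [compare_pair()].
#' @param oversample_spacing phantom rendering resolution (mm).
#' @return An object of class `objective_report`: list with `results` (one
#'   tibble row per dataset: mean_difference, p_value, fraction of slices
#'   with positive difference, ...), `per_slice` (all slice records),
#'   `config`, `package_version`.
#' @export
run_objective <- function(n_pairs = 5L, seed = 1L,
                          fov_large = 422.67, fov_small = 220.19,
                          matrix = 512L,
                          psf_fwhm = 0.6, noise_sd = 10,
                          n_slices = 5L, slice_spacing = 2,
                          dilation_radius_mm = 2, spline_order = 3L,
                          edge_scope = "per-volume", normalization = "sum",
                          oversample_spacing = 0.1) {
  config <- list(
    n_pairs = n_pairs, seed = seed, fov_large = fov_large,
    fov_small = fov_small, matrix = matrix,
    psf_fwhm = psf_fwhm, noise_sd = noise_sd,
    n_slices = n_slices, slice_spacing = slice_spacing,
    dilation_radius_mm = dilation_radius_mm, spline_order = spline_order,
    edge_scope = edge_scope, normalization = normalization,
    oversample_spacing = oversample_spacing
  )
  rows <- list()
  slices <- list()
  for (i in seq_len(n_pairs)) {
    s_i <- as.integer(seed + 1000L * i)
    phantom <- random_phantom_spec(s_i, n_slices = n_slices,
                                   slice_spacing = slice_spacing)
    pair <- simulate_recon_pair(
      phantom, fov_large = fov_large, fov_small = fov_small, matrix = matrix,
      psf_fwhm = psf_fwhm, noise_sd = noise_sd, seed = s_i + 1L,
      oversample_spacing = oversample_spacing
    )
    masks <- build_mask_set(pair$small,
                            dilation_radius_mm = dilation_radius_mm)
    aligned <- align_pair(pair$large, pair$small,
                          spline_order = spline_order)
    cmp <- compare_pair(aligned$small, aligned$large_resampled, masks,
                        edge_scope = edge_scope,
                        normalization = normalization)
    g <- glance(cmp)
    g$dataset <- i
    g$seed <- s_i
    g$frac_slices_small_sharper <- mean(cmp$per_slice$difference > 0)
    rows[[i]] <- g
    sl <- cmp$per_slice
    sl$dataset <- i
    slices[[i]] <- sl
  }
  results <- dplyr::relocate(dplyr::bind_rows(rows), "dataset")
  structure(
    list(
      results = results,
      per_slice = dplyr::bind_rows(slices),
      aggregate_mean_difference = mean(results$mean_difference),
      config = config,
      package_version = as.character(utils::packageVersion("fovsharp"))
    ),
    class = "objective_report"
  )
}

#' @export
print.objective_report <- function(x, ...) {
  cat(sprintf(
    "<objective_report> %d simulated pairs | aggregate mean difference %.3g | %d/%d pairs p < 0.05\n",
    nrow(x$results), x$aggregate_mean_difference,
    sum(x$results$p_value < 0.05), nrow(x$results)
  ))
  invisible(x)
}

#' End-to-end subjective (reader-study) analysis
#'
#' Runs the reader-study statistics chain on a rating table: non-diagnostic
#' exclusion, ICC(2,k) on the full per-reader data, reader pooling, and
#' per-segment summaries with paired small-vs-large tests. The table may be
#' supplied directly, read from CSV, or simulated from a [rating_spec()].
#'
#' @param ratings a rating table, a CSV path, or a [rating_spec()].
#' @param exclusion_policy see [exclude_non_diagnostic()].
#' @param pool whether to pool readers before the per-segment tests
#'   (default TRUE; unpooled mode runs the tests per reader and is exposed
#'   for sensitivity checks).
#' @return An object of class `subjective_report`: list with `summary` (a
#'   [summarize_segments()] tibble), `icc` (an [icc2k()] result), `pooled`
#'   (figure-ready pooled scores), `n_excluded`, `config`,
#'   `package_version`.
#' @export
run_subjective <- function(ratings,
                           exclusion_policy = "per-segment-pair",
                           pool = TRUE) {
  table <- if (inherits(ratings, "rating_spec")) {
    simulate_ratings(ratings)
  } else if (is.character(ratings)) {
    read_ratings(ratings)
  } else {
    validate_ratings(ratings)
  }
  kept <- exclude_non_diagnostic(table, exclusion_policy)
  # the ICC needs every reader per target; exclusion can leave partial
  # targets, which are omitted from the agreement analysis only
  n_readers <- length(unique(table$reader))
  complete_keys <- dplyr::filter(
    dplyr::count(kept, .data$exam, .data$side, .data$level, .data$fov),
    .data$n == n_readers
  )
  icc_input <- dplyr::semi_join(kept, complete_keys,
                                by = c("exam", "side", "level", "fov"))
  icc <- icc2k(ratings_to_matrix(icc_input))
  pooled <- pool_readers(kept)
  summary <- if (pool) {
    summarize_segments(pooled)
  } else {
    # unpooled sensitivity mode: treat each reader's score as one record
    summarize_segments(
      dplyr::mutate(kept,
                    exam = paste(.data$exam, .data$reader, sep = "."),
                    score = as.numeric(.data$score))
    )
  }
  structure(
    list(
      summary = summary, icc = icc, pooled = pooled,
      n_excluded = nrow(table) - nrow(kept),
      config = list(exclusion_policy = exclusion_policy, pool = pool,
                    alpha = 0.05, multiple_testing_correction = "none"),
      package_version = as.character(utils::packageVersion("fovsharp"))
    ),
    class = "subjective_report"
  )
}

#' @export
print.subjective_report <- function(x, ...) {
  cat(sprintf("<subjective_report> %d records excluded as non-diagnostic\n",
              x$n_excluded))
  print(x$icc)
  print(as.data.frame(x$summary), digits = 3)
  invisible(x)
}

#' Write a machine-readable report
#'
#' Emits the per-segment summary (or per-slice table) as CSV and the
#' headline quantities plus the full effective configuration as JSON.
#'
#' @param report an `objective_report` or `subjective_report`.
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (inherits(report, "objective_report")) {
    csv <- file.path(dir, "per_slice.csv")
    utils::write.csv(report$per_slice, csv, row.names = FALSE)
    js <- file.path(dir, "objective_summary.json")
    jsonlite::write_json(
      list(
        results = report$results,
        aggregate_mean_difference = report$aggregate_mean_difference,
        config = report$config, package_version = report$package_version
      ),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else if (inherits(report, "subjective_report")) {
    csv <- file.path(dir, "segment_summary.csv")
    utils::write.csv(as.data.frame(report$summary), csv, row.names = FALSE)
    js <- file.path(dir, "subjective_summary.json")
    jsonlite::write_json(
      list(
        icc = glance(report$icc), n_excluded = report$n_excluded,
        config = report$config, package_version = report$package_version
      ),
      js, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  } else {
    stop("unknown report type")
  }
  invisible(c(csv, js))
}
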