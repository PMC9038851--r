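#' Exclude non-diagnostic segment ratings
#'
#' Segments scored 1 (non-diagnostic) are removed before further analysis.
#' Two policies: `"per-segment-pair"` (default) removes both FOV members of
#' any (exam, side, level, reader) whose large- or small-FOV rating is
#' non-diagnostic, preserving the pairing needed by paired tests;
#' `"per-rating"` removes only the score-1 records themselves.
#'
#' @param table a rating table (see [validate_ratings()]).
#' @param policy `"per-segment-pair"` or `"per-rating"`.
#' @return the filtered tibble.
#' @export
exclude_non_diagnostic <- function(table,
                                   policy = c("per-segment-pair", "per-rating")) {
  policy <- match.arg(policy)
  table <- validate_ratings(table)
  if (policy == "per-rating") {
    return(dplyr::filter(table, !.data$non_diagnostic))
  }
  bad <- dplyr::distinct(
    dplyr::filter(table, .data$non_diagnostic),
    .data$exam, .data$side, .data$level, .data$reader
  )
  dplyr::anti_join(table, bad, by = c("exam", "side", "level", "reader"))
}

#' Pool reader scores
#'
#' Averages the available readers' scores within each
#' (exam, side, level, fov) key, recording how many readers contributed.
#'
#' @param table a rating table.
#' @return tibble keyed by (exam, side, level, fov) with `score` (mean over
#'   readers) and `n_readers`.
#' @export
pool_readers <- function(table) {
  table <- validate_ratings(table)
  dplyr::summarise(
    dplyr::group_by(table, .data$exam, .data$side, .data$level, .data$fov),
    score = mean(.data$score),
    n_readers = dplyr::n(),
    .groups = "drop"
  )
}

#' Per-segment Likert score summaries and FOV comparison
#'
#' For each vessel level and FOV: mean, sample SD, median and quartiles of
#' the pooled scores; per level, the mean difference small - large and the
#' p-values of a Wilcoxon signed-rank test (exact, tie-aware) and a paired
#' t-test on the (exam, side)-paired pooled scores.
#'
#' @param pooled a pooled rating table from [pool_readers()].
#' @return A tibble of class `segment_summary`: one row per (level, fov)
#'   with columns `mean`, `sd`, `median`, `q25`, `q75`, `n`, and per-level
#'   `delta_mean`, `p_wilcoxon`, `p_ttest` (repeated on both FOV rows).
#' @export
summarize_segments <- function(pooled) {
  stopifnot(all(c("exam", "side", "level", "fov", "score") %in% names(pooled)))
  if (nrow(pooled) == 0) stop("empty pooled table")
  stats_tab <- dplyr::summarise(
    dplyr::group_by(pooled, .data$level, .data$fov),
    mean = mean(.data$score),
    sd = if (dplyr::n() > 1) stats::sd(.data$score) else NA_real_,
    median = stats::median(.data$score),
    q25 = unname(stats::quantile(.data$score, 0.25)),
    q75 = unname(stats::quantile(.data$score, 0.75)),
    n = dplyr::n(),
    .groups = "drop"
  )
  wide <- tidyr::pivot_wider(
    pooled[, c("exam", "side", "level", "fov", "score")],
    names_from = "fov", values_from = "score"
  )
  per_level <- dplyr::group_modify(
    dplyr::group_by(wide, .data$level),
    function(df, key) {
      df <- df[stats::complete.cases(df[, c("small", "large")]), ]
      d <- df$small - df$large
      p_w <- if (length(d) >= 1 && any(d != 0)) {
        wilcoxon_signed_rank(d)$p_value
      } else {
        NA_real_
      }
      p_t <- if (length(d) >= 2 && stats::sd(d) > 0) {
        stats::t.test(df$small, df$large, paired = TRUE)$p.value
      } else {
        NA_real_
      }
      tibble::tibble(
        delta_mean = mean(df$small) - mean(df$large),
        p_wilcoxon = p_w, p_ttest = p_t, n_pairs = nrow(df)
      )
    }
  )
  out <- dplyr::left_join(stats_tab, dplyr::ungroup(per_level), by = "level")
  structure(dplyr::arrange(out, .data$level, .data$fov),
            class = c("segment_summary", class(out)))
}
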