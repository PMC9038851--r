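#' Intraclass correlation ICC(2,k): two-way random effects, absolute
#' agreement, reliability of the mean of k raters
#'
#' Computed from the two-way ANOVA decomposition of the complete
#' targets-by-raters score matrix: with row (target) mean square `MSR`,
#' column (rater) mean square `MSC` and residual `MSE`,
#' \deqn{ICC(2,k) = \frac{MSR - MSE}{MSR + (MSC - MSE)/n}}
#' where `n` is the number of targets. The 95% confidence interval follows
#' McGraw & Wong's F-based interval for the single-rater agreement ICC,
#' transformed to the k-rater form by the Spearman-Brown step-up. Reliability
#' is categorised as poor (< 0.5), moderate (0.5-0.75), good (0.75-0.9) or
#' excellent (> 0.9).
#'
#' @param scores numeric matrix, targets in rows, raters in columns; must be
#'   complete (no NA; no imputation is performed).
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An object of class `icc_result`: list with `icc`, `ci_lower`,
#'   `ci_upper`, `category`, the mean squares, `n_targets`, `n_raters`,
#'   `model`.
#' @export
icc2k <- function(scores, conf_level = 0.95) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < 2 || k < 2) stop("need >= 2 targets and >= 2 raters")
  if (anyNA(scores)) stop("missing data: ICC requires a complete matrix")

  row_means <- rowMeans(scores)
  col_means <- colMeans(scores)
  grand <- mean(scores)
  msr <- k * sum((row_means - grand)^2) / (n - 1)
  msc <- n * sum((col_means - grand)^2) / (k - 1)
  sse <- sum((scores - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)
  # single-rater agreement ICC and its F-based CI (then Spearman-Brown up)
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- k * icc_1 / (n * (1 - icc_1))
  b <- 1 + k * icc_1 * (n - 1) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r1) k * r1 / (1 + (k - 1) * r1)

  structure(
    list(
      icc = icc_k, ci_lower = sb(l1), ci_upper = sb(u1),
      conf_level = conf_level,
      category = icc_category(icc_k),
      msr = msr, msc = msc, mse = mse,
      n_targets = n, n_raters = k,
      model = "two-way random, absolute agreement, mean of k raters (ICC2k)"
    ),
    class = "icc_result"
  )
}

#' Reliability category of an ICC value
#'
#' Bands: below 0.5 poor, 0.5 to 0.75 moderate, 0.75 to 0.9 good, above 0.9
#' excellent.
#'
#' @param icc numeric ICC value(s).
#' @return character vector of categories.
#' @export
icc_category <- function(icc) {
  dplyr::case_when(
    icc < 0.5 ~ "poor",
    icc <= 0.75 ~ "moderate",
    icc <= 0.9 ~ "good",
    TRUE ~ "excellent"
  )
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(2,k) = %.3f (%d%% CI %.3f-%.3f), %s reliability [%d targets x %d raters]\n",
    x$icc, round(100 * x$conf_level), x$ci_lower, x$ci_upper, x$category,
    x$n_targets, x$n_raters
  ))
  invisible(x)
}

#' Rating table to targets-by-raters matrix
#'
#' Each (exam, side, level, fov) combination is one target; columns are
#' readers. Errors if any reader is missing for any target.
#'
#' @param table a rating table.
#' @return numeric matrix suitable for [icc2k()].
#' @export
ratings_to_matrix <- function(table) {
  table <- validate_ratings(table)
  wide <- tidyr::pivot_wider(
    table[, c("exam", "side", "level", "fov", "reader", "score")],
    names_from = "reader", values_from = "score"
  )
  m <- as.matrix(wide[, !(names(wide) %in% c("exam", "side", "level", "fov"))])
  if (anyNA(m)) stop("incomplete rating matrix: some readers missing")
  m
}

#' @export
#' @importFrom generics tidy
generics::tidy

#' @export
#' @importFrom generics glance
generics::glance

#' @method tidy icc_result
#' @export
tidy.icc_result <- function(x, ...) {
  tibble::tibble(
    term = "ICC(2,k)", estimate = x$icc,
    conf.low = x$ci_lower, conf.high = x$ci_upper,
    category = x$category
  )
}

#' @method glance icc_result
#' @export
glance.icc_result <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, conf.low = x$ci_lower, conf.high = x$ci_upper,
    category = x$category, n_targets = x$n_targets, n_raters = x$n_raters,
    msr = x$msr, msc = x$msc, mse = x$mse
  )
}

#' @method tidy pair_comparison
#' @export
tidy.pair_comparison <- function(x, ...) {
  x$per_slice
}

#' @method glance pair_comparison
#' @export
glance.pair_comparison <- function(x, ...) {
  tibble::tibble(
    mean_difference = x$mean_difference,
    small_mean = x$small_mean,
    large_mean = x$large_mean,
    statistic = x$statistic,
    p_value = x$p_value,
    n_slices = x$n_slices
  )
}
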