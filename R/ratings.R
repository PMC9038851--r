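#' Reference per-segment Likert score moments
#'
#' Mean and standard deviation of the 5-point image-quality score for each
#' vessel segment (femoral, popliteal, crural, pedal) and FOV size, as
#' observed in a 100-exam lower-extremity CTA reader study with three
#' readers. These are the default calibration of the rating simulator.
#'
#' @return A tibble with columns `level`, `fov`, `mean`, `sd`.
#' @export
reference_rating_moments <- function() {
  tibble::tibble(
    level = rep(c("femoral", "popliteal", "crural", "pedal"), each = 2),
    fov = rep(c("large", "small"), 4),
    mean = c(4.02, 4.70, 3.82, 4.65, 3.06, 4.18, 2.79, 3.87),
    sd = c(0.65, 0.48, 0.63, 0.52, 0.72, 0.72, 0.73, 0.82)
  )
}

#' Specification of the ordinal rating simulator
#'
#' Ratings are modelled as a discretised latent normal: each (exam, side,
#' level, FOV, reader) cell draws a latent score
#' `mean + sd * (sqrt(rho) * b + sqrt(1 - rho) * e)` with `b` a standard
#' normal effect shared by all readers and both FOVs of one
#' (exam, side, level), and `e` independent reader noise; the latent value is
#' rounded to the nearest integer and clipped to [1, 5]. The marginal latent
#' mean and SD of every cell thus equal the calibrated moments exactly, while
#' `rho` controls reader agreement and the small/large pairing correlation.
#'
#' @param moments tibble with columns `level`, `fov`, `mean`, `sd`; defaults
#'   to [reference_rating_moments()].
#' @param n_exams number of exams (default 100, two sides each).
#' @param n_readers number of readers (default 3).
#' @param rho fraction of latent variance shared across readers/FOVs, in
#'   [0, 1) (default 0.6).
#' @param calibration `"score"` (default): the latent mean/SD of each cell
#'   are adjusted so that the *discretised* score moments equal the
#'   calibrated moments (rounding to integers and clipping to [1, 5] bias
#'   the moments, and the calibration targets describe observed scores, not
#'   a latent scale); `"latent"`: use the moments directly as latent
#'   parameters.
#' @param seed integer seed.
#' @return An object of class `rating_spec`.
#' @export
rating_spec <- function(moments = reference_rating_moments(),
                        n_exams = 100L, n_readers = 3L, rho = 0.6,
                        calibration = c("score", "latent"),
                        seed = 1L) {
  calibration <- match.arg(calibration)
  moments <- tibble::as_tibble(moments)
  stopifnot(all(c("level", "fov", "mean", "sd") %in% names(moments)),
            all(moments$mean >= 1), all(moments$mean <= 5),
            all(moments$sd > 0),
            n_exams >= 1, n_readers >= 1, rho >= 0, rho < 1)
  if (calibration == "score") {
    fit <- purrr::map2(moments$mean, moments$sd, solve_latent_moments)
    moments$mean <- purrr::map_dbl(fit, 1)
    moments$sd <- purrr::map_dbl(fit, 2)
  }
  structure(
    list(moments = moments, n_exams = as.integer(n_exams),
         n_readers = as.integer(n_readers), rho = as.numeric(rho),
         calibration = calibration, seed = as.integer(seed)),
    class = "rating_spec"
  )
}

# score distribution of round-and-clip discretised N(mu, sigma)
discretized_score_moments <- function(mu, sigma) {
  cuts <- c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
  p <- diff(stats::pnorm(cuts, mu, sigma))
  m <- sum(p * (1:5))
  s <- sqrt(sum(p * (1:5)^2) - m^2)
  c(mean = m, sd = s)
}

# invert the discretisation: latent (mu, sigma) whose round-and-clip score
# moments hit the targets
solve_latent_moments <- function(target_mean, target_sd) {
  obj <- function(par) {
    if (par[2] <= 0.01) return(1e6)
    mo <- discretized_score_moments(par[1], par[2])
    (mo[1] - target_mean)^2 + (mo[2] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, target_sd), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  c(mu = fit$par[1], sigma = fit$par[2])
}

#' Simulate an ordinal reader-rating table
#'
#' Draws one 1-5 Likert score per (exam, side, level, fov, reader) cell
#' under the discretised latent-normal model of [rating_spec()]. A score of
#' 1 means non-diagnostic and sets the `non_diagnostic` flag. Reproducible:
#' equal seeds give identical tables.
#'
#' @param spec a [rating_spec()].
#' @return A tibble with columns `exam`, `side`, `level`, `fov`, `reader`,
#'   `score`, `non_diagnostic`.
#' @export
simulate_ratings <- function(spec) {
  stopifnot(inherits(spec, "rating_spec"))
  levels_ <- unique(spec$moments$level)
  grid <- tidyr::expand_grid(
    exam = seq_len(spec$n_exams),
    side = c("right", "left"),
    level = levels_,
    fov = unique(spec$moments$fov),
    reader = seq_len(spec$n_readers)
  )
  grid <- dplyr::left_join(grid, spec$moments, by = c("level", "fov"))
  with_local_seed(spec$seed, {
    shared <- tidyr::expand_grid(
      exam = seq_len(spec$n_exams), side = c("right", "left"),
      level = levels_
    )
    shared$b <- stats::rnorm(nrow(shared))
    grid <- dplyr::left_join(grid, shared, by = c("exam", "side", "level"))
    e <- stats::rnorm(nrow(grid))
    latent <- grid$mean +
      grid$sd * (sqrt(spec$rho) * grid$b + sqrt(1 - spec$rho) * e)
    score <- pmin(pmax(round(latent), 1L), 5L)
    dplyr::mutate(
      dplyr::select(grid, "exam", "side", "level", "fov", "reader"),
      score = as.integer(score),
      non_diagnostic = score == 1L
    )
  })
}

#' Validate a rating table
#'
#' Checks the rating-table contract: required columns, integer scores in
#' 1..5, the non-diagnostic flag consistent with score 1, and no duplicated
#' (exam, side, level, fov, reader) key.
#'
#' @param table a data frame of ratings.
#' @return the table (as tibble, with `non_diagnostic` filled in),
#'   invisibly usable in a pipe.
#' @export
validate_ratings <- function(table) {
  table <- tibble::as_tibble(table)
  need <- c("exam", "side", "level", "fov", "reader", "score")
  missing <- setdiff(need, names(table))
  if (length(missing) > 0) {
    stop("rating table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (!all(table$score %in% 1:5)) stop("scores must be integers in 1..5")
  if (!"non_diagnostic" %in% names(table)) {
    table$non_diagnostic <- table$score == 1L
  } else if (!all(table$non_diagnostic == (table$score == 1L))) {
    stop("non_diagnostic flag must equal (score == 1)")
  }
  dup <- duplicated(table[, c("exam", "side", "level", "fov", "reader")])
  if (any(dup)) stop("duplicated (exam, side, level, fov, reader) keys")
  table
}

#' Read / write rating tables as CSV
#'
#' @param path CSV file with header `exam,side,level,fov,reader,score`.
#' @return [read_ratings()]: a validated tibble.
#' @export
read_ratings <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty ratings file")
  validate_ratings(tab)
}

#' @rdname read_ratings
#' @param table a rating table.
#' @export
write_ratings <- function(table, path) {
  table <- validate_ratings(table)
  utils::write.csv(
    table[, c("exam", "side", "level", "fov", "reader", "score")],
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
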