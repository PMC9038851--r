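make_table <- function(scores_by_key) {
  # scores_by_key: tibble(exam, side, level, fov, reader, score)
  validate_ratings(scores_by_key)
}

test_that("non-diagnostic exclusion respects the pairing policy", {
  tab <- simulate_ratings(rating_spec(n_exams = 50, seed = 4))

  # no 1-scores: unchanged
  clean <- dplyr::filter(tab, score > 1)
  clean$non_diagnostic <- FALSE
  expect_equal(nrow(exclude_non_diagnostic(clean)), nrow(clean))

  # per-rating policy removes exactly the 1-scores
  kept <- exclude_non_diagnostic(tab, "per-rating")
  expect_equal(nrow(tab) - nrow(kept), sum(tab$score == 1))

  # per-segment-pair removes the partner FOV record too
  one <- tibble::tibble(
    exam = 1L, side = "right", level = "crural",
    fov = rep(c("large", "small"), each = 1), reader = 1L,
    score = c(1L, 4L)
  )
  two <- tibble::tibble(
    exam = 2L, side = "left", level = "pedal",
    fov = c("large", "small"), reader = 1L, score = c(3L, 4L)
  )
  res <- exclude_non_diagnostic(make_table(rbind(one, two)))
  expect_equal(nrow(res), 2)
  expect_true(all(res$exam == 2L))
})

test_that("reader pooling averages available readers per segment", {
  tab <- tibble::tibble(
    exam = 1L, side = "right", level = "femoral", fov = "small",
    reader = 1:3, score = c(4L, 4L, 5L)
  )
  pooled <- pool_readers(make_table(tab))
  expect_equal(pooled$score, 13 / 3)
  expect_equal(pooled$n_readers, 3L)

  # single reader: identity
  single <- pool_readers(make_table(tab[1, ]))
  expect_equal(single$score, 4)

  # pooled row count equals the number of distinct keys
  big <- simulate_ratings(rating_spec(n_exams = 30, seed = 6))
  pooled_big <- pool_readers(big)
  expect_equal(nrow(pooled_big),
               nrow(dplyr::distinct(big, exam, side, level, fov)))
})

test_that("ICC(2,k) matches the longhand ANOVA oracle and the bands", {
  # perfect agreement with between-target variance: ICC = 1
  m <- cbind(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(icc2k(m)$icc, 1)

  # 4x3 toy matrix against the longhand oracle
  toy <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2))
  expect_equal(icc2k(toy)$icc, oracle_icc2k(toy), tolerance = 1e-12)

  # random matrices
  set.seed(31)
  for (i in 1:200) {
    n <- sample(3:10, 1)
    k <- sample(2:5, 1)
    mat <- matrix(rnorm(n * k, 3, 1), n, k) + rnorm(n)
    expect_equal(icc2k(mat)$icc, oracle_icc2k(mat), tolerance = 1e-9)
  }

  expect_equal(icc_category(0.82), "good")
  expect_equal(icc_category(c(0.2, 0.6, 0.95)),
               c("poor", "moderate", "excellent"))
  expect_error(icc2k(cbind(c(1, NA), c(2, 3))), "missing")
  expect_error(icc2k(matrix(1:3, 3, 1)), ">= 2")
})

test_that("ICC confidence interval matches an independent reference", {
  # reference values computed once with an independent ANOVA-based
  # implementation (pingouin ICC2k) for this fixed matrix
  mat <- rbind(c(4, 4, 5), c(3, 3, 4), c(5, 5, 5), c(2, 3, 3),
               c(4, 5, 5), c(1, 2, 2))
  res <- icc2k(mat)
  expect_equal(res$icc, 0.9460043196544276, tolerance = 1e-9)
  expect_equal(res$ci_lower, 0.67, tolerance = 0.005)
  expect_equal(res$ci_upper, 0.99, tolerance = 0.005)
})

test_that("signed-rank test matches exhaustive enumeration", {
  # all-positive n = 6: W = 21, two-sided p = 1/32
  d <- c(0.5, 1, 1.5, 2, 2.5, 3)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$statistic, 21)
  expect_equal(res$p_value, 2 / 64)

  # random small cases, with and without ties and zeros
  set.seed(41)
  for (i in 1:150) {
    n <- sample(2:8, 1)
    d <- sample(c(-3:-1, 1:3), n, replace = TRUE)
    if (all(d == 0)) next
    ours <- wilcoxon_signed_rank(d)
    orc <- oracle_signed_rank(d)
    expect_equal(ours$statistic, orc$statistic)
    expect_equal(ours$p_value, orc$p_value, tolerance = 1e-12)
  }

  # agrees with the classical exact test when there are no ties
  set.seed(42)
  d <- c(1.3, -0.4, 2.2, 0.7, -1.9, 3.1, 0.2, -2.6)
  expect_equal(wilcoxon_signed_rank(d)$p_value,
               stats::wilcox.test(d, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_error(wilcoxon_signed_rank(c(0, 0)), "degenerate")
})

test_that("rank-sum test matches exhaustive enumeration", {
  # maximally separated groups: p = 2/20
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$statistic, 6)
  expect_equal(res$p_value, 0.1)

  # identical groups: p = 1
  expect_equal(wilcoxon_rank_sum(c(2, 3, 4), c(2, 3, 4))$p_value, 1)

  set.seed(43)
  for (i in 1:150) {
    m <- sample(2:4, 1)
    n <- sample(2:4, 1)
    a <- sample(1:5, m, replace = TRUE)
    b <- sample(1:5, n, replace = TRUE)
    ours <- wilcoxon_rank_sum(a, b)
    orc <- oracle_rank_sum(a, b)
    expect_equal(ours$statistic, orc$statistic)
    expect_equal(ours$p_value, orc$p_value, tolerance = 1e-12)
  }

  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("large-sample approximations stay close to the exact tail", {
  set.seed(44)
  d <- rnorm(40, 0.3)
  approx_p <- wilcoxon_signed_rank(d)$p_value
  exact_p <- wilcoxon_signed_rank(d, exact_limit = 64L)$p_value
  expect_equal(approx_p, exact_p, tolerance = 0.02)

  a <- rnorm(20)
  b <- rnorm(20, 0.4)
  approx_p <- wilcoxon_rank_sum(a, b)$p_value
  exact_p <- wilcoxon_rank_sum(a, b, exact_limit = 64L)$p_value
  expect_equal(approx_p, exact_p, tolerance = 0.02)
})

test_that("segment summaries report moments, quartiles and paired tests", {
  pooled <- pool_readers(
    exclude_non_diagnostic(simulate_ratings(rating_spec(n_exams = 60, seed = 8)))
  )
  sm <- summarize_segments(pooled)
  expect_equal(nrow(sm), 8)

  # delta means equal independently recomputed small - large means
  for (lev in unique(sm$level)) {
    ms <- mean(pooled$score[pooled$level == lev & pooled$fov == "small"])
    ml <- mean(pooled$score[pooled$level == lev & pooled$fov == "large"])
    # recompute over complete pairs only, as the summary does
    wide <- tidyr::pivot_wider(pooled[pooled$level == lev,
                                      c("exam", "side", "fov", "score")],
                               names_from = "fov", values_from = "score")
    wide <- wide[stats::complete.cases(wide), ]
    expect_equal(unique(sm$delta_mean[sm$level == lev]),
                 mean(wide$small) - mean(wide$large), tolerance = 1e-12)
  }

  # constant scores: sd and IQR are zero
  const <- tibble::tibble(
    exam = rep(1:4, each = 2), side = "right", level = "femoral",
    fov = rep(c("large", "small"), 4), score = 4, n_readers = 3L
  )
  smc <- summarize_segments(const)
  expect_true(all(smc$sd == 0))
  expect_true(all(smc$q75 - smc$q25 == 0))

  # invariant to record order and exam relabelling
  perm <- pooled[sample(nrow(pooled)), ]
  perm$exam <- match(perm$exam, sort(unique(perm$exam))) + 1000L
  sm2 <- summarize_segments(perm)
  expect_equal(sm$mean, sm2$mean)
  expect_equal(sm$delta_mean, sm2$delta_mean)
  expect_equal(sm$p_wilcoxon, sm2$p_wilcoxon)
})
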