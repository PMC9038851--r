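# Exact, tie-aware Wilcoxon tests.
#
# Both tests use tie-averaged ranks (so half-integer ranks are possible) and
# compute the exact permutation null distribution for small samples by
# dynamic programming over doubled (integer) ranks; larger samples use the
# normal approximation with tie-corrected variance and a 0.5 continuity
# correction. Two-sided p-values are twice the smaller tail, capped at 1.

# distribution of W+ = sum of ranks of positively signed observations over
# all 2^n equiprobable sign assignments; ranks may be half-integers, so the
# DP runs on 2*rank. Returns P(2W = s) indexed by s = 0..sum(2r).
signed_rank_null <- function(ranks2) {
  total <- sum(ranks2)
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (r in ranks2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f / 2^length(ranks2)
}

#' Wilcoxon signed-rank test (exact, tie-aware)
#'
#' Zero differences are dropped; absolute differences are ranked with tied
#' ranks averaged; the statistic is `W` = sum of ranks of the positive
#' differences. For `n <= exact_limit` non-zero differences the exact null
#' distribution over all sign assignments is used (valid with ties); above
#' that, a normal approximation with tie-aware variance `sum(r^2)/4` and
#' continuity correction.
#'
#' @param d numeric vector of paired differences.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return list with `statistic` (W), `p_value` (two-sided), `n` (non-zero
#'   differences), `method`.
#' @export
wilcoxon_signed_rank <- function(d, exact_limit = 25L) {
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop("degenerate data: all differences are zero")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))
  if (n <= exact_limit) {
    null <- signed_rank_null(r2)
    w2 <- as.integer(round(2 * w))
    lower <- sum(null[seq_len(w2 + 1L)])
    upper <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = n, method = method)
}

# distribution of the rank sum of m items drawn without replacement from the
# pooled (doubled) ranks: DP over items, dimensions (chosen + 1) x (sum + 1)
rank_sum_null <- function(ranks2, m) {
  total <- sum(ranks2)
  f <- matrix(0, nrow = m + 1L, ncol = total + 1L)
  f[1L, 1L] <- 1
  for (r in ranks2) {
    upper <- min(m, nrow(f) - 1L)
    for (j in rev(seq_len(upper))) {
      cols <- (r + 1L):(total + 1L)
      f[j + 1L, cols] <- f[j + 1L, cols] + f[j, cols - r]
    }
  }
  f[m + 1L, ] / choose(length(ranks2), m)
}

#' Wilcoxon rank-sum test (exact, tie-aware)
#'
#' Compares two independent groups by the rank sum of the first group over
#' the pooled tie-averaged ranks. Exact permutation null for pooled sizes
#' `<= exact_limit`; otherwise normal approximation with the tie-corrected
#' variance and continuity correction.
#'
#' @param a,b numeric score vectors for the two groups.
#' @param exact_limit largest pooled size for the exact distribution
#'   (default 25).
#' @return list with `statistic` (rank sum of `a`), `p_value` (two-sided),
#'   `n` (pooled size), `method`.
#' @export
wilcoxon_rank_sum <- function(a, b, exact_limit = 25L) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0) stop("both groups must be non-empty")
  m <- length(a)
  pooled <- c(a, b)
  nn <- length(pooled)
  r <- rank(pooled)
  w <- sum(r[seq_len(m)])
  if (nn <= exact_limit) {
    r2 <- as.integer(round(2 * r))
    null <- rank_sum_null(r2, m)
    w2 <- as.integer(round(2 * w))
    lower <- sum(null[seq_len(w2 + 1L)])
    upper <- sum(null[(w2 + 1L):length(null)])
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    nb <- nn - m
    mu <- m * (nn + 1) / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (nn * (nn - 1))
    sigma <- sqrt(m * nb / 12 * ((nn + 1) - tie_term))
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = w, p_value = p, n = nn, method = method)
}
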