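# Independent brute-force oracles. Deliberately written in plain-loop style,
# sharing no code with the package implementations they check.

# exhaustive Otsu scan over histogram splits; same candidate set and
# tie-break (lowest split) as the contract: threshold after bin t maximises
# between-class variance
oracle_otsu_hist <- function(counts, mids) {
  n_bins <- length(counts)
  best_sb <- -Inf
  best_t <- NA_integer_
  total <- sum(counts)
  for (t in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:t])
    w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / w0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    sb <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (sb > best_sb) {
      best_sb <- sb
      best_t <- t
    }
  }
  (mids[best_t] + mids[best_t + 1]) / 2
}

# elementwise central/one-sided finite differences in HU/mm
oracle_gradmag <- function(slice, spacing) {
  n <- nrow(slice); m <- ncol(slice)
  out <- matrix(0, n, m)
  for (i in 1:n) {
    for (j in 1:m) {
      gx <- if (i == 1) {
        (slice[2, j] - slice[1, j]) / spacing[1]
      } else if (i == n) {
        (slice[n, j] - slice[n - 1, j]) / spacing[1]
      } else {
        (slice[i + 1, j] - slice[i - 1, j]) / (2 * spacing[1])
      }
      gy <- if (j == 1) {
        (slice[i, 2] - slice[i, 1]) / spacing[2]
      } else if (j == m) {
        (slice[i, m] - slice[i, m - 1]) / spacing[2]
      } else {
        (slice[i, j + 1] - slice[i, j - 1]) / (2 * spacing[2])
      }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  }
  out
}

# full-pipeline single-slice metric, straight-line: gradient by loops, Otsu
# by exhaustive scan on the in-ROI gradient values, sum over the edge mask
oracle_slice_metric <- function(slice, roi, spacing, n_bins = 256) {
  gm <- oracle_gradmag(slice, spacing)
  vals <- gm[roi]
  rng <- range(vals)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- integer(n_bins)
  for (v in vals) {
    b <- max(1, min(n_bins, findInterval(v, breaks, rightmost.closed = TRUE)))
    counts[b] <- counts[b] + 1
  }
  best_sb <- -Inf; best_t <- NA
  total <- sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  for (t in 1:(n_bins - 1)) {
    w0 <- sum(counts[1:t]); w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:t] * mids[1:t]) / w0
    mu1 <- sum(counts[(t + 1):n_bins] * mids[(t + 1):n_bins]) / w1
    sb <- (w0 / total) * (w1 / total) * (mu0 - mu1)^2
    if (sb > best_sb) { best_sb <- sb; best_t <- t }
  }
  thr <- breaks[best_t + 1]
  mask <- roi & gm >= thr
  sum(gm[mask])
}

# exact signed-rank test by enumerating all 2^n sign assignments
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  ws <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(s))[1:n]
    ws[s + 1] <- sum(r[signs == 1])
  }
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  list(statistic = w_obs, p_value = min(1, 2 * min(lower, upper)))
}

# exact rank-sum test by enumerating all assignments of m pooled ranks
oracle_rank_sum <- function(a, b) {
  m <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  w_obs <- sum(r[1:m])
  sets <- utils::combn(length(pooled), m)
  ws <- apply(sets, 2, function(ix) sum(r[ix]))
  lower <- mean(ws <= w_obs + 1e-9)
  upper <- mean(ws >= w_obs - 1e-9)
  list(statistic = w_obs, p_value = min(1, 2 * min(lower, upper)))
}

# longhand two-way ANOVA ICC(2,k): explicit sums of squares
oracle_icc2k <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  grand <- mean(mat)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(mat[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(mat[, j]) - grand)^2
  sst <- sum((mat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (msc - mse) / n)
}

# Monte-Carlo oracle for the discretised latent-normal score mean
oracle_discretized_mean <- function(mu, sigma, n = 2e5, seed = 99) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  x <- rnorm(n, mu, sigma)
  mean(pmin(pmax(round(x), 1), 5))
}

# 10-90% rise distance of a line profile climbing from `lo` to `hi`
rise_distance <- function(x, v, lo, hi) {
  t10 <- lo + 0.1 * (hi - lo)
  t90 <- lo + 0.9 * (hi - lo)
  xf <- seq(min(x), max(x), length.out = 4000)
  vf <- approx(x, v, xout = xf)$y
  peak <- which.max(vf)
  seg <- 1:peak
  x10 <- xf[seg][which(vf[seg] >= t10)[1]]
  x90 <- xf[seg][which(vf[seg] >= t90)[1]]
  x90 - x10
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
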