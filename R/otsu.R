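#' Otsu threshold of a sample or histogram
#'
#' Maximises the between-class variance
#' \eqn{\sigma_b^2(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} over all
#' candidate bin-edge thresholds of the value histogram. A value belongs to
#' the upper class when it is >= the returned threshold. Ties in
#' \eqn{\sigma_b^2} are broken towards the lowest threshold.
#'
#' @param values numeric sample (ignored when `counts` is given).
#' @param n_bins number of histogram bins over the sample range (default 256).
#' @param counts optional histogram counts; then `mids` gives bin centres.
#' @param mids bin centres accompanying `counts`.
#' @return the threshold (a bin edge) as a scalar.
#' @export
#' @examples
#' otsu_threshold(c(rnorm(100, 0), rnorm(100, 10)))
otsu_threshold <- function(values = NULL, n_bins = 256L, counts = NULL,
                           mids = NULL) {
  if (is.null(counts)) {
    values <- values[is.finite(values)]
    if (length(unique(values)) < 2L) {
      stop("degenerate input: need >= 2 distinct values for Otsu thresholding")
    }
    rng <- range(values)
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
    idx <- findInterval(values, breaks, rightmost.closed = TRUE)
    counts <- tabulate(idx, n_bins)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  } else {
    if (is.null(mids)) mids <- seq_along(counts) - 1
    stopifnot(length(counts) == length(mids), all(counts >= 0))
    if (sum(counts > 0) < 2L) {
      stop("degenerate input: need >= 2 occupied bins for Otsu thresholding")
    }
    breaks <- NULL
  }

  n <- sum(counts)
  w0 <- cumsum(counts)                       # class 0: bins 1..t
  m0 <- cumsum(counts * mids)
  wtot <- n
  mtot <- m0[length(m0)]
  k <- length(counts) - 1L                   # candidate splits after bin t
  w0 <- w0[1:k]; m0 <- m0[1:k]
  w1 <- wtot - w0
  valid <- w0 > 0 & w1 > 0
  mu0 <- m0 / w0
  mu1 <- (mtot - m0) / w1
  sb <- (w0 / wtot) * (w1 / wtot) * (mu0 - mu1)^2
  sb[!valid] <- -Inf
  best <- which.max(sb)                      # which.max takes the first max
  if (!is.null(breaks)) breaks[best + 1L] else (mids[best] + mids[best + 1L]) / 2
}
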