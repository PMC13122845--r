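# Internal numerical helpers shared across the pipeline.

#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  bad <- x < lower | x > upper
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < lower | x > upper
  }
  x
}

# Centered moving average with shrinking windows at the edges; O(n) via a
# cumulative sum so that full-length ICP traces stay cheap to smooth.
#' @keywords internal
#' @noRd
moving_average <- function(x, k) {
  n <- length(x)
  k <- max(1L, as.integer(k))
  if (k == 1L || n == 0L) return(x)
  h <- k %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Local-maximum detector with topographic prominence and a minimum peak
# separation, the two guards needed for ICP pulses whose P2 sub-peak can
# exceed P1.
#' @keywords internal
#' @noRd
find_peaks <- function(x, min_distance = 1L, min_prominence = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2:(n - 1L)] > x[1:(n - 2L)] & x[2:(n - 1L)] >= x[3:n]) + 1L
  if (length(cand) == 0L) return(integer(0))

  prom <- vapply(cand, function(i) {
    xi <- x[i]
    j <- i - 1L
    lmin <- Inf
    while (j >= 1L && x[j] <= xi) {
      if (x[j] < lmin) lmin <- x[j]
      j <- j - 1L
    }
    j <- i + 1L
    rmin <- Inf
    while (j <= n && x[j] <= xi) {
      if (x[j] < rmin) rmin <- x[j]
      j <- j + 1L
    }
    if (!is.finite(lmin)) lmin <- xi
    if (!is.finite(rmin)) rmin <- xi
    xi - max(lmin, rmin)
  }, numeric(1))

  cand <- cand[prom >= min_prominence]
  if (length(cand) <= 1L) return(cand)

  # Greedy suppression: keep the tallest peaks, drop neighbours closer than
  # min_distance samples.
  ord <- cand[order(x[cand], decreasing = TRUE)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= min_distance)) kept <- c(kept, i)
  }
  sort(kept)
}

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Sample index range for a half-open time window [t0, t1); sample i (1-based)
# sits at t = (i - 1) / fs.
#' @keywords internal
#' @noRd
time_window_idx <- function(t0, t1, fs, n) {
  i0 <- max(1L, floor(t0 * fs + 1e-9) + 1L)
  i1 <- min(n, ceiling(t1 * fs - 1e-9))
  if (i1 < i0) stopf("time window [%g, %g) s contains no samples", t0, t1)
  i0:i1
}
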