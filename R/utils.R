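## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Scalar validation with the offending field named in the error, as the
## simulator contracts require.
assert_scalar <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE,
                          integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("field '%s' must be a single finite number", name)
  if (integer && x != round(x))
    stopf("field '%s' must be an integer", name)
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  if (lo_bad || hi_bad)
    stopf("field '%s' = %g is outside the allowed range %s%g, %g%s",
          name, x,
          if (strict_lower) "(" else "[", lower, upper,
          if (strict_upper) ")" else "]")
  invisible(x)
}

## Population standard deviation (divide by N): deterministic and defined
## for length-1 inputs, used for burst statistics.
pop_sd <- function(x) {
  n <- length(x)
  if (n == 0L) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

## Mode of a discrete vector; ties broken by the smallest value.
modal_value <- function(x) {
  if (length(x) == 0L) return(NA_real_)
  tab <- table(x)                       # names sorted ascending numerically
  vals <- as.numeric(names(tab))
  vals[order(-as.integer(tab), vals)][1L]
}

## Cumulative trapezoidal integration of a uniformly sampled signal.
cumtrapz <- function(x, fs) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  c(0, cumsum((x[-1L] + x[-n]) / 2)) / fs
}

## Zero-phase FFT filter with mirror padding; low/high are band edges in Hz
## (low = high-pass cutoff, high = low-pass cutoff). The frequency response
## uses raised-cosine transition bands (half-width `trans` relative to the
## cutoff) instead of a brick wall, so ringing stays local; padding is sized
## to the slowest cutoff so edge transients die out before the signal.
fft_filter <- function(x, fs, low = NULL, high = NULL, trans = 0.5) {
  n <- length(x)
  if (n < 8L) return(x)
  fc_min <- min(c(low, high, fs / 4))
  pad <- min(n - 1L, max(32L, as.integer(round(4 * fs / fc_min))))
  ## even reflection keeps the local mean continuous across the pads, which
  ## is what matters when removing low-frequency content
  xp <- c(rev(x[2L:(pad + 1L)]), x, rev(x[(n - pad):(n - 1L)]))
  np <- length(xp)
  f <- (seq_len(np) - 1L) * fs / np
  f <- pmin(f, fs - f)
  ## raised cosine rising 0 -> 1 over [a, b]
  ramp <- function(f, a, b) {
    y <- (f - a) / (b - a)
    y <- pmin(pmax(y, 0), 1)
    0.5 - 0.5 * cos(pi * y)
  }
  H <- rep(1, np)
  if (!is.null(low)) H <- H * ramp(f, low * (1 - trans), low * (1 + trans))
  if (!is.null(high)) H <- H * (1 - ramp(f, high * (1 - trans),
                                         high * (1 + trans)))
  X <- stats::fft(xp) * H
  out <- Re(stats::fft(X, inverse = TRUE)) / np
  out[pad + seq_len(n)]
}

## Dominant frequency of a (mean-removed) signal inside [band[1], band[2]] Hz,
## refined by parabolic interpolation of log-power around the peak bin.
dominant_frequency <- function(x, fs, band = c(0.5, 3)) {
  n <- length(x)
  if (n < 8L) return(NA_real_)
  x <- x - mean(x)
  if (all(x == 0)) return(0)
  p <- Mod(stats::fft(x))^2
  nf <- floor(n / 2)
  freqs <- (seq_len(nf)) * fs / n       # bins 1..nf, DC excluded
  p <- p[2L:(nf + 1L)]
  in_band <- freqs >= band[1L] & freqs <= band[2L]
  if (!any(in_band)) return(NA_real_)
  k <- which(in_band)[which.max(p[in_band])]
  f0 <- freqs[k]
  if (k > 1L && k < nf) {
    lp <- log(p[(k - 1L):(k + 1L)] + .Machine$double.xmin)
    den <- lp[1L] - 2 * lp[2L] + lp[3L]
    if (is.finite(den) && den < 0) {
      delta <- 0.5 * (lp[1L] - lp[3L]) / den
      f0 <- f0 + max(-0.5, min(0.5, delta)) * fs / n
    }
  }
  f0
}

## Fraction of non-DC spectral power inside the band.
band_power_ratio <- function(x, fs, band = c(0.5, 3)) {
  n <- length(x)
  if (n < 8L) return(0)
  x <- x - mean(x)
  tot <- sum(x^2)
  if (tot <= .Machine$double.eps) return(0)
  p <- Mod(stats::fft(x))^2
  nf <- floor(n / 2)
  freqs <- seq_len(nf) * fs / n
  pk <- p[2L:(nf + 1L)]
  sum(pk[freqs >= band[1L] & freqs <= band[2L]]) / sum(pk)
}

## Local maxima with a minimum peak-to-peak distance (greedy by height).
find_peaks <- function(x, min_dist = 1L, min_height = -Inf) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  cand <- which(x[2L:(n - 1L)] > x[1L:(n - 2L)] &
                x[2L:(n - 1L)] >= x[3L:n]) + 1L
  cand <- cand[x[cand] >= min_height]
  if (length(cand) <= 1L) return(cand)
  cand <- cand[order(-x[cand])]
  taken <- integer(0)
  for (i in cand) {
    if (!length(taken) || all(abs(taken - i) >= min_dist))
      taken <- c(taken, i)
  }
  sort(taken)
}

## Refine a peak index to sub-sample precision by parabolic interpolation.
refine_peak <- function(x, i) {
  n <- length(x)
  if (i <= 1L || i >= n) return(as.numeric(i))
  den <- x[i - 1L] - 2 * x[i] + x[i + 1L]
  if (!is.finite(den) || den >= 0) return(as.numeric(i))
  i + max(-0.5, min(0.5, 0.5 * (x[i - 1L] - x[i + 1L]) / den))
}
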