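## Independent oracles, deliberately written against the definitions rather
## than the package internals.

## Exhaustive all-pairs sample-entropy oracle: embed, compare every distinct
## template pair under the Chebyshev distance, count matches at length m and
## m + 1 over the n - m templates that admit a continuation.
sampen_oracle <- function(x, m = 2L, r = 0.2, relative = TRUE) {
  n <- length(x)
  tol <- if (relative) r * stats::sd(x) else r
  N <- n - m
  emb <- sapply(0:m, function(k) x[(1:N) + k])   # N x (m+1)
  B <- 0L; A <- 0L
  for (i in 1:(N - 1)) {
    js <- (i + 1):N
    dm <- abs(sweep(emb[js, 1:m, drop = FALSE], 2L, emb[i, 1:m], "-"))
    match_m <- apply(dm, 1L, max) <= tol
    B <- B + sum(match_m)
    A <- A + sum(match_m &
                   abs(emb[js, m + 1L] - emb[i, m + 1L]) <= tol)
  }
  if (B == 0L || A == 0L) return(Inf)
  -log(A / B)
}

## Random proper rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_dec)
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

## Construct a packet stream on the 16 ms grid from kept grid indices
## (1-based) and arbitrary in-range values.
stream_from_indices <- function(keep, n, sensor = "belt", value = 0.5) {
  acc <- matrix(value, length(keep), 3L)
  packet_stream(sensor, 16 * (keep - 1L), acc,
                expected_span_ms = 16 * (n - 1L))
}
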