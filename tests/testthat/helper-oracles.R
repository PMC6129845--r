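# Independent brute-force oracles used by both the unit and acceptance
# suites. These deliberately share no code with the package implementation.

# double-loop lagged normalized cross-correlation
xcorr_oracle <- function(x, y, lag_range = c(0L, 40L)) {
  best <- -Inf
  best_lag <- lag_range[1L]
  n <- length(x)
  for (L in lag_range[1L]:lag_range[2L]) {
    a <- y[(L + 1L):n]
    b <- x[1L:(n - L)]
    r <- if (sd(a) == 0 || sd(b) == 0) 0 else {
      ma <- mean(a); mb <- mean(b)
      sum((a - ma) * (b - mb)) / sqrt(sum((a - ma)^2) * sum((b - mb)^2))
    }
    if (r > best) {
      best <- r
      best_lag <- L
    }
  }
  list(maxcc = best, best_lag = best_lag)
}

# max empirical-CDF gap over the merged sample
ks_oracle <- function(a, b) {
  g <- sort(unique(c(a, b)))
  max(abs(vapply(g, function(x) mean(a <= x) - mean(b <= x), numeric(1))))
}
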