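# Shared numeric helpers. Filtering utilities operate on frames x pixels
# matrices so the whole movie is filtered in a handful of vectorized passes.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude, matching how
#' percentages are conventionally printed in composition tables (base R
#' `round()` rounds half to even).
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Apply an IIR filter along the rows of a matrix
#'
#' Direct-form transposed implementation using `stats::filter` for both the
#' moving-average and recursive parts, so every pixel column is filtered in
#' compiled code. Zero initial state; callers pad to absorb transients.
#'
#' @param b,a filter coefficients (leading denominator coefficient normalized to 1)
#' @param x numeric matrix, time along rows (a vector is treated as one column)
#' @return filtered matrix with the shape of `x`
#' @keywords internal
iir_filter_mat <- function(b, a, x) {
  if (is.null(dim(x))) return(.iir_vec(b, a, x))
  t(.iir_cols(b, a, t(x)))
}

# univariate path through the same compiled kernel
.iir_vec <- function(b, a, x, steady = FALSE) {
  drop(iir_cols_cpp(matrix(x, 1L), b / a[1L], a / a[1L], steady))
}

# IIR along the columns of a series x time matrix; the recursion runs in
# compiled code (src/filters.cpp). steady = TRUE starts from the steady
# state of a constant input at the first sample (suppresses edge transients)
.iir_cols <- function(b, a, xT, steady = FALSE) {
  iir_cols_cpp(xT, b / a[1L], a / a[1L], steady)
}

#' Zero-phase (forward-backward) filtering with reflective padding
#'
#' @param b,a filter coefficients
#' @param x matrix (time x series) or vector
#' @param n_pad samples of odd-symmetric reflective padding at each end
#' @return zero-phase filtered data, same shape as `x`
#' @keywords internal
filtfilt_mat <- function(b, a, x, n_pad = 0L) {
  if (is.null(dim(x))) {
    n <- length(x)
    n_pad <- min(as.integer(n_pad), n - 1L)
    if (n_pad > 0L) {
      # odd reflection: 2*x[1] - x[k+1], preserves value and slope at the edge
      x <- c(2 * x[1L] - x[(n_pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - n_pad)])
    }
    y <- .iir_vec(b, a, x, steady = TRUE)
    y <- rev(.iir_vec(b, a, rev(y), steady = TRUE))
    if (n_pad > 0L) y <- y[(n_pad + 1L):(n_pad + n)]
    return(y)
  }
  n <- nrow(x)
  n_pad <- min(as.integer(n_pad), n - 1L)
  xT <- t(x)
  if (n_pad > 0L) {
    top <- 2 * xT[, 1L] - xT[, (n_pad + 1L):2L, drop = FALSE]
    bot <- 2 * xT[, n] - xT[, (n - 1L):(n - n_pad), drop = FALSE]
    xT <- cbind(top, xT, bot)
  }
  yT <- .iir_cols(b, a, xT, steady = TRUE)
  yT <- .iir_cols(b, a, yT[, ncol(yT):1L, drop = FALSE], steady = TRUE)
  yT <- yT[, ncol(yT):1L, drop = FALSE]
  if (n_pad > 0L) yT <- yT[, (n_pad + 1L):(n_pad + n), drop = FALSE]
  t(yT)
}

#' Indices of strict local maxima of a series
#' @keywords internal
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
}

#' Topographic prominence of peaks
#'
#' For each peak, walk left and right until a strictly higher sample (or the
#' series end) is reached; the prominence is the peak height above the higher
#' of the two minima found on the way.
#'
#' @param x series
#' @param peaks indices of local maxima
#' @return numeric vector of prominences
#' @keywords internal
peak_prominence <- function(x, peaks) {
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p
    left_min <- h
    while (l > 1L && x[l] <= h) {
      l <- l - 1L
      if (x[l] < left_min) left_min <- x[l]
    }
    r <- p
    right_min <- h
    n <- length(x)
    while (r < n && x[r] <= h) {
      r <- r + 1L
      if (x[r] < right_min) right_min <- x[r]
    }
    h - max(left_min, right_min)
  }, numeric(1))
}

#' Moving-median detrend
#'
#' Subtracts a running median (default window 10 s) from a series; used to
#' remove slow drift from the integrated LFP while leaving bursts intact.
#'
#' @param x series
#' @param rate_hz samples per second
#' @param window_s window length in seconds
#' @return detrended series
#' @export
detrend_moving_median <- function(x, rate_hz, window_s = 10) {
  k <- as.integer(round(window_s * rate_hz))
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(3L, min(k, if (length(x) %% 2L == 0L) length(x) - 1L else length(x)))
  x - stats::runmed(x, k, endrule = "median")
}

#' Cosine similarity of two vectors
#' @keywords internal
cosine_sim <- function(a, b) {
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Match detected centers to planted centers by nearest Chebyshev distance
#'
#' Greedy one-to-one assignment, closest pairs first.
#'
#' @param detected,truth two-column matrices (row, col)
#' @param max_dist maximum Chebyshev distance for a match (pixels)
#' @return data.frame with columns detected, truth, dist (one row per match)
#' @export
match_centers <- function(detected, truth, max_dist = 2) {
  detected <- as.matrix(detected)
  truth <- as.matrix(truth)
  if (nrow(detected) == 0L || nrow(truth) == 0L) {
    return(data.frame(detected = integer(0), truth = integer(0), dist = numeric(0)))
  }
  d <- pmax(
    abs(outer(detected[, 1L], truth[, 1L], "-")),
    abs(outer(detected[, 2L], truth[, 2L], "-"))
  )
  out <- data.frame(detected = integer(0), truth = integer(0), dist = numeric(0))
  repeat {
    m <- which.min(d)
    if (length(m) == 0L || d[m] > max_dist) break
    i <- (m - 1L) %% nrow(d) + 1L
    j <- (m - 1L) %/% nrow(d) + 1L
    out <- rbind(out, data.frame(detected = i, truth = j, dist = d[m]))
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  out
}
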