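# LFP conditioning (rectify-integrate, anti-aliased resample to frame rate)
# and spatio-temporal filtering of the calcium movie. All temporal filters
# used downstream of event timing are zero-phase so peak frames are preserved.

#' Rectify and integrate an LFP trace
#'
#' Full-wave rectification followed by a single-pole exponential low-pass
#' (leaky integrator) with time constant `tau_s`, emulating an analog
#' rectify-and-integrate amplifier (typical time constant 100-200 ms).
#'
#' @param lfp a [lfp_trace()] object
#' @param tau_s integrator time constant in seconds (default 0.15, the
#'   midpoint of the conventional 100-200 ms range)
#' @return numeric vector, the integrated trace at the raw rate
#' @export
integrate_lfp <- function(lfp, tau_s = 0.15) {
  stopifnot(inherits(lfp, "pbs_lfp"))
  if (tau_s <= 0) stop("tau_s must be positive")
  if (length(lfp$raw) < 10 * tau_s * lfp$raw_rate_hz) {
    stop("raw trace shorter than 10 integrator time constants")
  }
  a <- exp(-1 / (lfp$raw_rate_hz * tau_s))
  y <- stats::filter((1 - a) * abs(lfp$raw), a, method = "recursive")
  as.numeric(y)
}

# zero-phase Chebyshev-I order-8 low-pass with unit DC gain
.cheby_lp <- function(x, wn, ripple_db = 0.05) {
  flt <- signal::cheby1(8, ripple_db, wn, type = "low")
  b <- flt$b / sum(flt$b) * sum(flt$a)   # normalize DC gain to exactly 1
  # order-8 Chebyshev poles sit close to the unit circle at low cutoffs;
  # generous reflective padding lets the zero-state transient die out
  filtfilt_mat(b, flt$a, x, n_pad = min(length(x) - 1L, ceiling(40 / wn)))
}

#' Resample the integrated LFP to imaging frame times
#'
#' Anti-aliasing by a zero-phase Chebyshev Type I IIR low-pass of order 8
#' with cutoff 0.8 x (frame_rate / 2), then linear interpolation at the frame
#' trigger times. Because the raw-to-frame rate ratio is very large (~1000x),
#' the filter is applied as a cascade of decimation stages with per-stage
#' ratio <= 10 (the standard recommendation for IIR decimators, whose poles
#' collapse onto the unit circle at extreme normalized cutoffs); every stage
#' is the same order-8 Chebyshev-I design with unit DC gain.
#'
#' Also computes `sd_detrended`, the SD of the frame-rate signal after
#' subtracting a 10 s moving median, which burst detection uses as its
#' amplitude yardstick.
#'
#' @param integrated full-rate integrated trace from [integrate_lfp()]
#' @param lfp the originating [lfp_trace()] (for rate and trigger times)
#' @param movie the paired [movie()] (for frame times and rate)
#' @param tau_s integrator time constant recorded alongside (metadata)
#' @return object of class `pbs_ilfp`: values, frame_times, tau_s, sd_detrended
#' @export
resample_to_frames <- function(integrated, lfp, movie, tau_s = 0.15) {
  stopifnot(inherits(lfp, "pbs_lfp"), inherits(movie, "pbs_movie"))
  frame_t <- lfp$frame_trigger_times %||% movie$frame_times
  span <- (length(integrated) - 1L) / lfp$raw_rate_hz
  if (min(frame_t) < 0 || max(frame_t) > span) {
    stop("frame times fall outside the raw trace")
  }
  fs_target <- movie$sampling_rate_hz
  cutoff_hz <- 0.8 * (fs_target / 2)

  x <- integrated
  rate <- lfp$raw_rate_hz
  # decimate until a single stage reaches the target cutoff comfortably
  while (rate / fs_target > 20) {
    r <- min(10L, floor(rate / (fs_target * 2)))
    x <- .cheby_lp(x, 0.8 / r)           # anti-alias for this stage
    keep <- seq(1L, length(x), by = r)
    x <- x[keep]
    rate <- rate / r
  }
  x <- .cheby_lp(x, cutoff_hz / (rate / 2))
  t_x <- (seq_along(x) - 1L) / rate
  vals <- approx(t_x, x, xout = frame_t, rule = 2)$y
  vals[vals < 0] <- 0
  det <- detrend_moving_median(vals, fs_target)
  structure(
    list(values = vals, frame_times = frame_t, tau_s = tau_s,
         sd_detrended = sd(det)),
    class = "pbs_ilfp"
  )
}

#' Condition an LFP trace end to end
#'
#' Convenience wrapper: [integrate_lfp()] then [resample_to_frames()].
#'
#' @inheritParams resample_to_frames
#' @param tau_s integrator time constant (s)
#' @return a `pbs_ilfp` object
#' @export
condition_lfp <- function(lfp, movie, tau_s = 0.15) {
  resample_to_frames(integrate_lfp(lfp, tau_s), lfp, movie, tau_s)
}

#' 3 x 3 unweighted spatial mean of each frame
#'
#' At borders the kernel shrinks to the available neighbors, so edge pixels
#' average 4 or 6 values rather than padded zeros.
#'
#' @param data frames x height x width array (or a single h x w matrix)
#' @return smoothed array of the same shape
#' @export
spatial_smooth_3x3 <- function(data) {
  single <- length(dim(data)) == 2L
  if (single) data <- array(data, c(1L, dim(data)))
  d <- dim(data)
  acc <- array(0, d)
  cnt <- matrix(0, d[2L], d[3L])
  for (dr in -1:1) for (dc in -1:1) {
    r_src <- max(1, 1 + dr):min(d[2L], d[2L] + dr)
    c_src <- max(1, 1 + dc):min(d[3L], d[3L] + dc)
    r_dst <- r_src - dr
    c_dst <- c_src - dc
    acc[, r_dst, c_dst] <- acc[, r_dst, c_dst, drop = FALSE] +
      data[, r_src, c_src, drop = FALSE]
    cnt[r_dst, c_dst] <- cnt[r_dst, c_dst] + 1
  }
  for (f in seq_len(d[1L])) acc[f, , ] <- acc[f, , ] / cnt
  if (single) acc[1L, , ] else acc
}

# complex frequency response of an IIR filter on angular frequencies w
.freq_resp <- function(flt, w) {
  num <- exp(-1i * outer(w, seq_along(flt$b) - 1)) %*% flt$b
  den <- exp(-1i * outer(w, seq_along(flt$a) - 1)) %*% flt$a
  drop(num / den)
}

# smallest 2-3-5-smooth padded length n + 2k with k >= k0
.smooth_padded_length <- function(n, k0) {
  k <- k0
  repeat {
    N <- n + 2L * k
    if (stats::nextn(N, c(2L, 3L, 5L)) == N) return(k)
    k <- k + 1L
  }
}

#' Band-pass and spatially smooth a calcium movie
#'
#' Per-pixel zero-phase Butterworth band-pass (an order-`order` high-pass at
#' `band_hz[1]` cascaded with an order-`order` low-pass at `band_hz[2]`)
#' followed by a 3 x 3 unweighted spatial mean per frame.
#'
#' The zero-phase temporal filter applies the squared magnitude response
#' |H(w)|^2 of the Butterworth cascade in the frequency domain — the exact
#' frequency response that forward-backward filtering realizes — after
#' odd-symmetric reflective padding of at least one low-cut period per end.
#' This keeps the filter strictly zero-phase (symmetric pulses keep their
#' peak frame) and exactly time-reversal symmetric even though the low band
#' edge gives the recursion a memory comparable to the recording length.
#' The per-pixel temporal mean is subtracted so the output is exactly
#' DC-free.
#'
#' @param m a [movie()] object
#' @param band_hz c(low, high) pass band in Hz (default 0.025-1.5)
#' @param order Butterworth order per section (default 3)
#' @return object of class `pbs_fmovie` with fields data, band_hz,
#'   filter_order, frame_times, sampling_rate_hz
#' @export
filter_movie <- function(m, band_hz = c(0.025, 1.5), order = 3) {
  stopifnot(inherits(m, "pbs_movie"))
  fs <- m$sampling_rate_hz
  nyq <- fs / 2
  if (band_hz[1L] <= 0 || band_hz[2L] >= nyq || band_hz[1L] >= band_hz[2L]) {
    stop("band must satisfy 0 < low < high < Nyquist")
  }
  dur <- diff(range(m$frame_times))
  if (dur <= 2 / band_hz[1L]) {
    stop("movie shorter than two periods of the low cut frequency")
  }
  d <- dim(m$data)
  n <- d[1L]
  p <- d[2L] * d[3L]
  x <- matrix(m$data, n, p)
  x <- sweep(x, 2L, colMeans(x))
  hp <- signal::butter(order, band_hz[1L] / nyq, type = "high")
  lp <- signal::butter(order, band_hz[2L] / nyq, type = "low")
  k <- .smooth_padded_length(n, min(n - 1L, ceiling(fs / band_hz[1L])))
  if (k > n - 1L) stop("movie too short to pad one low-cut period")
  N <- n + 2L * k
  w <- 2 * pi * (0:(N - 1L)) / N
  h2 <- Mod(.freq_resp(hp, w))^2 * Mod(.freq_resp(lp, w))^2
  out <- matrix(0, n, p)
  blk <- max(1L, floor(4e6 / N))   # cap working complex storage per block
  for (j0 in seq(1L, p, by = blk)) {
    jj <- j0:min(p, j0 + blk - 1L)
    xb <- x[, jj, drop = FALSE]
    top <- 2 * matrix(xb[1L, ], k, length(jj), byrow = TRUE) -
      xb[(k + 1L):2L, , drop = FALSE]
    bot <- 2 * matrix(xb[n, ], k, length(jj), byrow = TRUE) -
      xb[(n - 1L):(n - k), , drop = FALSE]
    xp <- rbind(top, xb, bot)
    yf <- stats::mvfft(xp) * h2
    yb <- Re(stats::mvfft(yf, inverse = TRUE)) / N
    out[, jj] <- yb[(k + 1L):(k + n), , drop = FALSE]
  }
  out <- sweep(out, 2L, colMeans(out))    # enforce exact DC removal
  out <- spatial_smooth_3x3(array(out, d))
  structure(
    list(data = out, band_hz = band_hz, filter_order = order,
         frame_times = m$frame_times, sampling_rate_hz = fs),
    class = "pbs_fmovie"
  )
}
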