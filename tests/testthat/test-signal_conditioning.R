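# Filtering and integration: closed-form responses, zero-phase behavior,
# linearity, and the frame-rate resampler's passband/stopband.

test_that("rectify-integrate matches the closed-form step response", {
  rate <- 2000
  tau <- 0.15
  A <- 3.7
  lfp <- lfp_trace(c(rep(0, 2000), rep(A, 6000)), rate)
  y <- integrate_lfp(lfp, tau_s = tau)
  # value one time constant after the step: A * (1 - e^-1)
  at_tau <- y[2000 + round(tau * rate)]
  expect_equal(at_tau, A * (1 - exp(-1)), tolerance = 0.01)
  expect_true(all(y >= 0))
  # zero input -> zero output
  expect_equal(integrate_lfp(lfp_trace(rep(0, 4000), rate), tau),
               rep(0, 4000))
})

test_that("square-wave rectified mean is recovered at steady state", {
  rate <- 10000
  A <- 2.5
  x <- A * rep(c(1, -1), each = 5, times = 4000)   # 1 kHz square wave
  y <- integrate_lfp(lfp_trace(x, rate), tau_s = 0.15)
  expect_equal(mean(tail(y, 5000)), A, tolerance = 0.02 * A)
})

test_that("integrator rejects nonpositive tau and too-short traces", {
  lfp <- lfp_trace(rnorm(5000), 2000)
  expect_error(integrate_lfp(lfp, tau_s = 0), "positive")
  expect_error(integrate_lfp(lfp_trace(rnorm(100), 2000), 0.15), "shorter")
})

test_that("resampling to frames preserves DC within 0.1%", {
  rate <- 2000
  n <- 80000
  m <- toy_movie(n = 390L, h = 4L, w = 4L, rate = 10)
  lfp <- lfp_trace(rnorm(n), rate, frame_trigger_times = m$frame_times)
  const <- rep(4.2, n)
  il <- resample_to_frames(const, lfp, m)
  expect_true(all(abs(il$values - 4.2) < 0.001 * 4.2))
  expect_equal(length(il$values), length(m$frame_times))
})

test_that("a 0.2 Hz component survives resampling at its frequency", {
  rate <- 2000
  dur <- 60
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- 1.5 + sin(2 * pi * 0.2 * t)
  nf <- 595L
  m <- toy_movie(n = nf, h = 4L, w = 4L, rate = 10)
  lfp <- lfp_trace(rnorm(length(t)), rate, frame_trigger_times = m$frame_times)
  il <- resample_to_frames(x, lfp, m)
  v <- il$values - mean(il$values)
  sp <- Mod(fft(v))[2:floor(nf / 2)]
  f_grid <- (1:(floor(nf / 2) - 1)) / (nf / 10)
  expect_equal(f_grid[which.max(sp)], 0.2, tolerance = 0.05)
})

test_that("a 40 Hz component is attenuated by at least 40 dB", {
  rate <- 2000
  dur <- 60
  t <- seq(0, dur - 1 / rate, by = 1 / rate)
  x <- 2 + sin(2 * pi * 40 * t)
  nf <- 595L
  m <- toy_movie(n = nf, h = 4L, w = 4L, rate = 10)
  lfp <- lfp_trace(rnorm(length(t)), rate, frame_trigger_times = m$frame_times)
  il <- resample_to_frames(x, lfp, m)
  # alias of 40 Hz onto the 10 Hz frame grid would appear at 0 Hz offset;
  # measure total AC power instead, which the input sine dominates
  ac_out <- var(il$values)
  ac_in <- var(x)
  expect_lt(ac_out / ac_in, 10^(-40 / 10))
})

test_that("movie band-pass rejects DC and keeps symmetric peaks in place", {
  n <- 900L          # 90 s at 10 Hz: longer than 2 periods of the low cut
  h <- 6L
  # constant movie -> ~0 everywhere
  m_const <- movie(array(5, c(n, h, h)), (0:(n - 1)) / 10, 1, 10)
  fm <- filter_movie(m_const)
  expect_lt(max(abs(fm$data)), 1e-9 * 5)
  # per-pixel temporal mean exactly removed on structured input
  set.seed(11)
  dat <- array(abs(rnorm(n * h * h, 10, 1)), c(n, h, h))
  fm2 <- filter_movie(movie(dat, (0:(n - 1)) / 10, 1, 10))
  mu <- apply(fm2$data, c(2, 3), mean)
  expect_lt(max(abs(mu)), 1e-6 * sd(fm2$data))
  # a symmetric Gaussian bump keeps its peak frame (zero phase)
  dat3 <- array(1, c(n, h, h))
  bump <- exp(-((1:n) - 450)^2 / (2 * 9^2))
  dat3[, 3, 3] <- 1 + 5 * bump
  fm3 <- filter_movie(movie(dat3, (0:(n - 1)) / 10, 1, 10))
  expect_equal(which.max(fm3$data[, 3, 3]), 450L, tolerance = 1)
})

test_that("0.3 Hz sinusoidal pixel shows no phase shift", {
  n <- 1200L
  t <- (0:(n - 1)) / 10
  dat <- array(1, c(n, 6L, 6L))
  dat[, 4, 4] <- 2 + sin(2 * pi * 0.3 * t)
  fm <- filter_movie(movie(dat, t, 1, 10))
  y <- fm$data[, 4, 4]
  x <- sin(2 * pi * 0.3 * t)
  lags <- -5:5
  cc <- vapply(lags, function(L) {
    if (L >= 0) cor(y[(L + 1):n], x[1:(n - L)]) else cor(y[1:(n + L)], x[(1 - L):n])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0L)
})

test_that("3x3 spatial smoothing averages a point impulse and shrinks at borders", {
  img <- matrix(0, 9, 9)
  img[5, 5] <- 9
  sm <- spatial_smooth_3x3(img)
  expect_equal(sm[4:6, 4:6], matrix(1, 3, 3))
  expect_equal(sm[7, 7], 0)
  # corner pixel averages its 4 available neighbors
  img2 <- matrix(0, 9, 9)
  img2[1, 1] <- 4
  expect_equal(spatial_smooth_3x3(img2)[1, 1], 1)
})

test_that("temporal filtering is zero-phase under time reversal and linear", {
  n <- 900L
  set.seed(3)
  dat <- array(rnorm(n * 16), c(n, 4L, 4L))
  m1 <- movie(dat + 10, (0:(n - 1)) / 10, 1, 10)
  m_rev <- movie(dat[n:1, , ] + 10, (0:(n - 1)) / 10, 1, 10)
  f1 <- filter_movie(m1)$data
  f2 <- filter_movie(m_rev)$data[n:1, , ]
  expect_equal(f1, f2, tolerance = 1e-6)
  # linearity: f(a x + b y) = a f(x) + b f(y)
  dat_b <- array(rnorm(n * 16), c(n, 4L, 4L))
  lin_in <- 2 * dat + 3 * dat_b
  f_lin <- filter_movie(movie(lin_in - min(lin_in), (0:(n - 1)) / 10, 1, 10))$data
  fa <- filter_movie(movie(dat - min(dat), (0:(n - 1)) / 10, 1, 10))$data
  fb <- filter_movie(movie(dat_b - min(dat_b), (0:(n - 1)) / 10, 1, 10))$data
  expect_equal(f_lin, 2 * fa + 3 * fb, tolerance = 1e-8)
})

test_that("matrix filtfilt agrees with per-column filtering", {
  set.seed(5)
  x <- matrix(rnorm(600), 200, 3)
  flt <- signal::butter(3, 0.3, "low")
  y_mat <- filtfilt_mat(flt$b, flt$a, x, n_pad = 50)
  for (j in 1:3) {
    expect_equal(y_mat[, j], filtfilt_mat(flt$b, flt$a, x[, j], n_pad = 50),
                 tolerance = 1e-12)
  }
})
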