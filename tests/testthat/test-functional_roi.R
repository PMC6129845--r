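# Lagged cross-correlation: brute-force oracle equivalence, correlation-map
# properties, and ROI detection on constructed fields.

test_that("normalized_xcorr_max equals the brute-force oracle on random series", {
  set.seed(42)
  for (i in 1:50) {
    n <- sample(60:200, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    got <- normalized_xcorr_max(x, y, c(0L, 20L))
    want <- xcorr_oracle(x, y, c(0L, 20L))
    expect_equal(got$maxcc, want$maxcc, tolerance = 1e-12)
    expect_identical(got$best_lag, want$best_lag)
  }
})

test_that("self-correlation is (1, 0) and a known shift is recovered", {
  set.seed(1)
  x <- rep(exp(-((1:50) - 25)^2 / 18), 8) + rnorm(400, 0, 0.01)
  expect_equal(normalized_xcorr_max(x, x), list(maxcc = 1, best_lag = 0L),
               tolerance = 1e-12)
  y <- c(rep(0, 7), x[1:(length(x) - 7)])
  got <- normalized_xcorr_max(x, y)
  expect_identical(got$best_lag, 7L)
  expect_gt(got$maxcc, 0.99)
})

test_that("independent noise stays below the 0.2 detection threshold", {
  set.seed(99)
  n_below <- 0
  trials <- 500
  for (i in seq_len(trials)) {
    got <- normalized_xcorr_max(rnorm(1000), rnorm(1000))
    if (got$maxcc < 0.2) n_below <- n_below + 1
  }
  expect_gte(n_below / trials, 0.95)
})

test_that("correlation image matches per-pixel computation and is scale invariant", {
  set.seed(8)
  n <- 200L
  dat <- array(rnorm(n * 25), c(n, 5L, 5L))
  fm <- toy_fmovie(dat)
  il <- toy_ilfp(abs(rnorm(n)))
  cm <- correlation_image(fm, il, c(0L, 10L))
  for (px in list(c(1, 1), c(3, 4), c(5, 5))) {
    want <- xcorr_oracle(il$values, dat[, px[1], px[2]], c(0L, 10L))
    expect_equal(cm$maxcc[px[1], px[2]], want$maxcc, tolerance = 1e-9)
    expect_equal(cm$best_lag[px[1], px[2]], want$best_lag)
  }
  cm5 <- correlation_image(toy_fmovie(dat * 5), il, c(0L, 10L))
  expect_equal(cm5$maxcc, cm$maxcc, tolerance = 1e-12)
  expect_true(all(abs(cm$maxcc) <= 1))
  expect_true(all(cm$best_lag >= 0 & cm$best_lag <= 10))
})

test_that("an all-zero movie yields a zero correlation map", {
  fm <- toy_fmovie(array(0, c(100L, 4L, 4L)))
  il <- toy_ilfp(abs(rnorm(100)))
  cm <- correlation_image(fm, il, c(0L, 5L))
  expect_true(all(cm$maxcc == 0))
})

test_that("ROI detection on a planted LFP-locked disk finds it, background stays low", {
  set.seed(21)
  n <- 400L
  h <- 24L
  sig <- rep(0, n)
  sig[seq(10, n, by = 40)] <- 1
  sig <- as.numeric(stats::filter(sig, exp(-(0:20) / 6), method = "convolution",
                                  sides = 1))
  sig[is.na(sig)] <- 0
  dat <- array(rnorm(n * h * h, 0, 0.3), c(n, h, h))
  for (dr in -2:2) for (dc in -2:2) {
    if (dr^2 + dc^2 <= 4) dat[, 12 + dr, 12 + dc] <- dat[, 12 + dr, 12 + dc] + 3 * sig
  }
  fm <- toy_fmovie(dat)
  il <- toy_ilfp(sig + rnorm(n, 0, 0.02))
  cm <- correlation_image(fm, il, c(0L, 10L))
  expect_gt(cm$maxcc[12, 12], 0.5)
  expect_lt(median(cm$maxcc[abs(row(cm$maxcc) - 12) > 5 | abs(col(cm$maxcc) - 12) > 5]), 0.2)
  rois <- detect_rois(cm, 0.2, fm)
  expect_equal(nrow(rois$table), 1L)
  expect_lte(max(abs(rois$table$row - 11), abs(rois$table$col - 11)), 2)
})

test_that("empty map gives an empty ROI list; threshold raising is monotone", {
  fm <- toy_fmovie(array(0, c(60L, 10L, 10L)))
  cm <- structure(list(maxcc = matrix(0, 10, 10), best_lag = matrix(0L, 10, 10),
                       lag_range = c(0L, 10L)), class = "pbs_cmap")
  expect_equal(nrow(detect_rois(cm, 0.2, fm)$table), 0L)
  run <- small_run()
  cm2 <- run$res$cmap
  fm2 <- run$res$fmovie
  counts <- vapply(c(0.1, 0.2, 0.35, 0.5, 0.7),
                   function(th) nrow(detect_rois(cm2, th, fm2)$table), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("two cells 4 px apart yield a single accepted ROI", {
  set.seed(13)
  n <- 300L
  h <- 20L
  sig <- sin(2 * pi * (1:n) / 40)^8
  dat <- array(rnorm(n * h * h, 0, 0.2), c(n, h, h))
  for (ctr in list(c(10, 8), c(10, 12))) {
    for (dr in -1:1) for (dc in -1:1) {
      dat[, ctr[1] + dr, ctr[2] + dc] <- dat[, ctr[1] + dr, ctr[2] + dc] + 2 * sig
    }
  }
  fm <- toy_fmovie(dat)
  il <- toy_ilfp(sig)
  cm <- correlation_image(fm, il, c(0L, 5L))
  rois <- detect_rois(cm, 0.2, fm)
  expect_equal(nrow(rois$table), 1L)
})

test_that("planted-cell ROI traces correlate with the LFP above threshold", {
  run <- small_run()
  tr <- run$res$rois$traces
  il <- run$res$ilfp
  for (i in seq_len(ncol(tr))) {
    got <- normalized_xcorr_max(il$values, tr[, i])
    expect_gte(got$maxcc, 0.2)
  }
})
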