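# Activation detection, the 50% cycle-inclusion rule, percent ranks, and
# cumulative timing curves.

make_burst_row <- function(frame, t) {
  data.frame(id = 1L, peak_frame = frame, peak_time_s = t, amplitude = 1,
             is_sigh = FALSE, accepted = TRUE)
}

test_that("a planted transient 3 frames after the burst peak times at +0.3 s", {
  n <- 200L
  trace <- rep(0, n)
  trace[100 + 3] <- 1
  trace[100 + 2] <- 0.5
  trace[100 + 4] <- 0.5
  a <- detect_activation(trace, 100L, 10, noise_sigma = 0.01)
  expect_equal(a$timing_s, 0.3)
  expect_equal(a$peak_frame, 103L)
})

test_that("flat or subthreshold traces yield no activation", {
  expect_null(detect_activation(rep(0, 200), 100L, 10, noise_sigma = 0.01))
  trace <- rep(0, 200)
  trace[99:101] <- c(0.5, 1, 0.5) * 0.02
  expect_null(detect_activation(trace, 100L, 10, noise_k = 3, noise_sigma = 0.01))
})

test_that("edge-truncated windows warn but still work", {
  trace <- rep(0, 60)
  trace[9:11] <- c(0.5, 1, 0.5)
  expect_warning(a <- detect_activation(trace, 10L, 10, noise_sigma = 0.01),
                 "truncated")
  expect_equal(a$timing_s, 0)
})

test_that("timing sign convention: transients before the LFP peak are negative", {
  n <- 400L
  bursts <- data.frame(id = 1:3, peak_frame = c(100L, 200L, 300L),
                       peak_time_s = c(10, 20, 30), amplitude = 1,
                       is_sigh = FALSE, accepted = TRUE)
  traces <- matrix(0, n, 2)
  for (pf in bursts$peak_frame) {
    traces[pf - 5 + (-1:1), 1] <- c(0.5, 1, 0.5)
    traces[pf - 2 + (-1:1), 2] <- c(0.5, 1, 0.5)
  }
  acts <- detect_activations(traces, bursts, 10)
  expect_true(all(acts$timing_s < 0))
  expect_equal(sort(unique(acts$timing_s)), c(-0.5, -0.2))
})

test_that("recovered timings track ground truth closely on synthetic data", {
  run <- small_run()
  tr <- eval_timing_recovery(run$res$activations, run$res$cells,
                             run$res$bursts, run$rec$truth, 10)
  expect_gte(tr$r, 0.9)
  expect_lte(tr$mae_frames, 1)
})

test_that("the 50% inclusion rule and percent ranks follow their definitions", {
  bursts <- make_burst_row(100L, 10)
  acts <- data.frame(cell_id = 1:4, burst_id = 1L, peak_frame = 98:101,
                     timing_s = c(-0.2, -0.1, 0, 0.1), peak_amplitude = 1)
  # 10 cells, 4 activated -> excluded
  out <- build_cycles(acts, 10L, bursts)
  expect_false(out$cycles$included)
  # 4 of 4 -> included with ranks 25/50/75/100
  out2 <- build_cycles(acts, 4L, bursts)
  expect_true(out2$cycles$included)
  expect_equal(out2$ranked$percent_rank, c(25, 50, 75, 100))
  expect_equal(out2$ranked$cell_id, 1:4)
  # 5 of 10 is "at least 50%" -> included
  acts5 <- rbind(acts, data.frame(cell_id = 5L, burst_id = 1L, peak_frame = 102L,
                                  timing_s = 0.2, peak_amplitude = 1))
  expect_true(build_cycles(acts5, 10L, bursts)$cycles$included)
})

test_that("ties in timing break by cell id and ranks stay within (0, 100]", {
  bursts <- make_burst_row(50L, 5)
  acts <- data.frame(cell_id = c(3L, 1L, 2L), burst_id = 1L,
                     peak_frame = c(50L, 50L, 52L),
                     timing_s = c(0, 0, 0.2), peak_amplitude = 1)
  out <- build_cycles(acts, 3L, bursts)
  expect_equal(out$ranked$cell_id, c(1L, 3L, 2L))
  expect_equal(max(out$ranked$percent_rank), 100)
  expect_true(all(out$ranked$percent_rank > 0))
  expect_equal(attr(out$ranked, "n_ties"), 1L)
})

test_that("raising the inclusion fraction never adds included cycles", {
  run <- small_run()
  res <- run$res
  n_insp <- sum(res$cells$cell_type %in% CELL_TYPES)
  counts <- vapply(c(0.25, 0.5, 0.75, 0.95), function(f) {
    sum(build_cycles(res$activations, n_insp, res$bursts,
                     inclusion = f)$cycles$included)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("most cycles are included under the default activation probabilities", {
  run <- small_run()
  expect_gte(mean(run$res$cycles$included), 0.8)
})

test_that("cumulative timing curves are proper CDFs", {
  acts <- data.frame(timing_s = c(-0.5, 0, 0.5), cell_type = "R-Ex")
  grid <- seq(-1, 1, by = 0.25)
  cc <- suppressWarnings(timing_cumulative(acts, grid))
  expect_equal(unname(cc[grid == 0, "R-Ex"]), 2 / 3)
  expect_equal(unname(cc[length(grid), "R-Ex"]), 1)
  expect_true(all(diff(cc[, "R-Ex"]) >= 0))
  # degenerate all-zero timings: step at 0
  acts0 <- data.frame(timing_s = rep(0, 5), cell_type = "Irr-Ex")
  cc0 <- suppressWarnings(timing_cumulative(acts0, grid))
  expect_equal(unname(cc0[, "Irr-Ex"]), as.numeric(grid >= 0))
  # synthetic run: every populated type curve ends at 1 and is nondecreasing
  run <- small_run()
  cs <- suppressWarnings(timing_cumulative(run$res$ranked))
  expect_true(all(abs(cs[nrow(cs), ] - 1) < 1e-12))
  expect_true(all(apply(cs, 2, function(v) all(diff(v) >= 0))))
})
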