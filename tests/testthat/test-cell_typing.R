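# Regularity cutoff, type mapping, and the composition table (checked against
# the published pooled composition of 84 inspiratory neurons).

test_that("regularity is strict at the cutoff", {
  expect_equal(classify_regularity(0.70, 0.55), "Regular")
  expect_equal(classify_regularity(0.55, 0.55), "Irregular")
  expect_equal(classify_regularity(c(0.3, 0.551), 0.55),
               c("Irregular", "Regular"))
  expect_error(classify_regularity(0.5, 1.2), "0,1")
})

test_that("Otsu cutoff separates a bimodal sample and matches brute force", {
  x <- c(rnorm(10, 0.30, 0.01), rnorm(10, 0.80, 0.01))
  withr::with_seed(2, x <- sample(x))
  cut <- suppressWarnings(suggest_cutoff(x))
  expect_gt(cut, max(x[x < 0.5]))
  expect_lt(cut, min(x[x > 0.5]))
  # brute-force inter-class variance maximization over a dense grid
  grid <- seq(min(x) + 1e-4, max(x) - 1e-4, length.out = 2000)
  bcv <- vapply(grid, function(thr) {
    lo <- x[x <= thr]; hi <- x[x > thr]
    length(lo) / length(x) * length(hi) / length(x) * (mean(lo) - mean(hi))^2
  }, numeric(1))
  best_grid <- grid[which.max(bcv)]
  # same partition: the suggested cutoff lies in the same inter-mode gap
  expect_equal(sum(x <= cut), sum(x <= best_grid))
})

test_that("unimodal samples clamp with a warning and tiny samples error", {
  set.seed(30)
  x <- rnorm(20, 0.25, 0.005)   # unimodal well below the plausible range
  expect_warning(cut <- suggest_cutoff(x), "clamped")
  expect_gte(cut, 0.40)
  expect_lte(cut, 0.70)
  expect_error(suggest_cutoff(c(0.2, 0.5, 0.9)), "fewer than 6")
})

test_that("marker/regularity combinations map to the five types", {
  expect_equal(assign_cell_type(FALSE, FALSE, "Regular"), "R-Ex")
  expect_equal(assign_cell_type(TRUE, FALSE, "Regular"), "R-Gly")
  expect_equal(assign_cell_type(FALSE, FALSE, "Irregular"), "Irr-Ex")
  expect_equal(assign_cell_type(TRUE, FALSE, "Irregular"), "Irr-Gly")
  expect_equal(assign_cell_type(TRUE, TRUE, "Irregular"), "Irr-Cotrans")
  expect_warning(ty <- assign_cell_type(TRUE, TRUE, "Regular"), "Unclassified")
  expect_equal(ty, "Unclassified")
  expect_warning(expect_equal(assign_cell_type(FALSE, TRUE, "Irregular"),
                              "Unclassified"))
  # total and deterministic over all combinations
  combos <- expand.grid(g = c(TRUE, FALSE), a = c(TRUE, FALSE),
                        r = c("Regular", "Irregular"))
  tys <- suppressWarnings(assign_cell_type(combos$g, combos$a, combos$r))
  expect_equal(length(tys), 8L)
  expect_true(all(tys %in% c(CELL_TYPES, "Unclassified")))
})

test_that("classification recovers ground-truth regularity on synthetic data", {
  # the compact fixture has only 24 bursts, which narrows the maxCC gap
  # between regular and irregular cells (the cutoff is known to depend on
  # burst count and recording length), so the bar here is lower than the
  # >= 85% checked at full scale in the acceptance suite
  run <- small_run()
  er <- eval_roi_recovery(run$res$rois, run$rec$truth)
  reg <- eval_regularity_recovery(run$res$cells, run$rec$truth, er$matches)
  expect_gte(reg$accuracy, 0.7)
})

test_that("composition table reproduces the published five-slice layout", {
  counts <- list(
    "1" = c(3, 3, 5, 2, 3),
    "2" = c(5, 1, 8, 2, 1),
    "3" = c(3, 3, 4, 3, 1),
    "4" = c(9, 2, 8, 2, 1),
    "5" = c(7, 2, 4, 2, 0)
  )
  cells <- do.call(rbind, lapply(names(counts), function(s) {
    data.frame(slice = s, cell_type = rep(CELL_TYPES, counts[[s]]))
  }))
  comp <- composition_table(cells)
  tot <- comp$counts[comp$counts$slice == "Total", ]
  expect_equal(unname(unlist(tot[, CELL_TYPES])), c(27, 11, 29, 11, 6))
  expect_equal(tot$Total, 84)
  p1 <- comp$percentages[comp$percentages$slice == "1", ]
  expect_equal(unname(unlist(p1[, CELL_TYPES])), c(18.8, 18.8, 31.3, 12.5, 18.8))
  ptot <- comp$percentages[comp$percentages$slice == "Total", ]
  expect_equal(unname(unlist(ptot[, CELL_TYPES])), c(32.1, 13.1, 34.5, 13.1, 7.1))
  # every percentage row sums to 100 within one-decimal rounding slack
  pc <- as.matrix(comp$percentages[, CELL_TYPES])
  expect_true(all(abs(rowSums(pc) - 100) <= 0.25))
})

test_that("empty slices give zero rows with a warning", {
  cells <- data.frame(slice = "1", cell_type = c("R-Ex", "Irr-Ex"))
  expect_warning(comp <- composition_table(cells, slices = c("1", "2")), "no classified")
  r2 <- comp$counts[comp$counts$slice == "2", ]
  expect_equal(r2$Total, 0)
  expect_equal(unname(unlist(comp$percentages[comp$percentages$slice == "2",
                                              CELL_TYPES])), rep(0, 5))
})
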