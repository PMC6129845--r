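# NMF unmixing: exact recovery on noise-free products, objective monotonicity,
# scale invariance, and marker flags.

test_that("noise-free mixture is recovered up to component matching", {
  set.seed(4)
  px <- 12L
  M <- default_mixing_matrix()
  maps <- list(OGB1 = matrix(0, px, px), EGFP = matrix(0, px, px),
               tdTomato = matrix(0, px, px))
  maps$OGB1[2:5, 2:5] <- 1
  maps$EGFP[7:10, 2:5] <- 0.8
  maps$tdTomato[7:10, 7:10] <- 1.2
  H <- rbind(as.vector(maps$OGB1), as.vector(maps$EGFP), as.vector(maps$tdTomato))
  V <- M %*% H
  dat <- array(0, c(3, 3, px, px))
  for (i in 1:3) for (j in 1:3) dat[i, j, , ] <- matrix(V[(i - 1) * 3 + j, ], px, px)
  st <- spectral_stack(dat, c(720, 800, 900), c("a", "b", "c"))
  um <- unmix(st, seed = 1)
  expect_lt(um$reconstruction_error, 1e-3)
  for (nm in names(maps)) {
    cs <- sum(um$abundance_maps[[nm]] * maps[[nm]]) /
      sqrt(sum(um$abundance_maps[[nm]]^2) * sum(maps[[nm]]^2))
    expect_gte(cs, 0.99)
  }
})

test_that("a rank-1 single-fluorophore stack factorizes to near-zero error", {
  px <- 8L
  M <- default_mixing_matrix()
  h <- matrix(runif(px * px), px, px)
  V <- M[, 1, drop = FALSE] %*% matrix(as.vector(h), 1)
  dat <- array(0, c(3, 3, px, px))
  for (i in 1:3) for (j in 1:3) dat[i, j, , ] <- matrix(V[(i - 1) * 3 + j, ], px, px)
  st <- spectral_stack(dat, c(720, 800, 900), c("a", "b", "c"))
  um <- unmix(st, n_components = 1L, seed = 2, dark_quantile = 0)
  expect_lt(um$reconstruction_error, 1e-6)
})

test_that("NMF objective is non-increasing across multiplicative updates", {
  set.seed(10)
  V <- matrix(runif(9 * 40), 9, 40)
  fit <- nmf_multiplicative(V, 3, seed = 5, max_iter = 200, tol = 0, trace = TRUE)
  expect_true(all(diff(fit$error_path) <= 1e-12))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
})

test_that("unmixing the default synthetic stack recovers ground-truth maps", {
  # full-scale field; trimming the burst count keeps the movie cheap while
  # leaving the reference stack identical in structure
  cfg <- default_paper_like_config(1)
  cfg$n_bursts <- 6L
  rec <- generate_recording(cfg)
  um <- unmix(rec$stack, seed = 1)
  truth_maps <- rec$truth$abundance
  expect_true(all(um$spectra >= 0))
  expect_equal(colSums(um$spectra), rep(1, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  sims <- vapply(names(truth_maps), function(nm) {
    a <- um$abundance_maps[[nm]]
    b <- truth_maps[[nm]]
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }, numeric(1))
  expect_gte(mean(sims), 0.95)
})

test_that("global intensity scaling changes neither flags nor assignment", {
  run <- small_run()
  st <- run$rec$stack
  st5 <- spectral_stack(st$data * 5, st$excitation_nm, st$emission_band_labels)
  um1 <- unmix(st, seed = 3)
  um5 <- unmix(st5, seed = 3)
  expect_identical(um1$assignment, um5$assignment)
  centers <- run$res$rois$table[, c("row", "col")]
  f1 <- fluorophore_flags(um1, centers)
  f5 <- fluorophore_flags(um5, centers)
  expect_identical(f1, f5)
})

test_that("marker flags match planted identities on matched cells", {
  run <- small_run()
  um <- run$res$unmix
  truth <- run$rec$truth
  er <- eval_roi_recovery(run$res$rois, truth)
  centers <- run$res$rois$table[match(er$matches$roi_id, run$res$rois$table$id),
                                c("row", "col")]
  fl <- fluorophore_flags(um, centers)
  want_ty <- truth$cells$cell_type[match(er$matches$truth_id, truth$cells$id)]
  want_gly <- want_ty %in% c("R-Gly", "Irr-Gly", "Irr-Cotrans")
  want_gad <- want_ty == "Irr-Cotrans"
  expect_gte(mean(fl$glyt2_pos == want_gly), 0.9)
  expect_gte(mean(fl$gad65_pos == want_gad), 0.9)
})

test_that("zero abundance maps give negative flags and zero stacks error", {
  px <- 10L
  um0 <- structure(
    list(abundance_maps = list(OGB1 = matrix(0, px, px),
                               EGFP = matrix(0, px, px),
                               tdTomato = matrix(0, px, px)),
         spectra = default_mixing_matrix(), reconstruction_error = 0,
         assignment = c("OGB1", "EGFP", "tdTomato")),
    class = "pbs_unmix")
  fl <- fluorophore_flags(um0, c(5, 5))
  expect_false(fl$glyt2_pos)
  expect_false(fl$gad65_pos)
  expect_error(fluorophore_flags(um0, c(0, 0)), "border")
  st0 <- spectral_stack(array(0, c(3, 3, px, px)), c(720, 800, 900),
                        c("a", "b", "c"))
  expect_error(unmix(st0), "all-zero")
})
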