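# Seeded generator for paper-like recordings: a rhythmic LFP burst train,
# five cell classes painted into a calcium movie, a 3x3 excitation/emission
# reference stack from a known mixing matrix, and the ground truth needed to
# score every downstream stage.

ALL_TYPES <- c(CELL_TYPES, "NonRhythmic")

#' Default 9 x 3 spectral mixing matrix
#'
#' Rows are the 9 acquisition channels in excitation-major order
#' (ex 720, 800, 900 nm; em 475/50, 531/40, 641/75 nm bands), columns the
#' fluorophores OGB-1, EGFP, tdTomato. Values are plausible relative
#' two-photon excitation x emission-band products, column-normalized to unit
#' sum; they are linearly independent, which is all the unmixer requires.
#'
#' @return 9 x 3 nonnegative matrix with unit-sum columns
#' @export
default_mixing_matrix <- function() {
  m <- cbind(
    # OGB-1: excited best near 800, green emission split over 475/531 bands
    OGB1     = c(0.02, 0.06, 0.01,  0.18, 0.50, 0.04,  0.04, 0.12, 0.01),
    # EGFP: excited best near 900, green emission
    EGFP     = c(0.02, 0.03, 0.00,  0.08, 0.12, 0.01,  0.22, 0.45, 0.03),
    # tdTomato: red emission only (nothing below ~550 nm), with appreciable
    # short-wavelength (S0->S2) two-photon excitation at 720
    tdTomato = c(0.00, 0.02, 0.35,  0.00, 0.02, 0.18,  0.01, 0.04, 0.38)
  )
  sweep(m, 2L, colSums(m), "/")
}

#' Configuration for the synthetic-recording generator
#'
#' Defaults (via [default_paper_like_config()]) encode the study conditions:
#' five inspiratory cell types plus non-rhythmic distractors, ~0.2 Hz bursting
#' with jitter, occasional large sigh bursts, OGB-1-like calcium kinetics and
#' a known spectral mixing matrix.
#'
#' @param n_cells_per_type named integer vector over
#'   R-Ex, R-Gly, Irr-Ex, Irr-Gly, Irr-Cotrans, NonRhythmic
#' @param burst_interval_s c(mean, sd) of the inter-burst interval (s)
#' @param n_bursts number of rhythmic bursts
#' @param sigh_every_n mean number of bursts between sighs (0 = no sighs)
#' @param timing_offset_ms data.frame with rownames = cell types and columns
#'   mean, sd: calcium-peak offset vs the LFP burst center (ms)
#' @param p_active named per-type per-cycle activation probability
#' @param amp data.frame (rownames = types) of transient amplitude mean, sd (a.u.)
#' @param ca_kernel c(rise_ms, decay_ms) of the double-exponential calcium kernel
#' @param noise_sd per-pixel per-frame imaging noise SD (a.u.)
#' @param mixing_matrix 9 x 3 nonnegative spectral signatures (channels x fluorophores)
#' @param seed RNG seed
#' @param img_px image side length (pixels, square field)
#' @param pixel_size_um micrometers per pixel
#' @param sampling_rate_hz imaging frame rate (Hz)
#' @param lfp_rate_hz LFP sampling rate (Hz)
#' @param cell_radius_px soma disk radius (pixels)
#' @param margin_px keep cell centers this far from the border
#' @param min_center_dist_px minimum Chebyshev distance between centers
#' @param sigh_scale amplitude factor of sigh bursts
#' @param sigh_doublet_ms delay of the second calcium peak during sighs
#' @param burst_env_sd_s Gaussian SD of the LFP burst envelope (s)
#' @param lfp_noise_sd background LFP noise SD relative to unit burst amplitude
#' @param baseline movie baseline fluorescence (a.u.)
#' @param stack_noise_sd reference-stack noise SD
#' @return object of class `pbs_synth_config`
#' @export
synth_config <- function(n_cells_per_type,
                         burst_interval_s = c(mean = 5, sd = 0.8),
                         n_bursts = 120L,
                         sigh_every_n = 20,
                         timing_offset_ms,
                         p_active,
                         amp,
                         ca_kernel = c(rise_ms = 80, decay_ms = 1000),
                         noise_sd = 1,
                         mixing_matrix = default_mixing_matrix(),
                         seed = 1L,
                         img_px = 80L,
                         pixel_size_um = 1.0,
                         sampling_rate_hz = 10,
                         lfp_rate_hz = 10000,
                         cell_radius_px = 3,
                         margin_px = 6L,
                         min_center_dist_px = 8,
                         sigh_scale = 2.5,
                         sigh_doublet_ms = 600,
                         burst_env_sd_s = 0.15,
                         lfp_noise_sd = 0.05,
                         baseline = 10,
                         stack_noise_sd = 0.02) {
  cfg <- structure(as.list(environment()), class = "pbs_synth_config")
  validate_synth_config(cfg)
  cfg
}

#' Validate a synthetic-data configuration
#' @param cfg a `pbs_synth_config`
#' @return `cfg`, invisibly; errors on violation
#' @export
validate_synth_config <- function(cfg) {
  stopifnot(inherits(cfg, "pbs_synth_config"))
  if (!all(ALL_TYPES %in% names(cfg$n_cells_per_type))) {
    stop("n_cells_per_type must name all of: ", paste(ALL_TYPES, collapse = ", "))
  }
  if (any(cfg$n_cells_per_type < 0)) stop("cell counts must be nonnegative")
  if (!all(CELL_TYPES %in% names(cfg$p_active))) stop("p_active must cover the 5 cell types")
  if (any(cfg$p_active < 0 | cfg$p_active > 1)) stop("p_active must lie in [0,1]")
  if (!all(CELL_TYPES %in% rownames(cfg$timing_offset_ms))) {
    stop("timing_offset_ms must have one row per cell type")
  }
  if (!all(CELL_TYPES %in% rownames(cfg$amp))) stop("amp must have one row per cell type")
  k <- cfg$ca_kernel
  if (!(k[["decay_ms"]] > k[["rise_ms"]] && k[["rise_ms"]] > 0)) {
    stop("ca_kernel must satisfy decay > rise > 0")
  }
  mm <- cfg$mixing_matrix
  if (any(mm < 0)) stop("mixing_matrix must be nonnegative")
  if (qr(mm)$rank < ncol(mm)) stop("mixing_matrix columns must be linearly independent")
  if (cfg$lfp_rate_hz <= 100 * cfg$sampling_rate_hz) {
    stop("lfp_rate_hz must exceed 100x the imaging rate")
  }
  invisible(cfg)
}

#' Paper-like default generator configuration
#'
#' Thirty rhythmic cells proportioned like the study's pooled composition
#' (10 R-Ex, 4 R-Gly, 10 Irr-Ex, 4 Irr-Gly, 2 Irr-Cotrans) plus 6 non-rhythmic
#' distractors; 120 bursts at 5 +/- 0.8 s with a sigh every ~20 bursts; type
#' mean offsets ordered Irr-Gly < Irr-Ex < R-Gly < R-Ex < Irr-Cotrans with
#' cycle-to-cycle SDs of 0.35-0.5 s; regular types activate nearly every cycle
#' with large transients, irregular types skip ~40% of cycles with small ones.
#' Pure function: repeated calls return identical configurations.
#'
#' @param seed RNG seed carried into the config
#' @return a [synth_config()] object
#' @export
default_paper_like_config <- function(seed = 1L) {
  synth_config(
    n_cells_per_type = c(
      "R-Ex" = 10L, "R-Gly" = 4L, "Irr-Ex" = 10L, "Irr-Gly" = 4L,
      "Irr-Cotrans" = 2L, "NonRhythmic" = 6L
    ),
    timing_offset_ms = data.frame(
      mean = c(225, 170, 102, 81, 290),
      sd   = c(350, 350, 450, 450, 400),
      row.names = CELL_TYPES
    ),
    p_active = c(
      "R-Ex" = 0.95, "R-Gly" = 0.95, "Irr-Ex" = 0.6, "Irr-Gly" = 0.6,
      "Irr-Cotrans" = 0.6
    ),
    amp = data.frame(
      mean = c(8, 8, 3.5, 3.5, 3.5),
      sd   = c(1.5, 1.5, 0.8, 0.8, 0.8),
      row.names = CELL_TYPES
    ),
    seed = as.integer(seed)
  )
}

# double-exponential calcium kernel evaluated at times t (s) after onset,
# normalized to unit peak; peak occurs at rise*log(1 + decay/rise) after onset
.ca_kernel_fun <- function(rise_s, decay_s) {
  t_peak <- rise_s * log(1 + decay_s / rise_s)
  peak <- (1 - exp(-t_peak / rise_s)) * exp(-t_peak / decay_s)
  list(
    t_peak = t_peak,
    eval = function(t) {
      v <- (1 - exp(-pmax(t, 0) / rise_s)) * exp(-pmax(t, 0) / decay_s) / peak
      v[t < 0] <- 0
      v
    }
  )
}

# Gaussian-edged disk footprint; weight 1 inside radius-1, soft shoulder out
# to radius + 1.5 px
.footprint <- function(radius_px) {
  r_max <- ceiling(radius_px + 1.5)
  g <- expand.grid(dr = -r_max:r_max, dc = -r_max:r_max)
  d <- sqrt(g$dr^2 + g$dc^2)
  w <- ifelse(d <= radius_px - 1, 1, exp(-(d - (radius_px - 1))^2 / (2 * 0.8^2)))
  w[d > r_max] <- 0
  keep <- w > 1e-3
  data.frame(dr = g$dr[keep], dc = g$dc[keep], w = w[keep])
}

.place_cells <- function(n, img_px, margin, min_dist, max_tries = 2000L,
                         max_restarts = 25L) {
  if (n == 0L) return(matrix(numeric(0), 0L, 2L, dimnames = list(NULL, c("row", "col"))))
  lo <- margin
  hi <- img_px - 1L - margin
  if (hi < lo) stop("image too small for the requested margin")
  # sequential rejection sampling can wedge in dense fields; restart afresh
  for (restart in seq_len(max_restarts)) {
    centers <- matrix(NA_real_, n, 2L, dimnames = list(NULL, c("row", "col")))
    placed <- 0L
    tries <- 0L
    while (placed < n && tries < max_tries) {
      tries <- tries + 1L
      cand <- c(sample(lo:hi, 1L), sample(lo:hi, 1L))
      if (placed > 0L) {
        cheb <- pmax(abs(centers[seq_len(placed), 1L] - cand[1L]),
                     abs(centers[seq_len(placed), 2L] - cand[2L]))
        if (min(cheb) < min_dist) next
      }
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
    if (placed == n) return(centers)
  }
  stop("could not place ", n, " non-overlapping cells after ", max_restarts,
       " restarts; enlarge the field or reduce the cell count")
}

#' Generate one synthetic recording with ground truth
#'
#' Produces a calcium [movie()], the matching [spectral_stack()], the raw
#' [lfp_trace()] and a ground-truth object holding cell positions/types,
#' burst times, sigh flags, and every true per-(cell, burst) calcium-peak
#' offset. Identical seeds give bit-identical outputs.
#'
#' Burst peak times in the ground truth are the centers of the LFP burst
#' envelopes; each active cell's calcium kernel peaks at
#' `burst center + offset`, with offsets drawn per type from
#' `timing_offset_ms`. Sigh bursts scale both the LFP envelope and the
#' calcium amplitude by `sigh_scale` and add a second calcium peak
#' `sigh_doublet_ms` later.
#'
#' @param cfg a [synth_config()] object
#' @return list with elements movie, stack, lfp, truth, cfg
#' @export
generate_recording <- function(cfg) {
  validate_synth_config(cfg)
  set.seed(cfg$seed)
  fs <- cfg$sampling_rate_hz
  px <- cfg$img_px

  # --- burst train -----------------------------------------------------
  nb <- cfg$n_bursts
  iv_mean <- cfg$burst_interval_s[["mean"]]
  iv_sd <- cfg$burst_interval_s[["sd"]]
  gaps <- pmax(1.5, rnorm(nb, iv_mean, iv_sd))
  burst_t <- iv_mean + c(0, cumsum(gaps[-nb]))
  sigh <- if (cfg$sigh_every_n > 0) runif(nb) < 1 / cfg$sigh_every_n else rep(FALSE, nb)
  duration <- burst_t[nb] + iv_mean
  n_frames <- ceiling(duration * fs)
  frame_t <- (seq_len(n_frames) - 1L) / fs

  # --- cells -----------------------------------------------------------
  types <- rep(ALL_TYPES, times = cfg$n_cells_per_type[ALL_TYPES])
  n_cells <- length(types)
  centers <- .place_cells(n_cells, px, cfg$margin_px, cfg$min_center_dist_px)
  cells <- data.frame(
    id = seq_len(n_cells),
    row = centers[, 1L], col = centers[, 2L],
    cell_type = types,
    regularity = ifelse(grepl("^R-", types), "Regular",
                        ifelse(grepl("^Irr-", types), "Irregular", NA)),
    stringsAsFactors = FALSE
  )

  # --- raw LFP ---------------------------------------------------------
  n_raw <- ceiling(duration * cfg$lfp_rate_hz)
  raw <- rnorm(n_raw, 0, cfg$lfp_noise_sd)
  env_sd <- cfg$burst_env_sd_s
  half_w <- ceiling(4 * env_sd * cfg$lfp_rate_hz)
  for (b in seq_len(nb)) {
    c_idx <- round(burst_t[b] * cfg$lfp_rate_hz) + 1L
    idx <- max(1L, c_idx - half_w):min(n_raw, c_idx + half_w)
    t_rel <- (idx - c_idx) / cfg$lfp_rate_hz
    a <- if (sigh[b]) cfg$sigh_scale else 1
    raw[idx] <- raw[idx] + a * exp(-t_rel^2 / (2 * env_sd^2)) * rnorm(length(idx))
  }
  lfp <- lfp_trace(raw, cfg$lfp_rate_hz, frame_trigger_times = frame_t)

  # --- per-cell calcium traces and truth offsets -----------------------
  ker <- .ca_kernel_fun(cfg$ca_kernel[["rise_ms"]] / 1000,
                        cfg$ca_kernel[["decay_ms"]] / 1000)
  traces <- matrix(0, n_frames, n_cells)
  off_cell <- integer(0); off_burst <- integer(0)
  off_val <- numeric(0); off_amp <- numeric(0)
  for (i in seq_len(n_cells)) {
    ty <- types[i]
    if (ty == "NonRhythmic") next
    p <- cfg$p_active[[ty]]
    mu <- cfg$timing_offset_ms[ty, "mean"] / 1000
    sdv <- cfg$timing_offset_ms[ty, "sd"] / 1000
    a_mu <- cfg$amp[ty, "mean"]
    a_sd <- cfg$amp[ty, "sd"]
    active <- runif(nb) < p
    offs <- pmin(2, pmax(-2, rnorm(nb, mu, sdv)))
    amps <- pmax(0.2 * a_mu, rnorm(nb, a_mu, a_sd))
    amps[sigh] <- amps[sigh] * cfg$sigh_scale
    for (b in which(active)) {
      peak_t <- burst_t[b] + offs[b]
      onset <- peak_t - ker$t_peak
      traces[, i] <- traces[, i] + amps[b] * ker$eval(frame_t - onset)
      if (sigh[b]) {
        onset2 <- onset + cfg$sigh_doublet_ms / 1000
        traces[, i] <- traces[, i] + 0.7 * amps[b] * ker$eval(frame_t - onset2)
      }
    }
    k <- sum(active)
    off_cell <- c(off_cell, rep(i, k))
    off_burst <- c(off_burst, which(active))
    off_val <- c(off_val, offs[active])
    off_amp <- c(off_amp, amps[active])
  }
  offsets <- data.frame(cell_id = off_cell, burst_id = off_burst,
                        offset_s = off_val, amplitude = off_amp)

  # --- movie -----------------------------------------------------------
  fp <- .footprint(cfg$cell_radius_px)
  dat <- array(rnorm(n_frames * px * px, cfg$baseline, cfg$noise_sd),
               c(n_frames, px, px))
  for (i in seq_len(n_cells)) {
    rr <- cells$row[i] + fp$dr + 1L   # to 1-based array index
    cc <- cells$col[i] + fp$dc + 1L
    ok <- rr >= 1L & rr <= px & cc >= 1L & cc <= px
    if (types[i] == "NonRhythmic") next
    for (j in which(ok)) {
      dat[, rr[j], cc[j]] <- dat[, rr[j], cc[j]] + traces[, i] * fp$w[j]
    }
  }
  dat[dat < 0] <- 0
  mov <- movie(dat, frame_t, cfg$pixel_size_um, fs)

  # --- spectral reference stack ---------------------------------------
  paint <- function(which_cells) {
    m <- matrix(0, px, px)
    for (i in which_cells) {
      rr <- cells$row[i] + fp$dr + 1L
      cc <- cells$col[i] + fp$dc + 1L
      ok <- rr >= 1L & rr <= px & cc >= 1L & cc <= px
      m[cbind(rr[ok], cc[ok])] <- pmax(m[cbind(rr[ok], cc[ok])], fp$w[ok])
    }
    m
  }
  h_ogb <- paint(seq_len(n_cells)) + 0.05            # indicator bulk-loads everything
  h_egfp <- paint(which(types %in% c("R-Gly", "Irr-Gly", "Irr-Cotrans")))
  h_tdt <- paint(which(types == "Irr-Cotrans"))
  H <- rbind(as.vector(h_ogb), as.vector(h_egfp), as.vector(h_tdt))
  V <- cfg$mixing_matrix %*% H
  V <- V + abs(rnorm(length(V), 0, cfg$stack_noise_sd))
  sdat <- array(0, c(3L, 3L, px, px))
  for (i in 1:3) for (j in 1:3) {
    sdat[i, j, , ] <- matrix(V[(i - 1L) * 3L + j, ], px, px)
  }
  stack <- spectral_stack(sdat, c(720, 800, 900), c("475/50", "531/40", "641/75"))

  truth <- structure(
    list(
      cells = cells,
      bursts = data.frame(id = seq_len(nb), peak_time_s = burst_t, is_sigh = sigh),
      offsets = offsets,
      abundance = list(OGB1 = h_ogb, EGFP = h_egfp, tdTomato = h_tdt)
    ),
    class = "pbs_truth"
  )
  list(movie = mov, stack = stack, lfp = lfp, truth = truth, cfg = cfg)
}

#' Write the ground truth of a synthetic recording to CSV files
#'
#' @param truth `pbs_truth` object from [generate_recording()]
#' @param out_dir directory
#' @return named vector of paths
#' @export
write_ground_truth <- function(truth, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(
    cells = file.path(out_dir, "truth_cells.csv"),
    bursts = file.path(out_dir, "truth_bursts.csv"),
    offsets = file.path(out_dir, "truth_offsets.csv")
  )
  data.table::fwrite(truth$cells, paths[["cells"]])
  data.table::fwrite(truth$bursts, paths[["bursts"]])
  data.table::fwrite(truth$offsets, paths[["offsets"]])
  paths
}
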