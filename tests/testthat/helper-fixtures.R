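# Small fixture builders shared across test files. All fixtures are built in
# code at test time; seeds are fixed so expectations are stable.

# a compact but fully featured generator configuration: ~13 cells, 24 bursts,
# ~130 s recording, 56 px field, 2 kHz LFP (keeps every invariant of the
# full-scale configuration while running in seconds)
small_synth_cfg <- function(seed = 1L, n_bursts = 24L) {
  cfg <- default_paper_like_config(seed)
  cfg$n_cells_per_type <- c(
    "R-Ex" = 3L, "R-Gly" = 2L, "Irr-Ex" = 3L, "Irr-Gly" = 2L,
    "Irr-Cotrans" = 1L, "NonRhythmic" = 2L
  )
  cfg$n_bursts <- as.integer(n_bursts)
  cfg$img_px <- 56L
  cfg$lfp_rate_hz <- 2000
  validate_synth_config(cfg)
  cfg
}

# memoized small end-to-end run (generation + all stages) reused by several
# test files
small_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- generate_recording(small_synth_cfg())
      res <- suppressWarnings(process_slice(rec, pipeline_config()))
      cache <<- list(rec = rec, res = res)
    }
    cache
  }
})

# a minimal valid movie: n frames of h x w noise-free ramps
toy_movie <- function(n = 20L, h = 16L, w = 16L, rate = 10) {
  dat <- array(0, c(n, h, w))
  for (f in seq_len(n)) dat[f, , ] <- f / n
  movie(dat, (seq_len(n) - 1) / rate, pixel_size_um = 1, sampling_rate_hz = rate)
}

# integrated-LFP object from a plain vector (for burst/sequence unit tests)
toy_ilfp <- function(values, rate = 10) {
  structure(
    list(values = values, frame_times = (seq_along(values) - 1) / rate,
         tau_s = 0.15,
         sd_detrended = sd(detrend_moving_median(values, rate))),
    class = "pbs_ilfp"
  )
}

# filtered-movie wrapper around an arbitrary frames x h x w array
toy_fmovie <- function(data, rate = 10) {
  structure(
    list(data = data, band_hz = c(0.025, 1.5), filter_order = 3L,
         frame_times = (seq_len(dim(data)[1L]) - 1) / rate,
         sampling_rate_hz = rate),
    class = "pbs_fmovie"
  )
}
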