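# Raw-data containers and all file-format plumbing. Movies and spectral
# stacks travel as multi-page TIFF + JSON sidecar; traces and result tables
# as CSV. All times are seconds with origin at the first LFP sample; pixel
# coordinates are 0-based (row, col).

#' Construct a calcium movie
#'
#' @param data numeric array, frames x height x width, nonnegative
#' @param frame_times seconds, one per frame, strictly increasing
#' @param pixel_size_um micrometers per pixel
#' @param sampling_rate_hz nominal frame rate
#' @return object of class `pbs_movie`
#' @export
movie <- function(data, frame_times, pixel_size_um, sampling_rate_hz) {
  stopifnot(length(dim(data)) == 3L)
  n <- dim(data)[1L]
  if (n < 2L) stop("frames >= 2 required")
  if (length(frame_times) != n) stop("frame_times length must equal frame count")
  dt <- diff(frame_times)
  if (any(dt <= 0)) stop("frame_times must be strictly increasing")
  if (any(data < 0)) stop("fluorescence must be nonnegative")
  nominal <- 1 / sampling_rate_hz
  if (abs(median(dt) - nominal) >= 0.1 * nominal) {
    stop("median frame spacing deviates >10% from 1/sampling_rate_hz")
  }
  if (max(dt) > 2 * median(dt)) {
    warning("irregular frame timing: at least one inter-frame gap exceeds 2x the median")
  }
  structure(
    list(data = data, frame_times = as.numeric(frame_times),
         pixel_size_um = pixel_size_um, sampling_rate_hz = sampling_rate_hz),
    class = "pbs_movie"
  )
}

#' @export
print.pbs_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<pbs_movie> %d frames, %d x %d px (%.2f um/px), %.3g Hz, %.1f s\n",
              d[1], d[2], d[3], x$pixel_size_um, x$sampling_rate_hz,
              diff(range(x$frame_times))))
  invisible(x)
}

#' Construct a multispectral reference stack
#'
#' @param data nonnegative array, n_excitations x n_emissions x height x width
#' @param excitation_nm excitation wavelengths (nm)
#' @param emission_band_labels emission filter band names
#' @return object of class `pbs_stack`
#' @export
spectral_stack <- function(data, excitation_nm, emission_band_labels) {
  stopifnot(length(dim(data)) == 4L)
  if (dim(data)[1L] != length(excitation_nm)) stop("excitation count mismatch")
  if (dim(data)[2L] != length(emission_band_labels)) stop("emission band count mismatch")
  if (any(data < 0)) stop("stack intensities must be nonnegative")
  structure(
    list(data = data, excitation_nm = excitation_nm,
         emission_band_labels = emission_band_labels),
    class = "pbs_stack"
  )
}

#' Construct an LFP trace
#'
#' @param raw electrode signal (arbitrary units) sampled at `raw_rate_hz`
#' @param raw_rate_hz sampling rate in Hz (~10 kHz in practice)
#' @param frame_trigger_times optional seconds of each imaging frame trigger
#' @return object of class `pbs_lfp`
#' @export
lfp_trace <- function(raw, raw_rate_hz, frame_trigger_times = NULL) {
  stopifnot(is.numeric(raw), raw_rate_hz > 0)
  if (!is.null(frame_trigger_times)) {
    if (any(diff(frame_trigger_times) <= 0)) {
      stop("frame_trigger_times must be strictly increasing")
    }
    span <- (length(raw) - 1L) / raw_rate_hz
    if (min(frame_trigger_times) < 0 || max(frame_trigger_times) > span) {
      stop("frame_trigger_times outside the raw trace's time span")
    }
  }
  structure(
    list(raw = as.numeric(raw), raw_rate_hz = raw_rate_hz,
         frame_trigger_times = frame_trigger_times),
    class = "pbs_lfp"
  )
}

#' @export
print.pbs_lfp <- function(x, ...) {
  cat(sprintf("<pbs_lfp> %d samples @ %.4g Hz (%.1f s)%s\n",
              length(x$raw), x$raw_rate_hz, length(x$raw) / x$raw_rate_hz,
              if (is.null(x$frame_trigger_times)) "" else
                sprintf(", %d frame triggers", length(x$frame_trigger_times))))
  invisible(x)
}

# power-of-two scale so division is exact in binary floating point
.tiff_scale <- function(mx) {
  if (mx <= 1) 1 else 2^ceiling(log2(mx))
}

#' Write a movie as multi-page float TIFF + JSON sidecar
#'
#' Intensities are divided by a power-of-two scale (recorded in the sidecar)
#' so they fit the TIFF library's unit intensity range without decimal rounding.
#'
#' @param m a [movie()] object
#' @param path TIFF path; the sidecar goes to `<path>.json`
#' @return `path`, invisibly
#' @export
write_movie <- function(m, path) {
  stopifnot(inherits(m, "pbs_movie"))
  sc <- .tiff_scale(max(m$data))
  pages <- lapply(seq_len(dim(m$data)[1L]), function(f) m$data[f, , ] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(
    pixel_size_um = m$pixel_size_um,
    sampling_rate_hz = m$sampling_rate_hz,
    intensity_scale = sc,
    frame_times = m$frame_times
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_movie()] (sidecar at `<path>.json`)
#' @return a [movie()] object
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop("metadata sidecar missing (", sidecar, "); refusing to guess pixel size/frame rate")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("pixel_size_um", "sampling_rate_hz")) {
    if (is.null(meta[[f]])) stop("metadata missing field: ", f)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 2L) stop("frames >= 2 required")
  sc <- meta$intensity_scale %||% 1
  dat <- array(0, c(length(pages), nrow(pages[[1L]]), ncol(pages[[1L]])))
  for (f in seq_along(pages)) dat[f, , ] <- pages[[f]] * sc
  ft <- meta$frame_times %||% ((seq_along(pages) - 1) / meta$sampling_rate_hz)
  movie(dat, ft, meta$pixel_size_um, meta$sampling_rate_hz)
}

#' Write a spectral stack as multi-page TIFF + JSON sidecar
#'
#' Pages are ordered excitation-major: (ex1,em1), (ex1,em2), ...
#'
#' @param s a [spectral_stack()] object
#' @param path TIFF path
#' @return `path`, invisibly
#' @export
write_stack <- function(s, path) {
  stopifnot(inherits(s, "pbs_stack"))
  d <- dim(s$data)
  sc <- .tiff_scale(max(s$data))
  pages <- list()
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    pages[[length(pages) + 1L]] <- s$data[i, j, , ] / sc
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(excitation_nm = s$excitation_nm,
               emission_band_labels = s$emission_band_labels,
               intensity_scale = sc)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectral stack written by [write_stack()]
#' @param path TIFF path
#' @return a [spectral_stack()] object
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("unreadable file: ", path)
  if (!file.exists(sidecar)) stop("metadata sidecar missing: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nex <- length(meta$excitation_nm)
  nem <- length(meta$emission_band_labels)
  stopifnot(length(pages) == nex * nem)
  sc <- meta$intensity_scale %||% 1
  dat <- array(0, c(nex, nem, nrow(pages[[1L]]), ncol(pages[[1L]])))
  k <- 1L
  for (i in seq_len(nex)) for (j in seq_len(nem)) {
    dat[i, j, , ] <- pages[[k]] * sc
    k <- k + 1L
  }
  spectral_stack(dat, meta$excitation_nm, meta$emission_band_labels)
}

#' Write an LFP trace to CSV
#'
#' Columns time_s, value and, when trigger times are present, a 0/1 trigger
#' column whose rising edges mark frame starts.
#'
#' @param lfp a [lfp_trace()] object
#' @param path CSV path
#' @return `path`, invisibly
#' @export
write_lfp_csv <- function(lfp, path) {
  stopifnot(inherits(lfp, "pbs_lfp"))
  t <- (seq_along(lfp$raw) - 1L) / lfp$raw_rate_hz
  df <- data.frame(time_s = t, value = lfp$raw)
  if (!is.null(lfp$frame_trigger_times)) {
    trig <- numeric(length(t))
    idx <- pmin(length(t), round(lfp$frame_trigger_times * lfp$raw_rate_hz) + 1L)
    trig[idx] <- 1
    df$trigger <- trig
  }
  data.table::fwrite(df, path)
  invisible(path)
}

#' Read an LFP trace from CSV
#'
#' Expects columns `time_s` and `value`; an optional `trigger` column is
#' thresholded at half its maximum and rising edges become frame trigger
#' times. The raw rate is inferred as 1/median(diff(time_s)).
#'
#' @param path CSV path
#' @return a [lfp_trace()] object
#' @export
read_lfp_csv <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  dt <- data.table::fread(path)
  if (!all(c("time_s", "value") %in% names(dt))) {
    stop("CSV must have columns time_s and value")
  }
  if (nrow(dt) < 1000L) stop("fewer than 1000 samples")
  tm <- dt$time_s
  if (any(diff(tm) <= 0)) stop("non-monotonic time column")
  rate <- 1 / median(diff(tm))
  trig_times <- NULL
  if ("trigger" %in% names(dt)) {
    tr <- dt$trigger
    thr <- max(tr) / 2
    if (is.finite(thr) && thr > 0) {
      edges <- which(diff(tr > thr) == 1L) + 1L
      if (tr[1L] > thr) edges <- c(1L, edges)
      trig_times <- tm[edges] - tm[1L]
    }
  }
  lfp_trace(dt$value, rate, trig_times)
}

#' Write all pipeline result tables to a directory
#'
#' Emits `cells.csv` (per-cell type, maxCC, position), `activations.csv`
#' (per activation cell, cycle, timing), and `composition.csv` laid out like
#' a per-slice composition table: one counts row and one percentage row per
#' slice plus a Total pair.
#'
#' @param cells data.frame with at least slice, id, row, col, maxcc, cell_type
#' @param activations data.frame with cell_id, burst_id, timing_s (may be empty)
#' @param composition result of [composition_table()], or NULL to compute from `cells`
#' @param out_dir output directory (created if needed)
#' @return named character vector of written paths
#' @export
write_results_tables <- function(cells, activations, composition = NULL, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("out_dir not writable: ", out_dir)
  }
  paths <- c(
    cells = file.path(out_dir, "cells.csv"),
    activations = file.path(out_dir, "activations.csv"),
    composition = file.path(out_dir, "composition.csv")
  )
  data.table::fwrite(cells, paths[["cells"]])
  data.table::fwrite(activations, paths[["activations"]])
  if (nrow(cells) == 0L) {
    warning("no cells: writing header-only composition table")
    hdr <- setNames(rep(list(numeric(0)), length(CELL_TYPES) + 3L),
                    c("slice", "row", CELL_TYPES, "Total"))
    data.table::fwrite(as.data.frame(hdr), paths[["composition"]])
    return(paths)
  }
  if (is.null(composition)) {
    composition <- composition_table(cells)
  }
  data.table::fwrite(composition_long(composition), paths[["composition"]])
  paths
}

#' Flatten a composition table into the interleaved counts/percentages layout
#'
#' @param comp result of [composition_table()]
#' @return data.frame with a counts row and a percentage row per slice
#' @export
composition_long <- function(comp) {
  cnt <- comp$counts
  pct <- comp$percentages
  out <- NULL
  for (i in seq_len(nrow(cnt))) {
    out <- rbind(
      out,
      data.frame(slice = cnt$slice[i], row = "count",
                 cnt[i, c(CELL_TYPES, "Total")], check.names = FALSE),
      data.frame(slice = cnt$slice[i], row = "percent",
                 pct[i, c(CELL_TYPES, "Total")], check.names = FALSE)
    )
  }
  rownames(out) <- NULL
  out
}
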