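# Per-(cell, burst) activation detection around each accepted LFP burst,
# the >= 50% cycle-inclusion rule, per-cycle activation orders with percent
# ranks, and per-type cumulative timing curves.

#' Robust noise level of a cell's trace from inter-burst frames
#'
#' 1.4826 x MAD of the samples farther than `window_frames` from every
#' accepted burst peak. If no such frame exists, falls back to the whole
#' trace with a warning.
#'
#' @param trace per-frame fluorescence of one cell
#' @param peak_frames accepted burst peak frames (1-based)
#' @param window_frames half-window in frames (default 24)
#' @return noise SD estimate
#' @export
trace_noise_sigma <- function(trace, peak_frames, window_frames = 24L) {
  n <- length(trace)
  near <- rep(FALSE, n)
  for (p in peak_frames) {
    near[max(1L, p - window_frames):min(n, p + window_frames)] <- TRUE
  }
  x <- trace[!near]
  if (length(x) < 10L) {
    warning("too few inter-burst frames for noise estimation; using whole trace")
    x <- trace
  }
  mad(x, constant = 1.4826)
}

#' Detect a single cell's activation around one burst
#'
#' The candidate is the largest strict local maximum of the cell's filtered
#' trace within `peak_frame +/- window_frames` (truncated at the recording
#' edges with a warning). An activation exists iff the candidate amplitude
#' exceeds `noise_k` x the cell's inter-burst noise SD. Timing is the peak
#' frame offset divided by the frame rate: negative = before the LFP peak.
#'
#' @param trace per-frame fluorescence of one cell
#' @param peak_frame burst peak frame (1-based)
#' @param rate_hz frame rate
#' @param window_frames half-window (default 24)
#' @param noise_k threshold in noise SDs (default 3)
#' @param noise_sigma precomputed noise SD (see [trace_noise_sigma()])
#' @return one-row data.frame (peak_frame, timing_s, peak_amplitude) or NULL
#' @export
detect_activation <- function(trace, peak_frame, rate_hz, window_frames = 24L,
                              noise_k = 3.0, noise_sigma) {
  n <- length(trace)
  lo <- peak_frame - window_frames
  hi <- peak_frame + window_frames
  if (lo < 1L || hi > n) {
    warning("activation window truncated at the recording edge")
    lo <- max(1L, lo)
    hi <- min(n, hi)
  }
  seg <- trace[lo:hi]
  lm <- local_maxima(seg)
  if (length(lm) == 0L) return(NULL)
  cand <- lm[which.max(seg[lm])]
  amp <- seg[cand]
  if (amp <= noise_k * noise_sigma) return(NULL)
  f <- lo + cand - 1L
  data.frame(peak_frame = f, timing_s = (f - peak_frame) / rate_hz,
             peak_amplitude = amp)
}

#' Detect all activations of all cells around all accepted bursts
#'
#' @param traces frames x n_cells matrix of filtered ROI traces
#' @param bursts a [detect_bursts()] (after [flag_sighs()]) result
#' @param rate_hz frame rate
#' @param window_frames half-window (default 24)
#' @param noise_k threshold in noise SDs (default 3)
#' @param cell_ids optional cell ids (default column index)
#' @return data.frame: cell_id, burst_id, peak_frame, timing_s, peak_amplitude
#' @export
detect_activations <- function(traces, bursts, rate_hz, window_frames = 24L,
                               noise_k = 3.0, cell_ids = NULL) {
  acc <- bursts[bursts$accepted, , drop = FALSE]
  nc <- ncol(traces)
  cell_ids <- cell_ids %||% seq_len(nc)
  out <- vector("list", nc * nrow(acc))
  k <- 0L
  for (i in seq_len(nc)) {
    sig <- trace_noise_sigma(traces[, i], acc$peak_frame, window_frames)
    for (b in seq_len(nrow(acc))) {
      a <- suppressWarnings(detect_activation(
        traces[, i], acc$peak_frame[b], rate_hz, window_frames, noise_k, sig))
      if (!is.null(a)) {
        k <- k + 1L
        out[[k]] <- cbind(data.frame(cell_id = cell_ids[i], burst_id = acc$id[b]), a)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(cell_id = integer(0), burst_id = integer(0),
                      peak_frame = integer(0), timing_s = numeric(0),
                      peak_amplitude = numeric(0)))
  }
  do.call(rbind, out[seq_len(k)])
}

#' Build per-cycle activation orders and percent ranks
#'
#' A cycle (accepted burst) is included iff at least `inclusion` of the
#' `n_cells` classified inspiratory cells were activated. Within an included
#' cycle, activations are sorted by timing (ties broken by smaller cell id;
#' tie counts are reported via an attribute) and position i of N gets
#' percent rank 100 * i / N.
#'
#' @param activations result of [detect_activations()]
#' @param n_cells number of classified inspiratory cells in the slice
#' @param bursts accepted-burst table ([detect_bursts()] output)
#' @param inclusion minimum activated fraction (default 0.5)
#' @return list: `cycles` (burst_id, included, n_activated),
#'   `ranked` (activations of included cycles with rank and percent_rank),
#'   attribute "n_ties" on `ranked`
#' @export
build_cycles <- function(activations, n_cells, bursts, inclusion = 0.5) {
  acc <- bursts[bursts$accepted, , drop = FALSE]
  if (nrow(acc) < 1L) stop("no accepted bursts")
  cyc <- data.frame(burst_id = acc$id, included = FALSE, n_activated = 0L)
  ranked <- NULL
  n_ties <- 0L
  for (j in seq_len(nrow(acc))) {
    a <- activations[activations$burst_id == acc$id[j], , drop = FALSE]
    cyc$n_activated[j] <- nrow(a)
    if (nrow(a) >= inclusion * n_cells && nrow(a) > 0L) {
      cyc$included[j] <- TRUE
      ord <- order(a$timing_s, a$cell_id)
      a <- a[ord, , drop = FALSE]
      n_ties <- n_ties + sum(duplicated(a$timing_s))
      a$rank <- seq_len(nrow(a))
      a$percent_rank <- 100 * a$rank / nrow(a)
      ranked <- rbind(ranked, a)
    }
  }
  if (is.null(ranked)) {
    ranked <- data.frame(cell_id = integer(0), burst_id = integer(0),
                         peak_frame = integer(0), timing_s = numeric(0),
                         peak_amplitude = numeric(0), rank = integer(0),
                         percent_rank = numeric(0))
  }
  attr(ranked, "n_ties") <- n_ties
  list(cycles = cyc, ranked = ranked)
}

#' Per-type cumulative activation-timing curves
#'
#' Empirical CDF of activation timings per cell type, evaluated on `grid`.
#' Types with no activations are omitted with a warning.
#'
#' @param activations data.frame with timing_s and cell_type columns
#' @param grid time points (s) at which to evaluate the CDFs
#' @return matrix grid-points x types of cumulative probabilities
#' @export
timing_cumulative <- function(activations, grid = seq(-2.4, 2.4, by = 0.1)) {
  types <- intersect(CELL_TYPES, unique(activations$cell_type))
  missing <- setdiff(unique(activations$cell_type), types)
  if (length(setdiff(CELL_TYPES, types)) > 0L) {
    warning("no activations for type(s): ",
            paste(setdiff(CELL_TYPES, types), collapse = ", "))
  }
  out <- sapply(types, function(ty) {
    x <- activations$timing_s[activations$cell_type == ty]
    vapply(grid, function(g) mean(x <= g), numeric(1))
  })
  out <- matrix(out, nrow = length(grid), dimnames = list(NULL, types))
  rownames(out) <- format(grid)
  out
}
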