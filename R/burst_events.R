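# Burst-peak detection on the integrated, frame-aligned LFP, with the
# 0.8 x SD amplitude criterion and sigh flagging.

#' Detect rhythmic burst peaks in the integrated LFP
#'
#' The trace is detrended with a 10 s moving median; candidate peaks are
#' strict local maxima whose detrended value AND topographic prominence both
#' exceed `sd_factor` x SD(detrended). Peaks closer than `min_interval_s`
#' are resolved by keeping the larger. The prominence requirement (beyond
#' the bare amplitude criterion) stops noise ripples riding on a burst
#' shoulder from being counted as separate bursts.
#'
#' @param ilfp a `pbs_ilfp` from [resample_to_frames()]
#' @param sd_factor amplitude/prominence criterion (default 0.8)
#' @param min_interval_s minimum peak spacing in seconds (default 1)
#' @return data.frame of class `pbs_bursts`: id, peak_frame (1-based),
#'   peak_time_s, amplitude (detrended), is_sigh (FALSE until
#'   [flag_sighs()]), accepted
#' @export
detect_bursts <- function(ilfp, sd_factor = 0.8, min_interval_s = 1.0) {
  stopifnot(inherits(ilfp, "pbs_ilfp"))
  t <- ilfp$frame_times
  if (diff(range(t)) < 30) stop("recording shorter than 30 s")
  rate <- 1 / median(diff(t))
  det <- detrend_moving_median(ilfp$values, rate)
  sd_det <- ilfp$sd_detrended %||% sd(det)
  thr <- sd_factor * sd_det
  pk <- local_maxima(det)
  pk <- pk[det[pk] > thr]
  if (length(pk) > 0L) {
    pk <- pk[peak_prominence(det, pk) >= thr]
  }
  # enforce minimum spacing, larger peak wins
  if (length(pk) > 1L) {
    ord <- pk[order(-det[pk])]
    keep <- numeric(0)
    for (p in ord) {
      if (length(keep) == 0L || min(abs(t[keep] - t[p])) >= min_interval_s) {
        keep <- c(keep, p)
      }
    }
    pk <- sort(keep)
  }
  out <- data.frame(
    id = seq_along(pk),
    peak_frame = as.integer(pk),
    peak_time_s = t[pk],
    amplitude = det[pk],
    is_sigh = logical(length(pk)),
    accepted = rep(TRUE, length(pk))
  )
  class(out) <- c("pbs_bursts", "data.frame")
  attr(out, "sd_detrended") <- sd_det
  out
}

#' Flag sigh-like large-amplitude bursts
#'
#' A burst is a sigh when its amplitude exceeds `sigh_factor` x the median
#' amplitude of all detected bursts. Sighs keep their row but are marked
#' `accepted = FALSE` so sequence analysis skips them. With fewer than 3
#' events the median is unstable and nothing is flagged (with a warning).
#'
#' @param events a [detect_bursts()] result
#' @param sigh_factor multiple of the median amplitude (default 2)
#' @return `events` with is_sigh and accepted updated
#' @export
flag_sighs <- function(events, sigh_factor = 2.0) {
  if (nrow(events) < 3L) {
    warning("fewer than 3 bursts: sigh flagging skipped")
    return(events)
  }
  med <- median(events$amplitude)
  events$is_sigh <- events$amplitude > sigh_factor * med
  events$accepted <- events$accepted & !events$is_sigh
  events
}
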