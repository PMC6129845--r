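# Lagged normalized cross-correlation of every pixel against the integrated
# LFP, and placement of 7x7 ROIs on suprathreshold blobs.

#' Maximum lagged normalized cross-correlation between two series
#'
#' For each lag L in `lag_range`, the Pearson correlation between the
#' fluorescence series delayed by L frames and the LFP series is computed
#' over the overlapping stretch (`y[(L+1):N]` vs `x[1:(N-L)]`); the maximum
#' over lags and its argmax are returned. Positive lag means the fluorescence
#' lags the LFP (calcium is downstream of spiking). A zero-variance overlap
#' contributes correlation 0 at that lag. Ties take the smallest lag.
#'
#' @param x reference series (integrated LFP)
#' @param y probe series (fluorescence)
#' @param lag_range c(min, max) lag in frames, default c(0, 40)
#' @return list(maxcc, best_lag)
#' @export
normalized_xcorr_max <- function(x, y, lag_range = c(0L, 40L)) {
  n <- length(x)
  stopifnot(length(y) == n)
  lags <- lag_range[1L]:lag_range[2L]
  if (n <= max(lags) + 10L) stop("series too short for the requested lag range")
  cc <- vapply(lags, function(L) {
    a <- y[(L + 1L):n]
    b <- x[1L:(n - L)]
    if (sd(a) == 0 || sd(b) == 0) 0 else cor(a, b)
  }, numeric(1))
  i <- which.max(cc)
  list(maxcc = cc[i], best_lag = lags[i])
}

#' Per-pixel maxCC map of a filtered movie against the integrated LFP
#'
#' Vectorized over pixels: per lag, the overlap sums come from cumulative
#' sums along time and a single crossproduct, so the full map costs
#' O(lags x frames x pixels) flops with no per-pixel loop.
#'
#' @param fm a [filter_movie()] result
#' @param ilfp a `pbs_ilfp` from [resample_to_frames()]
#' @param lag_range c(min, max) lag in frames
#' @return object of class `pbs_cmap`: maxcc and best_lag matrices (height x
#'   width) plus lag_range
#' @export
correlation_image <- function(fm, ilfp, lag_range = c(0L, 40L)) {
  stopifnot(inherits(fm, "pbs_fmovie"), inherits(ilfp, "pbs_ilfp"))
  d <- dim(fm$data)
  n <- d[1L]
  if (length(ilfp$values) != n) stop("movie and integrated LFP lengths differ")
  p <- d[2L] * d[3L]
  X <- matrix(fm$data, n, p)
  y <- ilfp$values
  lags <- lag_range[1L]:lag_range[2L]
  best <- rep(-Inf, p)
  best_lag <- rep(lags[1L], p)
  eps <- 1e-12
  # suffix sums over the overlap window (L+1):n, updated incrementally per
  # lag so no cumulative-sum matrices are materialized
  sx <- colSums(X)
  sxx <- colSums(X^2)
  if (lags[1L] > 0L) for (L in seq_len(lags[1L])) {
    sx <- sx - X[L, ]
    sxx <- sxx - X[L, ]^2
  }
  ys1 <- c(0, cumsum(y))
  ys2 <- c(0, cumsum(y^2))
  first <- TRUE
  for (L in lags) {
    if (!first) {
      sx <- sx - X[L, ]
      sxx <- sxx - X[L, ]^2
    }
    first <- FALSE
    m <- n - L
    # sum over t of X[t+L, ] * y[t]  via a shifted copy of y
    ysh <- c(rep(0, L), y[seq_len(m)])
    sxy <- as.numeric(crossprod(X, ysh))
    sy <- ys1[m + 1L]
    syy <- ys2[m + 1L]
    vx <- sxx - sx^2 / m
    vy <- syy - sy^2 / m
    denom <- sqrt(pmax(vx, 0) * max(vy, 0))
    r <- ifelse(denom > eps, (sxy - sx * sy / m) / denom, 0)
    upd <- r > best
    best[upd] <- r[upd]
    best_lag[upd] <- L
  }
  structure(
    list(maxcc = matrix(best, d[2L], d[3L]),
         best_lag = matrix(best_lag, d[2L], d[3L]),
         lag_range = lag_range),
    class = "pbs_cmap"
  )
}

#' Detect functional ROIs from a correlation map
#'
#' Pixels with maxCC above `threshold` are grouped into 8-connected
#' components; components smaller than `min_area` pixels are dropped. Each
#' surviving component proposes its maxCC-peak pixel as an ROI center.
#' Candidates are accepted greedily in order of decreasing maxCC, rejecting
#' any within Chebyshev distance < 7 px of an accepted center (the ROI side
#' length), so 7x7 windows never overlap. Centers whose window would clip
#' the border are shifted inward by up to `half` px, else rejected. Each
#' accepted ROI's trace is the per-frame unweighted mean of its 7x7 window
#' of the filtered movie.
#'
#' @param cmap a [correlation_image()] result
#' @param threshold maxCC detection threshold (default 0.2)
#' @param fm the [filter_movie()] result the map came from
#' @param min_area minimum component area in pixels (default 9)
#' @param half ROI half-width (default 3, i.e. 7x7)
#' @return list with `table` (data.frame id, row, col, maxcc, best_lag;
#'   0-based pixel coordinates) and `traces` (frames x n_roi matrix)
#' @export
detect_rois <- function(cmap, threshold = 0.2, fm, min_area = 9L, half = 3L) {
  stopifnot(inherits(cmap, "pbs_cmap"), inherits(fm, "pbs_fmovie"))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0,1)")
  mk <- cmap$maxcc > threshold
  empty <- list(
    table = data.frame(id = integer(0), row = integer(0), col = integer(0),
                       maxcc = numeric(0), best_lag = integer(0)),
    traces = matrix(numeric(0), dim(fm$data)[1L], 0L)
  )
  if (!any(mk)) return(empty)
  lab <- EBImage::bwlabel(mk * 1)
  n_comp <- max(lab)
  h <- nrow(mk); w <- ncol(mk)
  # candidate centers: regional maxCC maxima inside sufficiently large
  # components (adjacent cells can merge into one suprathreshold blob, so a
  # single peak per component would undercount; the greedy non-overlap rule
  # below prunes duplicate peaks of the same cell)
  keep_comp <- which(tabulate(lab[lab > 0L], nbins = n_comp) >= min_area)
  if (length(keep_comp) == 0L) return(empty)
  is_peak <- matrix(TRUE, h, w)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    shifted <- matrix(-Inf, h, w)
    r_src <- max(1, 1 + dr):min(h, h + dr)
    c_src <- max(1, 1 + dc):min(w, w + dc)
    shifted[r_src - dr, c_src - dc] <- cmap$maxcc[r_src, c_src]
    is_peak <- is_peak & (cmap$maxcc >= shifted)
  }
  pk <- which(is_peak & matrix(lab %in% keep_comp, h, w))
  cand <- NULL
  for (peak in pk) {
    r0 <- (peak - 1L) %% h + 1L
    c0 <- (peak - 1L) %/% h + 1L
    # the maxCC blob is plateau-like across a soma, so the raw regional max
    # can sit a few px off the cell body; recenter on the suprathreshold-
    # weighted centroid of the plateau around the peak
    rr <- max(1L, r0 - half):min(h, r0 + half)
    cc <- max(1L, c0 - half):min(w, c0 + half)
    wts <- pmax(cmap$maxcc[rr, cc, drop = FALSE] - threshold, 0)
    if (sum(wts) > 0) {
      r0 <- as.integer(round(sum(rowSums(wts) * rr) / sum(wts)))
      c0 <- as.integer(round(sum(colSums(wts) * cc) / sum(wts)))
    }
    # shift window inward if it would clip, by at most `half`
    r <- min(max(r0, 1L + half), h - half)
    cl <- min(max(c0, 1L + half), w - half)
    if (abs(r - r0) > half || abs(cl - c0) > half) next
    cand <- rbind(cand, data.frame(row = r, col = cl, maxcc = cmap$maxcc[r0, c0],
                                   best_lag = cmap$best_lag[r0, c0]))
  }
  cand <- unique(cand)
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  cand <- cand[order(-cand$maxcc), , drop = FALSE]
  acc <- integer(0)
  for (i in seq_len(nrow(cand))) {
    if (length(acc) > 0L) {
      cheb <- pmax(abs(cand$row[acc] - cand$row[i]), abs(cand$col[acc] - cand$col[i]))
      if (min(cheb) < 2L * half + 1L) next
    }
    acc <- c(acc, i)
  }
  tab <- cand[acc, , drop = FALSE]
  tab <- tab[order(-tab$maxcc), , drop = FALSE]
  tab <- data.frame(id = seq_len(nrow(tab)),
                    row = tab$row - 1L, col = tab$col - 1L,   # 0-based out
                    maxcc = tab$maxcc, best_lag = tab$best_lag)
  traces <- roi_traces(fm, tab, half = half)
  list(table = tab, traces = traces)
}

#' Mean 7x7-window traces of ROIs from a filtered movie
#'
#' @param fm a [filter_movie()] result
#' @param tab data.frame with 0-based row, col ROI centers
#' @param half window half-width
#' @return frames x n_roi matrix
#' @export
roi_traces <- function(fm, tab, half = 3L) {
  d <- dim(fm$data)
  out <- matrix(0, d[1L], nrow(tab))
  for (i in seq_len(nrow(tab))) {
    r <- tab$row[i] + 1L
    cl <- tab$col[i] + 1L
    rr <- (r - half):(r + half)
    cc <- (cl - half):(cl + half)
    if (min(rr) < 1L || max(rr) > d[2L] || min(cc) < 1L || max(cc) > d[3L]) {
      stop("ROI window clips the image border")
    }
    win <- fm$data[, rr, cc, drop = FALSE]
    out[, i] <- rowMeans(matrix(win, d[1L], length(rr) * length(cc)))
  }
  out
}
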