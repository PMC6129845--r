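# Parameter-recovery scoring of a processed synthetic slice against its
# ground truth: ROI detection, regularity classification, burst detection
# and activation-timing recovery.

#' Score ROI detection against planted cells
#'
#' @param rois [detect_rois()] result
#' @param truth `pbs_truth` from [generate_recording()]
#' @param max_dist matching radius (Chebyshev pixels, default 2)
#' @return list: n_detected, n_planted (rhythmic cells), count_ratio,
#'   match_fraction (detected ROIs matched to a planted rhythmic cell within
#'   `max_dist`), matches (data.frame roi_id, truth_id, dist)
#' @export
eval_roi_recovery <- function(rois, truth, max_dist = 2) {
  rhythmic <- truth$cells[truth$cells$cell_type %in% CELL_TYPES, , drop = FALSE]
  m <- match_centers(rois$table[, c("row", "col")],
                     rhythmic[, c("row", "col")], max_dist = max_dist)
  n_det <- nrow(rois$table)
  list(
    n_detected = n_det,
    n_planted = nrow(rhythmic),
    count_ratio = n_det / nrow(rhythmic),
    match_fraction = if (n_det == 0L) 0 else nrow(m) / n_det,
    matches = data.frame(roi_id = rois$table$id[m$detected],
                         truth_id = rhythmic$id[m$truth], dist = m$dist)
  )
}

#' Score regularity classification against ground truth
#'
#' @param cells [classify_cells()] result
#' @param truth ground truth
#' @param matches match table from [eval_roi_recovery()]
#' @return list: accuracy, n_scored
#' @export
eval_regularity_recovery <- function(cells, truth, matches) {
  got <- cells$regularity[match(matches$roi_id, cells$id)]
  want <- truth$cells$regularity[match(matches$truth_id, truth$cells$id)]
  ok <- !is.na(want)
  list(accuracy = mean(got[ok] == want[ok]), n_scored = sum(ok))
}

#' Score burst detection against ground truth
#'
#' Accepted detected bursts are matched one-to-one to planted non-sigh
#' bursts within `tol_frames`.
#'
#' @param bursts [detect_bursts()]/[flag_sighs()] result
#' @param truth ground truth
#' @param rate_hz frame rate
#' @param tol_frames matching tolerance (default 2)
#' @return list: hit_rate (planted found), false_rate (detected unmatched),
#'   sigh_jaccard (flagged vs planted sighs), burst_match (data.frame)
#' @export
eval_burst_recovery <- function(bursts, truth, rate_hz, tol_frames = 2) {
  tol_s <- tol_frames / rate_hz
  planted <- truth$bursts[!truth$bursts$is_sigh, , drop = FALSE]
  acc <- bursts[bursts$accepted, , drop = FALSE]
  m <- match_centers(cbind(acc$peak_time_s, 0), cbind(planted$peak_time_s, 0),
                     max_dist = tol_s)
  # sigh agreement: match all detected to all planted, compare flags
  m_all <- match_centers(cbind(bursts$peak_time_s, 0),
                         cbind(truth$bursts$peak_time_s, 0), max_dist = tol_s)
  fl_det <- bursts$is_sigh[m_all$detected]
  fl_tru <- truth$bursts$is_sigh[m_all$truth]
  inter <- sum(fl_det & fl_tru)
  union <- sum(fl_det | fl_tru)
  list(
    hit_rate = nrow(m) / nrow(planted),
    false_rate = if (nrow(acc) == 0L) 0 else (nrow(acc) - nrow(m)) / nrow(acc),
    sigh_jaccard = if (union == 0L) 1 else inter / union,
    burst_match = data.frame(burst_id = acc$id[m$detected],
                             truth_burst = planted$id[m$truth])
  )
}

#' Score activation-timing recovery against ground truth
#'
#' Joins detected activations to true offsets over matched (cell, burst)
#' pairs and reports the correlation and the mean absolute error in frames.
#'
#' @param activations [detect_activations()] result
#' @param cells classified cells (for ROI id -> position)
#' @param bursts detected bursts
#' @param truth ground truth
#' @param rate_hz frame rate
#' @return list: r, mae_frames, n_pairs, pairs (data.frame with detected
#'   timing_s and true offset_s)
#' @export
eval_timing_recovery <- function(activations, cells, bursts, truth, rate_hz) {
  roi_m <- match_centers(cells[, c("row", "col")],
                         truth$cells[, c("row", "col")], max_dist = 2)
  cell_map <- setNames(truth$cells$id[roi_m$truth], cells$id[roi_m$detected])
  bm <- eval_burst_recovery(bursts, truth, rate_hz)$burst_match
  burst_map <- setNames(bm$truth_burst, bm$burst_id)
  a <- activations
  a$truth_cell <- cell_map[as.character(a$cell_id)]
  a$truth_burst <- burst_map[as.character(a$burst_id)]
  a <- a[!is.na(a$truth_cell) & !is.na(a$truth_burst), , drop = FALSE]
  key_a <- paste(a$truth_cell, a$truth_burst)
  key_t <- paste(truth$offsets$cell_id, truth$offsets$burst_id)
  i <- match(key_a, key_t)
  ok <- !is.na(i)
  pairs <- data.frame(timing_s = a$timing_s[ok],
                      offset_s = truth$offsets$offset_s[i[ok]])
  list(
    r = if (nrow(pairs) > 2L) cor(pairs$timing_s, pairs$offset_s) else NA_real_,
    mae_frames = mean(abs(pairs$timing_s - pairs$offset_s)) * rate_hz,
    n_pairs = nrow(pairs),
    pairs = pairs
  )
}
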