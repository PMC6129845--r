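# Regular/irregular discrimination by maxCC cutoff, marker-based type
# assignment, and the per-slice composition table.

#' Classify regularity from maxCC
#'
#' Regular strictly above the cutoff ("above the cut-off"), Irregular
#' otherwise (a cell exactly at the cutoff is Irregular).
#'
#' @param maxcc numeric vector of per-cell maxCC values
#' @param cutoff maxCC cutoff in (0,1)
#' @return character vector "Regular"/"Irregular"
#' @export
classify_regularity <- function(maxcc, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0,1)")
  ifelse(maxcc > cutoff, "Regular", "Irregular")
}

#' Suggest a maxCC cutoff by Otsu's method
#'
#' Maximizes the between-class variance over all candidate thresholds
#' (midpoints of the sorted sample), then clamps the result to
#' `[clamp[1], clamp[2]]` with a warning when clamping occurs — unimodal
#' maxCC samples otherwise produce arbitrary splits. In practice cutoffs are
#' expected around 0.4-0.7 depending on burst count, noise and recording
#' length, and a manual override is always available downstream.
#'
#' @param maxcc_values per-cell maxCC sample (>= 6 values)
#' @param clamp allowed cutoff interval (default c(0.40, 0.70))
#' @return cutoff value
#' @export
suggest_cutoff <- function(maxcc_values, clamp = c(0.40, 0.70)) {
  x <- sort(maxcc_values)
  n <- length(x)
  if (n < 6L) {
    stop("fewer than 6 cells: choose a cutoff manually (paper-range 0.47-0.64)")
  }
  cand <- (x[-n] + x[-1L]) / 2
  bcv <- vapply(cand, function(thr) {
    lo <- x[x <= thr]
    hi <- x[x > thr]
    if (length(lo) == 0L || length(hi) == 0L) return(-Inf)
    w0 <- length(lo) / n
    w1 <- 1 - w0
    w0 * w1 * (mean(lo) - mean(hi))^2
  }, numeric(1))
  thr <- cand[which.max(bcv)]
  if (thr < clamp[1L] || thr > clamp[2L]) {
    warning(sprintf(
      "Otsu cutoff %.3f outside [%.2f, %.2f]; clamped (sample may be unimodal)",
      thr, clamp[1L], clamp[2L]))
    thr <- min(max(thr, clamp[1L]), clamp[2L])
  }
  thr
}

#' Map marker flags and regularity to one of the five cell types
#'
#' (-,-,Regular) -> R-Ex; (+,-,Regular) -> R-Gly; (-,-,Irregular) -> Irr-Ex;
#' (+,-,Irregular) -> Irr-Gly; (+,+,Irregular) -> Irr-Cotrans. Combinations
#' never observed in tissue ((-,+) either regularity, and (+,+,Regular))
#' return "Unclassified" with a warning; such cells are retained in outputs
#' but excluded from five-type statistics.
#'
#' @param glyt2_pos,gad65_pos logical marker flags (vectorized)
#' @param regularity "Regular"/"Irregular" (vectorized)
#' @return character vector of cell types
#' @export
assign_cell_type <- function(glyt2_pos, gad65_pos, regularity) {
  n <- max(length(glyt2_pos), length(gad65_pos), length(regularity))
  glyt2_pos <- rep_len(glyt2_pos, n)
  gad65_pos <- rep_len(gad65_pos, n)
  regularity <- rep_len(regularity, n)
  reg <- regularity == "Regular"
  out <- rep("Unclassified", n)
  out[!glyt2_pos & !gad65_pos & reg] <- "R-Ex"
  out[glyt2_pos & !gad65_pos & reg] <- "R-Gly"
  out[!glyt2_pos & !gad65_pos & !reg] <- "Irr-Ex"
  out[glyt2_pos & !gad65_pos & !reg] <- "Irr-Gly"
  out[glyt2_pos & gad65_pos & !reg] <- "Irr-Cotrans"
  if (any(out == "Unclassified")) {
    warning(sum(out == "Unclassified"),
            " cell(s) with marker/regularity combinations not seen in tissue; ",
            "labelled Unclassified")
  }
  out
}

#' Classify all detected ROIs into cell records
#'
#' Combines marker flags from the unmixed reference stack with the
#' regular/irregular maxCC split into one record per cell.
#'
#' @param rois a [detect_rois()] result
#' @param flags data.frame from [fluorophore_flags()] (row per ROI)
#' @param cutoff maxCC cutoff; NULL to call [suggest_cutoff()] on the sample
#' @return data.frame: id, row, col, maxcc, best_lag, glyt2_pos, gad65_pos,
#'   regularity, cell_type, cutoff_used
#' @export
classify_cells <- function(rois, flags, cutoff = NULL) {
  tab <- rois$table
  stopifnot(nrow(tab) == nrow(flags))
  if (is.null(cutoff)) cutoff <- suggest_cutoff(tab$maxcc)
  reg <- classify_regularity(tab$maxcc, cutoff)
  ty <- assign_cell_type(flags$glyt2_pos, flags$gad65_pos, reg)
  cbind(tab, flags,
        data.frame(regularity = reg, cell_type = ty, cutoff_used = cutoff))
}

#' Per-slice cell-type composition table
#'
#' Counts per (slice, type) with a Total column, plus percentages
#' 100 * count / row_total rounded half-up to one decimal, and a Total row
#' summing the per-slice counts. Unclassified cells are excluded. An empty
#' slice yields a zero row and 0.0 percentages with a warning.
#'
#' @param cells data.frame with columns cell_type and (optionally) slice;
#'   absent slice column means a single slice "1"
#' @param slices optional character vector fixing slice order (and allowing
#'   empty slices)
#' @return list(counts, percentages): data.frames with columns slice,
#'   the five cell types, Total
#' @export
composition_table <- function(cells, slices = NULL) {
  if (!"slice" %in% names(cells)) cells$slice <- "1"
  cells <- cells[cells$cell_type %in% CELL_TYPES, , drop = FALSE]
  if (is.null(slices)) slices <- sort(unique(as.character(cells$slice)))
  if (length(slices) < 1L) stop("at least one slice required")
  cnt <- matrix(0L, length(slices), length(CELL_TYPES),
                dimnames = list(slices, CELL_TYPES))
  for (i in seq_along(slices)) {
    sub <- cells[as.character(cells$slice) == slices[i], , drop = FALSE]
    tb <- table(factor(sub$cell_type, levels = CELL_TYPES))
    cnt[i, ] <- as.integer(tb)
  }
  cnt <- rbind(cnt, Total = colSums(cnt))
  tot <- rowSums(cnt)
  pct <- matrix(0, nrow(cnt), ncol(cnt), dimnames = dimnames(cnt))
  for (i in seq_len(nrow(cnt))) {
    if (tot[i] == 0) {
      warning("slice '", rownames(cnt)[i], "' has no classified cells; percentages set to 0")
    } else {
      pct[i, ] <- round_half_up(100 * cnt[i, ] / tot[i], 1L)
    }
  }
  counts <- data.frame(slice = rownames(cnt), cnt, Total = tot,
                       check.names = FALSE, row.names = NULL)
  percentages <- data.frame(slice = rownames(cnt), pct,
                            Total = ifelse(tot == 0, 0, 100),
                            check.names = FALSE, row.names = NULL)
  list(counts = counts, percentages = percentages)
}
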