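# QC and summary figures (base graphics, PNG). These are review aids: the
# ROI overlay stands in for the visual double-checking step used with real
# recordings, and the summary panels mirror the standard presentation of
# sequence statistics (occupancy per rank bin, cumulative curves, leader
# fractions, mean timings).

TYPE_COLS <- c("R-Ex" = "#1b7837", "R-Gly" = "#2166ac", "Irr-Ex" = "#7fbf7b",
               "Irr-Gly" = "#67a9cf", "Irr-Cotrans" = "#e6ab02")

#' Write a QC overlay of detected ROIs on the maxCC map
#'
#' @param cmap a [correlation_image()] result
#' @param rois a [detect_rois()] result
#' @param path PNG output path
#' @param half ROI half-width (for the drawn boxes)
#' @return `path`, invisibly
#' @export
plot_roi_overlay <- function(cmap, rois, path, half = 3L) {
  h <- nrow(cmap$maxcc)
  w <- ncol(cmap$maxcc)
  grDevices::png(path, width = 640, height = 640)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(2, 2, 2, 1))
  graphics::image(seq_len(w) - 1L, seq_len(h) - 1L, t(cmap$maxcc[h:1, ]),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "", ylab = "", main = "maxCC map with accepted ROIs",
                  useRaster = TRUE)
  tab <- rois$table
  if (nrow(tab) > 0L) {
    y <- (h - 1L) - tab$row   # image() above flips rows
    graphics::rect(tab$col - half - 0.5, y - half - 0.5,
                   tab$col + half + 0.5, y + half + 0.5,
                   border = "red", lwd = 1.5)
    graphics::text(tab$col, y, labels = tab$id, col = "red", cex = 0.7, pos = 3)
  }
  invisible(path)
}

#' Write the four-panel sequence summary figure
#'
#' Panels: per-type occupancy across percent-rank bins (mean across slices),
#' per-type cumulative activation probability across bins, leader fractions,
#' and mean activation timing +/- SE.
#'
#' @param summ a [summarize_sequence()] result
#' @param path PNG output path
#' @return `path`, invisibly
#' @export
plot_summary <- function(summ, path) {
  grDevices::png(path, width = 900, height = 700)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  bins <- seq(10, 100, by = 100 / nrow(summ$occupancy$mean))
  occ <- summ$occupancy$mean
  graphics::matplot(bins, 100 * occ, type = "b", pch = 16, lty = 1,
                    col = TYPE_COLS[colnames(occ)],
                    xlab = "percent rank of activation order",
                    ylab = "% of activations in bin",
                    main = "occupancy by cell type")
  graphics::legend("topright", colnames(occ), col = TYPE_COLS[colnames(occ)],
                   lty = 1, pch = 16, cex = 0.7, bty = "n")
  cum <- summ$type_cumulative$mean
  graphics::matplot(bins, cum, type = "b", pch = 16, lty = 1,
                    col = TYPE_COLS[colnames(cum)],
                    xlab = "percent rank of activation order",
                    ylab = "cumulative activation probability",
                    main = "cumulative activation by type")
  lead <- summ$leader_fractions$mean
  graphics::barplot(100 * lead, col = TYPE_COLS[names(lead)], las = 2,
                    ylab = "% of cycles led", main = "first in sequence")
  mt <- summ$mean_timing$mean
  se <- summ$mean_timing$se
  bp <- graphics::barplot(1000 * mt, col = TYPE_COLS[names(mt)], las = 2,
                          ylab = "mean activation timing (ms)",
                          main = "mean timing vs LFP peak",
                          ylim = range(0, 1000 * (mt + 2 * se), na.rm = TRUE))
  ok <- is.finite(mt) & is.finite(se)
  graphics::arrows(bp[ok], 1000 * (mt[ok] - se[ok]),
                   bp[ok], 1000 * (mt[ok] + se[ok]),
                   angle = 90, code = 3, length = 0.04)
  invisible(path)
}
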