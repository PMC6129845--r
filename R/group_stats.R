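# Across-slice summaries of the activation sequence (occupancy per percent-
# rank bin, cumulative curves, leader and early-activation fractions, mean
# timings) and the statistical tests: one-way ANOVA with Tukey HSD on
# per-slice values, and pairwise two-sample Kolmogorov-Smirnov tests.

PR_BINS <- seq(0, 100, by = 10)

.bin_of <- function(pr, bin_percent = 10) {
  # bins (0,10], (10,20], ..., (90,100]
  pmin(ceiling(pr / bin_percent), 100 / bin_percent)
}

#' Per-slice sequence metrics
#'
#' Computes, for one slice: occupancy (fraction of each bin's activations
#' contributed by each type), per-type cumulative activation probability
#' across bins, leader fractions (type of the first activation per included
#' cycle), early fractions (cycles with >= 1 activation of the type at or
#' before -0.5 s and at or before 0 s, plus the pooled irregular Ex/Gly
#' pair), and per-type mean timing.
#'
#' @param ranked ranked activations of included cycles (from [build_cycles()]),
#'   with a cell_type column joined on
#' @param bin_percent percent-rank bin width (default 10)
#' @return list of per-slice metric tables
#' @export
slice_metrics <- function(ranked, bin_percent = 10) {
  nb <- 100 / bin_percent
  occ <- matrix(NA_real_, nb, length(CELL_TYPES),
                dimnames = list(paste0("(", PR_BINS[-length(PR_BINS)], ",",
                                       PR_BINS[-1L], "]"), CELL_TYPES))
  cum <- matrix(NA_real_, nb, length(CELL_TYPES), dimnames = dimnames(occ))
  if (nrow(ranked) > 0L) {
    b <- .bin_of(ranked$percent_rank, bin_percent)
    for (k in seq_len(nb)) {
      in_bin <- b == k
      tot <- sum(in_bin)
      if (tot > 0L) {
        occ[k, ] <- vapply(CELL_TYPES, function(ty)
          sum(in_bin & ranked$cell_type == ty) / tot, numeric(1))
      }
    }
    for (ty in CELL_TYPES) {
      sel <- ranked$cell_type == ty
      tot <- sum(sel)
      if (tot > 0L) {
        cnt <- vapply(seq_len(nb), function(k) sum(sel & b == k), numeric(1))
        cum[, ty] <- cumsum(cnt) / tot
      }
    }
  }
  cycles <- unique(ranked$burst_id)
  n_cyc <- length(cycles)
  leader <- setNames(numeric(length(CELL_TYPES)), CELL_TYPES)
  early_m05 <- leader; early_0 <- leader
  mean_timing <- setNames(rep(NA_real_, length(CELL_TYPES)), CELL_TYPES)
  if (n_cyc > 0L) {
    first <- ranked[ranked$rank == 1L, , drop = FALSE]
    for (ty in CELL_TYPES) {
      leader[ty] <- sum(first$cell_type == ty) / n_cyc
      early_m05[ty] <- sum(vapply(cycles, function(cy)
        any(ranked$burst_id == cy & ranked$cell_type == ty &
              ranked$timing_s <= -0.5), logical(1))) / n_cyc
      early_0[ty] <- sum(vapply(cycles, function(cy)
        any(ranked$burst_id == cy & ranked$cell_type == ty &
              ranked$timing_s <= 0), logical(1))) / n_cyc
      if (any(ranked$cell_type == ty)) {
        mean_timing[ty] <- mean(ranked$timing_s[ranked$cell_type == ty])
      }
    }
  }
  irr_pair <- ranked$cell_type %in% c("Irr-Ex", "Irr-Gly")
  early_pair <- c(
    before_0.5 = if (n_cyc == 0L) 0 else
      sum(vapply(cycles, function(cy)
        any(ranked$burst_id == cy & irr_pair & ranked$timing_s <= -0.5),
        logical(1))) / n_cyc,
    upto_0 = if (n_cyc == 0L) 0 else
      sum(vapply(cycles, function(cy)
        any(ranked$burst_id == cy & irr_pair & ranked$timing_s <= 0),
        logical(1))) / n_cyc
  )
  list(occupancy = occ, type_cumulative = cum, leader_fractions = leader,
       early_fractions = rbind(`-0.5s` = early_m05, `0s` = early_0),
       early_irr_pair = early_pair, mean_timing = mean_timing,
       n_cycles = n_cyc)
}

.mean_se <- function(mat_list, extract) {
  # stack a per-slice metric and return mean and SE (SD/sqrt(n)) across slices
  arr <- simplify2array(lapply(mat_list, extract))
  nd <- length(dim(arr))
  if (nd == 1L || is.null(dim(arr))) {
    arr <- matrix(arr, ncol = length(mat_list))
    nd <- 2L
  }
  n <- dim(arr)[nd]
  mean_v <- apply(arr, seq_len(nd - 1L), mean, na.rm = TRUE)
  sd_v <- apply(arr, seq_len(nd - 1L), sd, na.rm = TRUE)
  list(mean = mean_v, se = sd_v / sqrt(n))
}

#' Across-slice sequence summary
#'
#' Per-slice metrics are computed first ([slice_metrics()]), then averaged
#' across slices with SE = SD/sqrt(n_slices), the slice being the unit of
#' analysis. Slices with zero included cycles are dropped with a warning.
#'
#' @param ranked_by_slice named list (one element per slice) of ranked
#'   activation tables with cell_type columns
#' @param bin_percent percent-rank bin width
#' @return object of class `pbs_summary`: occupancy/type_cumulative/
#'   leader_fractions/early_fractions/mean_timing, each a list(mean, se);
#'   per_slice metrics; n_slices
#' @export
summarize_sequence <- function(ranked_by_slice, bin_percent = 10) {
  keep <- vapply(ranked_by_slice, function(r) nrow(r) > 0L, logical(1))
  if (any(!keep)) {
    warning("dropping ", sum(!keep), " slice(s) with zero included cycles")
  }
  ranked_by_slice <- ranked_by_slice[keep]
  if (length(ranked_by_slice) == 0L) stop("no slice with included cycles")
  per <- lapply(ranked_by_slice, slice_metrics, bin_percent = bin_percent)
  structure(
    list(
      occupancy = .mean_se(per, function(m) m$occupancy),
      type_cumulative = .mean_se(per, function(m) m$type_cumulative),
      leader_fractions = .mean_se(per, function(m) m$leader_fractions),
      early_fractions = .mean_se(per, function(m) m$early_fractions),
      early_irr_pair = .mean_se(per, function(m) m$early_irr_pair),
      mean_timing = .mean_se(per, function(m) m$mean_timing),
      per_slice = per,
      n_slices = length(per)
    ),
    class = "pbs_summary"
  )
}

#' One-way ANOVA with Tukey HSD across cell types
#'
#' Operates on per-slice summary values (the slice is the unit of analysis).
#'
#' @param values numeric vector of observations
#' @param groups factor/character of the same length
#' @param do_tukey compute Tukey HSD pairwise comparisons (default TRUE)
#' @return list: anova (data.frame test, statistic, p_value,
#'   significant_at_0.05), tukey (pairwise data.frame) or NULL
#' @export
anova_tukey <- function(values, groups, do_tukey = TRUE) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (any(table(groups) < 2L)) stop("every group needs >= 2 observations")
  wg <- tapply(values, groups, function(v) sum((v - mean(v))^2))
  if (all(wg == 0)) {
    gm <- tapply(values, groups, mean)
    if (max(gm) - min(gm) == 0) {
      # all observations identical: F = 0/0 -> no evidence of any difference
      an <- data.frame(test = "ANOVA", statistic = 0, p_value = 1,
                       significant_at_0.05 = FALSE)
      return(list(anova = an, tukey = NULL))
    }
    stop("zero within-group variance everywhere: ANOVA degenerate")
  }
  fit <- aov(values ~ groups)
  s <- summary(fit)[[1L]]
  an <- data.frame(test = "ANOVA", statistic = s$`F value`[1L],
                   p_value = s$`Pr(>F)`[1L],
                   significant_at_0.05 = s$`Pr(>F)`[1L] < 0.05)
  tk <- NULL
  if (do_tukey) {
    t0 <- TukeyHSD(fit)$groups
    tk <- data.frame(test = "TukeyHSD", pair = rownames(t0),
                     diff = t0[, "diff"], p_value = t0[, "p adj"],
                     significant_at_0.05 = t0[, "p adj"] < 0.05,
                     row.names = NULL)
  }
  list(anova = an, tukey = tk)
}

#' Pairwise two-sample Kolmogorov-Smirnov tests across cell types
#'
#' All pairs of the supplied samples are compared; pairs with a sample
#' smaller than `min_n` are skipped with a warning. No multiple-testing
#' correction is applied by default (raw pairwise p-values are reported);
#' `adjust = "holm"` is available.
#'
#' @param samples named list of numeric vectors (one per cell type)
#' @param min_n minimum sample size per group (default 5)
#' @param adjust p-value adjustment method ("none" or any [stats::p.adjust()]
#'   method)
#' @return data.frame: test, group1, group2, statistic (D), p_value,
#'   significant_at_0.05
#' @export
ks_pairwise <- function(samples, min_n = 5L, adjust = "none") {
  nm <- names(samples)
  stopifnot(!is.null(nm))
  out <- NULL
  for (i in seq_along(samples)) for (j in seq_along(samples)) {
    if (j <= i) next
    a <- samples[[i]]; b <- samples[[j]]
    if (length(a) < min_n || length(b) < min_n) {
      warning("skipping pair ", nm[i], " vs ", nm[j], ": sample too small")
      next
    }
    kt <- suppressWarnings(ks.test(a, b))
    out <- rbind(out, data.frame(test = "KS", group1 = nm[i], group2 = nm[j],
                                 statistic = unname(kt$statistic),
                                 p_value = kt$p.value))
  }
  if (is.null(out)) {
    return(data.frame(test = character(0), group1 = character(0),
                      group2 = character(0), statistic = numeric(0),
                      p_value = numeric(0), significant_at_0.05 = logical(0)))
  }
  if (adjust != "none") out$p_value <- stats::p.adjust(out$p_value, adjust)
  out$significant_at_0.05 <- out$p_value < 0.05
  out
}
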