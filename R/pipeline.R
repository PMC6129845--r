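# End-to-end orchestration: simulate (or load) -> unmix -> condition ->
# correlation map -> ROIs -> cell typing -> bursts -> activation sequence ->
# across-slice statistics, with the configuration serialized into the output
# directory for provenance.

#' Pipeline configuration
#'
#' All tunables of every stage in one validated list. Defaults are the
#' conventional printed parameter values of the method (band 0.025-1.5 Hz,
#' lag range 0-40 frames, maxCC threshold 0.2, burst criterion 0.8 x SD,
#' timing window +/- 24 frames, 50% cycle inclusion, 10% rank bins).
#'
#' @param band_hz movie band-pass (Hz)
#' @param lag_range maxCC lag search range (frames)
#' @param maxcc_threshold ROI detection threshold
#' @param cutoff regular/irregular maxCC cutoff; NA = automatic (Otsu)
#' @param tau_s LFP integrator time constant (s), conventionally 0.1-0.2
#' @param sd_factor burst amplitude criterion (x SD of detrended LFP)
#' @param min_interval_s minimum burst spacing (s)
#' @param sigh_factor sigh amplitude criterion (x median burst amplitude)
#' @param window_frames activation half-window (frames)
#' @param noise_k activation threshold (x inter-burst noise SD)
#' @param inclusion minimum activated fraction for cycle inclusion
#' @param bin_percent percent-rank bin width
#' @param n_slices number of slices (synthetic batch)
#' @param seed base seed; slice s simulates with seed + s - 1
#' @param save_movies write filtered movies as TIFF artifacts (large; off by
#'   default)
#' @return validated list of class `pbs_config`
#' @export
pipeline_config <- function(band_hz = c(0.025, 1.5),
                            lag_range = c(0L, 40L),
                            maxcc_threshold = 0.2,
                            cutoff = NA_real_,
                            tau_s = 0.15,
                            sd_factor = 0.8,
                            min_interval_s = 1.0,
                            sigh_factor = 2.0,
                            window_frames = 24L,
                            noise_k = 3.0,
                            inclusion = 0.5,
                            bin_percent = 10,
                            n_slices = 5L,
                            seed = 1L,
                            save_movies = FALSE) {
  cfg <- structure(as.list(environment()), class = "pbs_config")
  validate_pipeline_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#' @param cfg a `pbs_config` (or plain list with the same fields)
#' @return the config, invisibly; errors on any out-of-range value
#' @export
validate_pipeline_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("config error: ", msg)
  chk(cfg$band_hz[1L] > 0 && cfg$band_hz[1L] < cfg$band_hz[2L], "band_hz must be 0 < low < high")
  chk(cfg$maxcc_threshold > 0 && cfg$maxcc_threshold < 1, "maxcc_threshold must lie in (0,1)")
  chk(is.na(cfg$cutoff) || (cfg$cutoff > 0 && cfg$cutoff < 1), "cutoff must lie in (0,1) or NA")
  chk(cfg$tau_s > 0, "tau_s must be positive")
  chk(cfg$sd_factor > 0, "sd_factor must be positive")
  chk(cfg$window_frames >= 1, "window_frames must be >= 1")
  chk(cfg$inclusion > 0 && cfg$inclusion <= 1, "inclusion must lie in (0,1]")
  chk(cfg$bin_percent > 0 && 100 %% cfg$bin_percent == 0, "bin_percent must divide 100")
  chk(cfg$lag_range[1L] >= 0 && cfg$lag_range[2L] > cfg$lag_range[1L], "lag_range invalid")
  chk(cfg$n_slices >= 1, "n_slices must be >= 1")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with any subset of [pipeline_config()] fields
#' @return validated `pbs_config`
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0L) stop("config error: unknown field(s): ",
                                 paste(unknown, collapse = ", "))
  do.call(pipeline_config, y)
}

#' Process one slice (recording) through every analysis stage
#'
#' @param rec list with movie, stack, lfp (and optionally truth), e.g. from
#'   [generate_recording()]
#' @param cfg a [pipeline_config()]
#' @return list: ilfp, fmovie, cmap, rois, unmix, cells, bursts, activations,
#'   cycles, ranked (ranked activations with cell_type joined)
#' @export
process_slice <- function(rec, cfg = pipeline_config()) {
  validate_pipeline_config(cfg)
  ilfp <- condition_lfp(rec$lfp, rec$movie, tau_s = cfg$tau_s)
  fm <- filter_movie(rec$movie, band_hz = cfg$band_hz)
  cmap <- correlation_image(fm, ilfp, lag_range = cfg$lag_range)
  rois <- detect_rois(cmap, threshold = cfg$maxcc_threshold, fm = fm)
  um <- unmix(rec$stack, seed = cfg$seed)
  if (nrow(rois$table) > 0L) {
    flags <- fluorophore_flags(um, rois$table[, c("row", "col")])
  } else {
    flags <- data.frame(glyt2_pos = logical(0), gad65_pos = logical(0))
  }
  cutoff <- if (is.na(cfg$cutoff)) NULL else cfg$cutoff
  cells <- classify_cells(rois, flags, cutoff = cutoff)
  bursts <- flag_sighs(detect_bursts(ilfp, sd_factor = cfg$sd_factor,
                                     min_interval_s = cfg$min_interval_s),
                       sigh_factor = cfg$sigh_factor)
  insp <- cells$cell_type %in% CELL_TYPES
  rate <- rec$movie$sampling_rate_hz
  acts <- detect_activations(rois$traces[, insp, drop = FALSE], bursts, rate,
                             window_frames = cfg$window_frames,
                             noise_k = cfg$noise_k,
                             cell_ids = cells$id[insp])
  cyc <- build_cycles(acts, sum(insp), bursts, inclusion = cfg$inclusion)
  ranked <- cyc$ranked
  ranked$cell_type <- cells$cell_type[match(ranked$cell_id, cells$id)]
  list(ilfp = ilfp, fmovie = fm, cmap = cmap, rois = rois, unmix = um,
       cells = cells, bursts = bursts, activations = acts,
       cycles = cyc$cycles, ranked = ranked)
}

#' Run the full multi-slice synthetic pipeline
#'
#' Simulates `cfg$n_slices` recordings (slice s with generator seed
#' `cfg$seed + s - 1`), processes each through [process_slice()], pools the
#' across-slice summary and tests, and writes all result tables, the summary
#' JSON and the serialized configuration into `out_dir`. Rerunning with an
#' identical configuration is bit-identical.
#'
#' @param cfg a [pipeline_config()]
#' @param out_dir output directory (created); NULL skips all file output
#' @param synth_cfg a [synth_config()] template for the generator (its seed
#'   field is overridden per slice); default [default_paper_like_config()]
#' @param keep_slices return the full per-slice stage objects (memory-heavy;
#'   default FALSE keeps only tables)
#' @return list of class `pbs_run`: cells, composition, bursts, activations,
#'   summary, anova_timing, tukey_timing, ks_timing, per_slice (tables),
#'   out_dir
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir = NULL,
                         synth_cfg = default_paper_like_config(),
                         keep_slices = FALSE) {
  validate_pipeline_config(cfg)
  slices <- vector("list", cfg$n_slices)
  cells_all <- NULL
  acts_all <- NULL
  bursts_all <- NULL
  ranked_by_slice <- list()
  for (s in seq_len(cfg$n_slices)) {
    scfg <- synth_cfg
    scfg$seed <- as.integer(cfg$seed + s - 1L)
    rec <- generate_recording(scfg)
    res <- process_slice(rec, cfg)
    label <- as.character(s)
    if (!is.null(out_dir)) {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      plot_roi_overlay(res$cmap, res$rois,
                       file.path(out_dir, sprintf("qc_rois_slice%s.png", label)))
      if (cfg$save_movies) {
        write_movie(rec$movie, file.path(out_dir, sprintf("movie_slice%s.tiff", label)))
      }
    }
    cells_s <- cbind(slice = label, res$cells)
    cells_all <- rbind(cells_all, cells_s)
    acts_s <- if (nrow(res$ranked) > 0L) cbind(slice = label, res$ranked) else NULL
    acts_all <- rbind(acts_all, acts_s)
    bursts_all <- rbind(bursts_all, cbind(slice = label, as.data.frame(res$bursts)))
    ranked_by_slice[[label]] <- res$ranked
    slices[[s]] <- if (keep_slices) c(res, list(truth = rec$truth)) else
      list(cells = res$cells, cycles = res$cycles, ranked = res$ranked,
           bursts = as.data.frame(res$bursts), truth = rec$truth)
    rm(rec)
  }
  comp <- composition_table(cells_all)
  summ <- summarize_sequence(ranked_by_slice, bin_percent = cfg$bin_percent)
  # per-slice mean timing per type -> ANOVA/Tukey across types
  mt <- do.call(rbind, lapply(names(summ$per_slice), function(s) {
    data.frame(slice = s, cell_type = CELL_TYPES,
               mean_timing = unname(summ$per_slice[[s]]$mean_timing))
  }))
  mt <- mt[is.finite(mt$mean_timing), , drop = FALSE]
  aov_res <- tryCatch(
    anova_tukey(mt$mean_timing, mt$cell_type),
    error = function(e) list(anova = NULL, tukey = NULL)
  )
  ks_res <- if (!is.null(acts_all)) {
    ks_pairwise(split(acts_all$timing_s, acts_all$cell_type)[
      intersect(CELL_TYPES, unique(acts_all$cell_type))])
  } else NULL
  run <- structure(
    list(cells = cells_all, composition = comp, bursts = bursts_all,
         activations = acts_all, summary = summ,
         anova_timing = aov_res$anova, tukey_timing = aov_res$tukey,
         ks_timing = ks_res, per_slice = slices, cfg = cfg,
         out_dir = out_dir),
    class = "pbs_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write the artifact set of a pipeline run
#' @param run a `pbs_run` from [run_pipeline()]
#' @param out_dir output directory
#' @return named vector of written paths, invisibly
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- write_results_tables(run$cells, run$activations %||%
                                  data.frame(cell_id = integer(0),
                                             burst_id = integer(0),
                                             timing_s = numeric(0)),
                                run$composition, out_dir)
  data.table::fwrite(run$bursts, file.path(out_dir, "bursts.csv"))
  if (!is.null(run$ks_timing)) {
    data.table::fwrite(run$ks_timing, file.path(out_dir, "tests.csv"))
  }
  mt <- run$summary$mean_timing
  data.table::fwrite(
    data.frame(cell_type = names(mt$mean), mean_timing_s = unname(mt$mean),
               se_s = unname(mt$se)),
    file.path(out_dir, "summary.csv"))
  plot_summary(run$summary, file.path(out_dir, "summary_panels.png"))
  yaml::write_yaml(unclass(run$cfg), file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(n_slices = run$summary$n_slices,
         n_cells = nrow(run$cells),
         mean_timing_s = as.list(mt$mean),
         leader_fractions = as.list(run$summary$leader_fractions$mean)),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
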