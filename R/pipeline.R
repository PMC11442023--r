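op_log <- function(quiet, ...) if (!quiet) message(sprintf(...))

#' Movie-level preprocessing
#'
#' Optional 3x3 spatial mean filtering (edge pixels average their available
#' neighbours) applied frame-wise, and polarity normalization.  Per-trace
#' baseline correction is available through [preprocess()].
#'
#' @param movie a `movie_stack`.
#' @param spatial_filter apply the 3x3 spatial mean.
#' @return a `movie_stack`, polarity `"upright"`.
#' @export
preprocess_movie <- function(movie, spatial_filter = FALSE) {
  stopifnot(inherits(movie, "movie_stack"))
  nr <- movie$nrow; nc <- movie$ncol
  for (ch in names(movie$channels)) {
    X <- movie$channels[[ch]]
    if (movie$polarity == "inverted") {
      rng <- range(X, finite = TRUE)
      X <- (rng[1] + rng[2]) - X
    }
    if (spatial_filter) {
      acc <- X
      cnt <- matrix(1, nrow(X), ncol(X))
      # neighbour offsets in column-major pixel indexing
      px_row <- rep(seq_len(nr), nc)
      px_col <- rep(seq_len(nc), each = nr)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        src_r <- px_row - dr; src_c <- px_col - dc
        ok <- src_r >= 1 & src_r <= nr & src_c >= 1 & src_c <= nc
        src <- (src_c - 1) * nr + src_r
        acc[ok, ] <- acc[ok, ] + X[src[ok], ]
        cnt[ok, ] <- cnt[ok, ] + 1
      }
      X <- acc / cnt
    }
    movie$channels[[ch]] <- X
  }
  movie$polarity <- "upright"
  movie
}

region_mean <- function(map, mask) {
  v <- map[mask]
  if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
}

#' Whole-heart SNS APD80 shortening on synthetic data
#'
#' Reproduces the sinus-rhythm SNS measurement: a pre-stimulation baseline
#' segment and a segment covering the end of a 60-s stimulation are
#' synthesized for the given group, per-pixel APD80 maps are built from each,
#' and the tissue-mean APD80 difference is returned.
#'
#' @param group `"sham"` or `"mi"`.
#' @param seed integer seed (the two segments derive distinct streams).
#' @param grid pixel grid.
#' @param baseline_s baseline segment duration (s).
#' @param sns_window_s protocol-clock window, near the 60-s plateau, whose
#'   beats are measured (s since SNS onset).
#' @param ... further overrides for [sim_preset()] / [movie_config()].
#' @return a list with `baseline_ms`, `sns_ms`, `shortening_ms`
#'   (baseline - SNS, positive = shortening) and the true generator
#'   shortening `true_shortening_ms` at the window midpoint.
#' @export
measure_sns_apd_shortening <- function(group, seed, grid = c(100, 100),
                                       baseline_s = 2.4,
                                       sns_window_s = c(58, 60), ...) {
  base_cfg <- sim_preset(group, "sinus", seed = seed, grid = grid,
                         duration_s = baseline_s, channels = "vm", ...)
  base <- generate_movie(base_cfg)
  maps_b <- build_maps(base$movie, "vm")
  tis_b <- tissue_mask(maps_b$snr)
  apd_b <- region_mean(maps_b$apd80, tis_b)

  t_rec <- c(sns_window_s[1] - 1.2, sns_window_s[2])
  sns_cfg <- sim_preset(group, "sns", seed = seed + 10007L, grid = grid,
                        duration_s = diff(t_rec), t_start_s = t_rec[1],
                        channels = "vm", ...)
  sns <- generate_movie(sns_cfg)
  maps_s <- build_maps(sns$movie, "vm", time_range_s = sns_window_s)
  tis_s <- tissue_mask(maps_s$snr)
  apd_s <- region_mean(maps_s$apd80, tis_s)

  tmid <- mean(sns_window_s)
  true_s <- mean(true_metric_map(sns$truth, "apd80", 0)) -
    mean(true_metric_map(sns$truth, "apd80", tmid))
  list(baseline_ms = apd_b, sns_ms = apd_s,
       shortening_ms = apd_b - apd_s, true_shortening_ms = true_s)
}

#' Whole-heart isoproterenol CaTD80 percent change on synthetic data
#'
#' Baseline sinus segment versus a post-onset isoproterenol segment;
#' tissue-mean CaTD80 percent change, the beta-adrenergic responsiveness
#' readout.
#'
#' @inheritParams measure_sns_apd_shortening
#' @param segment_s duration of each segment (s).
#' @param iso_t_start_s protocol-clock start of the isoproterenol segment (s
#'   after onset; any positive value, the response is a step).
#' @return a list with `baseline_ms`, `iso_ms` and `pct_change`
#'   (100 x (iso - baseline) / baseline, negative = shortening).
#' @export
measure_iso_catd_change <- function(group, seed, grid = c(100, 100),
                                    segment_s = 2.8, iso_t_start_s = 30,
                                    ...) {
  base_cfg <- sim_preset(group, "sinus", seed = seed, grid = grid,
                         duration_s = segment_s, channels = "ca", ...)
  base <- generate_movie(base_cfg)
  maps_b <- build_maps(base$movie, "ca")
  tis_b <- tissue_mask(maps_b$snr)
  catd_b <- region_mean(maps_b$catd80, tis_b)

  iso_cfg <- sim_preset(group, "iso", seed = seed + 20011L, grid = grid,
                        duration_s = segment_s, t_start_s = iso_t_start_s,
                        channels = "ca", ...)
  iso <- generate_movie(iso_cfg)
  maps_i <- build_maps(iso$movie, "ca")
  tis_i <- tissue_mask(maps_i$snr)
  catd_i <- region_mean(maps_i$catd80, tis_i)

  list(baseline_ms = catd_b, iso_ms = catd_i,
       pct_change = 100 * (catd_i - catd_b) / catd_b)
}

#' Infarct-mask recovery against ground truth on synthetic data
#'
#' Synthesizes an MI movie, segments the infarct by the SNR band and
#' rise-time criteria, and scores the mask against the generator's true
#' infarct disc.
#'
#' @param seed integer seed.
#' @param grid pixel grid.
#' @param duration_s recording duration (s).
#' @param config an [analysis_config()].
#' @param ... overrides for [sim_preset()].
#' @return a list with `jaccard`, `precision`, `recall`, and the masks.
#' @export
measure_infarct_recovery <- function(seed, grid = c(100, 100),
                                     duration_s = 2.4,
                                     config = analysis_config(), ...) {
  sim <- generate_movie(sim_preset("mi", "sinus", seed = seed, grid = grid,
                                   duration_s = duration_s,
                                   channels = "vm", ...))
  maps <- build_maps(sim$movie, "vm", aggregate = config$aggregate)
  tis <- tissue_mask(maps$snr, config$snr_min, config$min_component_px)
  inf <- infarct_mask(maps$snr, maps$trise, config$snr_band,
                      config$rise_threshold_ms, config$snr_criterion,
                      tissue = tis,
                      min_component_px = config$min_component_px)
  c(mask_overlap(inf, sim$truth$infarct_mask),
    list(infarct = inf, tissue = tis, truth = sim$truth$infarct_mask))
}

#' Run the full synthetic analysis pipeline for one heart
#'
#' Chains simulate, analyze, segment and summarize: synthesizes rate-matched
#' paced recordings (baseline and, at the SNS plateau, stimulated), builds
#' voltage and calcium metric maps, segments tissue/infarct/remote regions
#' from the baseline maps (sham hearts use the anatomical ROIs), computes
#' regional means and APD dispersion per condition, and returns the
#' long-format results table.  With `out_dir` set, maps (32-bit TIFF), masks
#' (8-bit TIFF) and `results.csv` are written; outputs are bit-reproducible
#' from (configuration, seed).
#'
#' @param group `"sham"` or `"mi"`.
#' @param seed integer seed.
#' @param grid pixel grid.
#' @param conditions subset of `c("baseline", "sns")`.
#' @param segment_s duration of each synthesized segment (s).
#' @param config an [analysis_config()].
#' @param out_dir optional output directory.
#' @param heart_id identifier written to the table.
#' @param quiet suppress per-stage log messages.
#' @return the results data.frame (invisibly when `out_dir` is set).
#' @export
run_pipeline <- function(group, seed, grid = c(100, 100),
                         conditions = c("baseline", "sns"), segment_s = 2.4,
                         config = analysis_config(), out_dir = NULL,
                         heart_id = paste0(group, "_", seed),
                         quiet = FALSE) {
  stopifnot(inherits(config, "analysis_config"))
  rows <- list()
  maps_by_cond <- list()
  prot_name <- "paced"
  for (cond in conditions) {
    stim <- if (cond == "sns") "sns" else "none"
    t0 <- if (cond == "sns") config$sns_duration_s - segment_s else 0
    cfg <- sim_preset(group, prot_name, seed = seed +
                        1000L * match(cond, conditions),
                      grid = grid, duration_s = segment_s, t_start_s = t0)
    cfg$protocol$stim <- stim
    cfg$protocol$pcl_ms <- config$pcl_ms
    op_log(quiet, "[simulate] %s %s: %gs paced at PCL %g ms (stim %s)",
           heart_id, cond, segment_s, config$pcl_ms, stim)
    sim <- generate_movie(cfg)
    movie <- preprocess_movie(sim$movie, config$spatial_filter)
    m <- list(vm = build_maps(movie, "vm", aggregate = config$aggregate),
              ca = build_maps(movie, "ca", aggregate = config$aggregate))
    op_log(quiet, "[analyze] %s %s: %d beats, %d/%d pixels measured",
           heart_id, cond, m$vm$n_beats, sum(!is.na(m$vm$apd80)),
           length(m$vm$apd80))
    maps_by_cond[[cond]] <- m
  }

  base_maps <- maps_by_cond[[conditions[1]]]
  tis <- tissue_mask(base_maps$vm$snr, config$snr_min,
                     config$min_component_px)
  inf <- infarct_mask(base_maps$vm$snr, base_maps$vm$trise, config$snr_band,
                      config$rise_threshold_ms, config$snr_criterion,
                      tissue = tis, min_component_px = config$min_component_px)
  roi <- sham_rois(grid, size_px = round(0.07 * prod(grid)),
                   base = config$base)
  if (sum(inf) == 0) inf <- roi$infarct & tis
  rem <- remote_mask(tis, inf, config$exclusion_px, config$base,
                     sham_roi = roi)
  op_log(quiet, "[segment] %s: tissue %d px, infarct %d px, remote %d px",
         heart_id, sum(tis), sum(inf), sum(rem))

  regions <- list(whole = tis, remote = rem, infarct = inf)
  pitch <- 0.31
  for (cond in conditions) {
    m <- maps_by_cond[[cond]]
    for (rg in names(regions)) {
      rows[[length(rows) + 1]] <- data.frame(
        heart_id = heart_id, group = group, region = rg, condition = cond,
        metric = c("apd80", "catd80", "trise", "snr"),
        value = c(region_mean(m$vm$apd80, regions[[rg]]),
                  region_mean(m$ca$catd80, regions[[rg]]),
                  region_mean(m$vm$trise, regions[[rg]]),
                  region_mean(m$vm$snr, regions[[rg]])),
        unit = c("ms", "ms", "ms", "ratio"))
    }
    disp <- apd_dispersion(m$vm$apd80, tis, pitch)
    rows[[length(rows) + 1]] <- data.frame(
      heart_id = heart_id, group = group, region = "whole",
      condition = cond, metric = "apd_dispersion",
      value = disp$dispersion, unit = "ms/cm2")
  }
  results <- do.call(rbind, rows)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (cond in conditions) {
      m <- maps_by_cond[[cond]]
      write_metric_map(m$vm$apd80, file.path(out_dir,
        sprintf("apd80_%s.tif", cond)))
      write_metric_map(m$ca$catd80, file.path(out_dir,
        sprintf("catd80_%s.tif", cond)))
      write_metric_map(m$vm$snr, file.path(out_dir,
        sprintf("snr_%s.tif", cond)), unit = "ratio")
      write_metric_map(m$vm$trise, file.path(out_dir,
        sprintf("trise_%s.tif", cond)))
    }
    write_mask(tis, file.path(out_dir, "tissue.tif"))
    write_mask(inf, file.path(out_dir, "infarct.tif"))
    write_mask(rem, file.path(out_dir, "remote.tif"))
    write_results(results, file.path(out_dir, "results.csv"))
    op_log(quiet, "[write] %s: results and maps in %s", heart_id, out_dir)
    return(invisible(results))
  }
  results
}
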