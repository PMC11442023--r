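format_error <- function(field, msg) {
  stop("movie format error in '", field, "': ", msg, call. = FALSE)
}

# scale a matrix to [0,1] for the TIFF writer, returning the transform
norm_for_tiff <- function(x) {
  rng <- range(x, finite = TRUE)
  scale <- if (rng[2] > rng[1]) rng[2] - rng[1] else 1
  list(data = (x - rng[1]) / scale, offset = rng[1], scale = scale)
}

#' Write / read a movie as multi-frame TIFF + JSON sidecar
#'
#' One 32-bit TIFF stack per channel (`<name>_vm.tif`, `<name>_ca.tif`)
#' holding frames scaled to `[0, 1]`, plus `<name>.json` with the per-channel
#' offset/scale and all acquisition metadata (sampling rate, pixel pitch,
#' polarity, protocol, protocol-clock start, seed, stimulus times).  The
#' round trip restores data exactly up to the writer's 32-bit quantization
#' (1 part in 2^32 - 1, relative error ~2e-10) and metadata losslessly.
#'
#' @param movie a `movie_stack`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return `write_movie` returns the sidecar path invisibly; `read_movie`
#'   returns a `movie_stack`.
#' @export
write_movie <- function(movie, dir, name = "movie") {
  stopifnot(inherits(movie, "movie_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- list(nrow = movie$nrow, ncol = movie$ncol,
               n_frames = ncol(movie$channels[[1]]),
               sampling_rate_hz = movie$sampling_rate_hz,
               pixel_pitch_mm = movie$pixel_pitch_mm,
               polarity = movie$polarity,
               t_start_s = movie$t_start_s, seed = movie$seed,
               protocol = unclass(movie$protocol),
               stim_times_ms = movie$stim_times_ms,
               channels = list())
  for (ch in names(movie$channels)) {
    nm <- norm_for_tiff(movie$channels[[ch]])
    frames <- lapply(seq_len(ncol(nm$data)), function(t)
      matrix(nm$data[, t], movie$nrow, movie$ncol))
    f <- file.path(dir, paste0(name, "_", ch, ".tif"))
    tiff::writeTIFF(frames, f, bits.per.sample = 32L)
    meta$channels[[ch]] <- list(file = basename(f), offset = nm$offset,
                                scale = nm$scale)
  }
  side <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(side)
}

#' @rdname write_movie
#' @param path the JSON sidecar path written by `write_movie`.
#' @export
read_movie <- function(path) {
  if (!file.exists(path)) stop("no such sidecar: ", path, call. = FALSE)
  meta <- jsonlite::read_json(path)
  for (f in c("nrow", "ncol", "n_frames", "sampling_rate_hz",
              "pixel_pitch_mm", "polarity", "t_start_s", "channels"))
    if (is.null(meta[[f]])) format_error(f, "missing required field")
  if (meta$sampling_rate_hz <= 0)
    format_error("sampling_rate_hz", "must be positive")
  chans <- list()
  nfr <- integer()
  for (ch in names(meta$channels)) {
    info <- meta$channels[[ch]]
    frames <- tiff::readTIFF(file.path(dirname(path), info$file), all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    nfr[ch] <- length(frames)
    X <- vapply(frames, as.vector, numeric(meta$nrow * meta$ncol))
    if (nrow(X) != meta$nrow * meta$ncol)
      format_error(ch, "frame shape does not match nrow x ncol")
    chans[[ch]] <- X * info$scale + info$offset
  }
  if (length(unique(nfr)) > 1)
    format_error("channels", sprintf("unequal frame counts (%s)",
                                     paste(nfr, collapse = " vs ")))
  if (any(nfr != meta$n_frames))
    format_error("n_frames", "sidecar frame count does not match TIFF")
  prot <- do.call(protocol, meta$protocol[c("mode", "pcl_ms", "stim",
                                            "onset_s")])
  structure(list(channels = chans, nrow = meta$nrow, ncol = meta$ncol,
                 sampling_rate_hz = meta$sampling_rate_hz,
                 pixel_pitch_mm = meta$pixel_pitch_mm,
                 polarity = meta$polarity, protocol = prot,
                 t_start_s = meta$t_start_s,
                 seed = meta$seed,
                 stim_times_ms = if (length(meta$stim_times_ms))
                   unlist(meta$stim_times_ms) else NULL),
            class = "movie_stack")
}

#' Write / read a metric map as 32-bit TIFF + JSON sidecar
#'
#' Missing pixels are encoded as a reserved value below the data range and
#' restored to `NA` on reading.
#'
#' @param map numeric matrix (may contain `NA`).
#' @param path TIFF output path; the sidecar is `<path>.json`.
#' @param unit unit label stored in the sidecar.
#' @return `write_metric_map` returns `path` invisibly; `read_metric_map` the
#'   matrix with a `"unit"` attribute.
#' @export
write_metric_map <- function(map, path, unit = "ms") {
  vals <- map
  finite <- is.finite(vals)
  rng <- if (any(finite)) range(vals[finite]) else c(0, 1)
  na_code <- rng[1] - 0.05 * max(rng[2] - rng[1], 1)
  vals[!finite] <- na_code
  nm <- norm_for_tiff(vals)
  tiff::writeTIFF(matrix(nm$data, nrow(map), ncol(map)), path,
                  bits.per.sample = 32L)
  jsonlite::write_json(list(nrow = nrow(map), ncol = ncol(map), unit = unit,
                            offset = nm$offset, scale = nm$scale,
                            na_code = na_code),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metric_map
#' @export
read_metric_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"))
  x <- tiff::readTIFF(path) * meta$scale + meta$offset
  x[abs(x - meta$na_code) <= 1e-6 * meta$scale] <- NA
  attr(x, "unit") <- meta$unit
  x
}

#' Write / read a region mask as 8-bit TIFF (0/255)
#'
#' @param mask logical matrix.
#' @param path TIFF path.
#' @return `write_mask` returns `path` invisibly; `read_mask` a logical
#'   matrix.
#' @export
write_mask <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path,
                  bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) tiff::readTIFF(path) > 0.5

#' Analysis configuration
#'
#' All segmentation and measurement conventions in one validated list, with
#' the study's criteria as defaults: SNR tissue floor 5, infarct SNR band
#' [5, 10], rise-time threshold 15 ms (strict), minimum component 10 px,
#' remote exclusion 10 px, pacing cycle length 200 ms, SNS duration 60 s.
#'
#' @param snr_min tissue SNR floor.
#' @param snr_band inclusive infarct SNR band.
#' @param rise_threshold_ms strict infarct rise-time threshold (ms).
#' @param snr_criterion `"band_5_10"` or `"below_15"`.
#' @param min_component_px,exclusion_px segmentation sizes (px).
#' @param aggregate beat aggregation for [build_maps()].
#' @param baseline_correct,spatial_filter preprocessing switches.
#' @param pcl_ms pacing cycle length (ms).
#' @param sns_duration_s SNS duration (s).
#' @param base base-of-heart image edge.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(snr_min = 5, snr_band = c(5, 10),
                            rise_threshold_ms = 15,
                            snr_criterion = "band_5_10",
                            min_component_px = 10, exclusion_px = 10,
                            aggregate = "ensemble",
                            baseline_correct = FALSE, spatial_filter = FALSE,
                            pcl_ms = 200, sns_duration_s = 60,
                            base = "top") {
  if (snr_min <= 0 || rise_threshold_ms <= 0 || min_component_px < 0 ||
      exclusion_px < 0 || pcl_ms <= 0 || sns_duration_s <= 0)
    stop("thresholds must be positive", call. = FALSE)
  if (snr_band[1] > snr_band[2])
    stop("snr_band low must be <= high", call. = FALSE)
  structure(list(snr_min = snr_min, snr_band = snr_band,
                 rise_threshold_ms = rise_threshold_ms,
                 snr_criterion = snr_criterion,
                 min_component_px = min_component_px,
                 exclusion_px = exclusion_px, aggregate = aggregate,
                 baseline_correct = baseline_correct,
                 spatial_filter = spatial_filter, pcl_ms = pcl_ms,
                 sns_duration_s = sns_duration_s, base = base),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_config <- function(path) {
  do.call(analysis_config, yaml::read_yaml(path))
}

#' Write / read a long-format results table
#'
#' CSV with header `heart_id, group, region, condition, metric, value, unit`;
#' one record per (heart, region, condition, metric).
#'
#' @param results a data.frame with those columns.
#' @param path CSV path.
#' @return `write_results` returns `path` invisibly; `read_results` the
#'   data.frame.
#' @export
write_results <- function(results, path) {
  need <- c("heart_id", "group", "region", "condition", "metric", "value",
            "unit")
  stopifnot(all(need %in% names(results)))
  utils::write.csv(results[, need], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
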