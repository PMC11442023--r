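#' Infarct geometry for the synthetic movie generator
#'
#' The infarct is a disc in pixel coordinates.  Inside the disc the beat
#' amplitude is scaled by `snr_scale` (depressing SNR), the upstroke is slowed
#' by `rise_slow_factor`, and the APD80 is offset by `apd_offset_ms`.  A border
#' zone of width `border_px` blends all parameters linearly from infarct values
#' to remote values (blend weights are quantized to 1/32 steps, which also
#' keeps the number of distinct waveforms small).  `sns_response_scale` scales
#' the SNS-driven APD shortening inside the infarct relative to remote
#' myocardium, producing the SNS-driven rise in APD dispersion seen in
#' infarcted hearts.
#'
#' @param center_px infarct disc center, `c(row, col)` (1-based pixels).
#' @param radius_px disc radius in pixels (0 = no infarct core).
#' @param snr_scale multiplicative amplitude attenuation in (0, 1].
#' @param rise_slow_factor multiplicative upstroke slowing, >= 1.
#' @param apd_offset_ms APD80 offset of infarct relative to remote (ms).
#' @param border_px border-zone annulus width (pixels).
#' @param sns_response_scale infarct SNS APD-response scale relative to remote.
#' @return an object of class `infarct_geometry`.
#' @export
infarct_geometry <- function(center_px = c(75, 50), radius_px = 15,
                             snr_scale = 0.225, rise_slow_factor = 4,
                             apd_offset_ms = 10, border_px = 3,
                             sns_response_scale = 0.6) {
  if (radius_px < 0) stop("'radius_px' must be >= 0", call. = FALSE)
  if (snr_scale <= 0 || snr_scale > 1)
    stop("'snr_scale' must be in (0, 1]", call. = FALSE)
  if (rise_slow_factor < 1)
    stop("'rise_slow_factor' must be >= 1", call. = FALSE)
  if (border_px < 0) stop("'border_px' must be >= 0", call. = FALSE)
  structure(list(center_px = center_px, radius_px = radius_px,
                 snr_scale = snr_scale, rise_slow_factor = rise_slow_factor,
                 apd_offset_ms = apd_offset_ms, border_px = border_px,
                 sns_response_scale = sns_response_scale),
            class = "infarct_geometry")
}

#' Protocol description for a synthetic recording
#'
#' @param mode `"sinus"` (rate set by the modulation model) or `"paced"`
#'   (fixed pacing cycle length).
#' @param pcl_ms pacing cycle length in ms (paced mode).
#' @param stim `"none"`, `"sns"` (sympathetic nerve stimulation) or `"iso"`
#'   (isoproterenol step).
#' @param onset_s stimulus onset on the protocol clock (s); the protocol
#'   clock starts at 0 with the first beat.
#' @return a list of class `protocol`.
#' @export
protocol <- function(mode = c("sinus", "paced"), pcl_ms = 200,
                     stim = c("none", "sns", "iso"), onset_s = 0) {
  mode <- match.arg(mode)
  stim <- match.arg(stim)
  if (pcl_ms <= 0) stop("'pcl_ms' must be positive", call. = FALSE)
  structure(list(mode = mode, pcl_ms = pcl_ms, stim = stim,
                 onset_s = onset_s), class = "protocol")
}

#' Configuration for a synthetic dual-dye movie
#'
#' Defaults follow the acquisition used throughout: 1 kHz sampling, a
#' 31 mm x 31 mm field of view on a 100 x 100 pixel grid (0.31 mm pitch).
#' The generated movie records the protocol-clock interval
#' `[t_start_s, t_start_s + duration_s)`, so steady-state or late-stimulation
#' segments can be produced without simulating the full run.
#'
#' @param grid `c(nrow, ncol)` pixel grid.
#' @param sampling_rate_hz frame rate (Hz).
#' @param pixel_pitch_mm pixel pitch (mm).
#' @param duration_s recorded duration (s).
#' @param t_start_s protocol-clock time of the first frame (s).
#' @param vm,ca [waveform_params()] for the voltage and Ca2+ channels.
#' @param modulation a [modulation_model()].
#' @param infarct an [infarct_geometry()] or `NULL` for a homogeneous heart.
#' @param noise_sd additive i.i.d. Gaussian noise SD per pixel-frame
#'   (fluorescence units).
#' @param protocol a [protocol()].
#' @param channels channels to synthesize, subset of `c("vm", "ca")`.
#' @param drift_per_s optional linear baseline drift (units/s; photobleaching
#'   surrogate), 0 by default.
#' @param polarity `"upright"` (depolarization increases signal) or
#'   `"inverted"`.
#' @param seed integer RNG seed (required: movies are reproducible).
#' @return an object of class `movie_config`.
#' @export
movie_config <- function(grid = c(100, 100), sampling_rate_hz = 1000,
                         pixel_pitch_mm = 0.31, duration_s = 2,
                         t_start_s = 0,
                         vm = waveform_params(apd80_ms = 180,
                                              upstroke_rise_ms = 5,
                                              repol_shape = 12),
                         ca = waveform_params(apd80_ms = 240,
                                              upstroke_rise_ms = 12,
                                              repol_shape = 18),
                         modulation = modulation_model(),
                         infarct = NULL, noise_sd = 0.03,
                         protocol = optimap::protocol(),
                         channels = c("vm", "ca"),
                         drift_per_s = 0,
                         polarity = c("upright", "inverted"),
                         seed) {
  if (missing(seed) || !is.finite(seed))
    stop("'seed' is required: synthetic movies must be reproducible",
         call. = FALSE)
  if (sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be positive", call. = FALSE)
  if (duration_s <= 0) stop("'duration_s' must be positive", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  channels <- match.arg(channels, several.ok = TRUE)
  polarity <- match.arg(polarity)
  stopifnot(inherits(vm, "waveform_params"), inherits(ca, "waveform_params"),
            inherits(modulation, "modulation_model"),
            inherits(protocol, "protocol"),
            is.null(infarct) || inherits(infarct, "infarct_geometry"))
  structure(list(grid = as.integer(grid), sampling_rate_hz = sampling_rate_hz,
                 pixel_pitch_mm = pixel_pitch_mm, duration_s = duration_s,
                 t_start_s = t_start_s, vm = vm, ca = ca,
                 modulation = modulation, infarct = infarct,
                 noise_sd = noise_sd, protocol = protocol,
                 channels = channels, drift_per_s = drift_per_s,
                 polarity = polarity, seed = as.integer(seed)),
            class = "movie_config")
}

#' Preset movie configurations for the study groups
#'
#' `"sham"` has no infarct and the sham SNS APD response (-30.7 ms at 60 s of
#' SNS, whole heart) and isoproterenol CaTD80 response (-33.04%).  `"mi"` has
#' an apical infarct disc (reduced SNR, slowed upstroke, +10 ms APD offset,
#' attenuated SNS response) with the MI whole-heart responses (-24.3 ms SNS
#' APD shortening, -42.60% CaTD80 with isoproterenol).  The infarct scales
#' with the grid: center at 75% of rows / 50% of columns, radius 15% of the
#' smaller grid dimension.
#'
#' @param group `"sham"` or `"mi"`.
#' @param protocol_name `"sinus"`, `"paced"`, `"sns"` (sinus + SNS at t = 0)
#'   or `"iso"` (sinus + isoproterenol step at t = 0).
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [movie_config()].
#' @return a `movie_config`.
#' @export
sim_preset <- function(group = c("sham", "mi"),
                       protocol_name = c("sinus", "paced", "sns", "iso"),
                       seed, ...) {
  group <- match.arg(group)
  protocol_name <- match.arg(protocol_name)
  mod <- modulation_model(
    apd_sns_delta_ms = if (group == "mi") -24.3 else -30.7,
    catd_iso_pct = if (group == "mi") -42.60 else -33.04)
  prot <- switch(protocol_name,
                 sinus = protocol("sinus", stim = "none"),
                 paced = protocol("paced", pcl_ms = 200, stim = "none"),
                 sns = protocol("sinus", stim = "sns", onset_s = 0),
                 iso = protocol("sinus", stim = "iso", onset_s = 0))
  dots <- list(...)
  grid <- if (!is.null(dots$grid)) dots$grid else c(100, 100)
  inf <- if (group == "mi")
    infarct_geometry(center_px = round(c(0.75 * grid[1], 0.5 * grid[2])),
                     radius_px = round(0.15 * min(grid)))
  else NULL
  movie_config(modulation = mod, infarct = inf, protocol = prot,
               seed = seed, ...)
}

# Blend-weight map: 1 inside the disc, linear to 0 across the border annulus,
# quantized to 1/32 steps.  Warns when the disc is clipped by the grid.
infarct_weight_map <- function(grid, infarct) {
  if (is.null(infarct) || infarct$radius_px <= 0)
    return(matrix(0, grid[1], grid[2]))
  r0 <- infarct$center_px[1]
  c0 <- infarct$center_px[2]
  R <- infarct$radius_px
  b <- max(infarct$border_px, .Machine$double.eps)
  if (r0 - R < 1 || r0 + R > grid[1] || c0 - R < 1 || c0 + R > grid[2])
    warning("infarct disc extends beyond the pixel grid; clipped",
            call. = FALSE)
  d <- sqrt(outer((seq_len(grid[1]) - r0)^2,
                  (seq_len(grid[2]) - c0)^2, `+`))
  w <- pmin(pmax((R + infarct$border_px - d) / b, 0), 1)
  round(w * 32) / 32
}

# Beat activation times (ms, protocol clock) covering [from_ms, to_ms].
beat_schedule <- function(cfg, from_ms, to_ms) {
  prot <- cfg$protocol
  if (prot$mode == "paced") {
    acts <- seq(0, to_ms, by = prot$pcl_ms)
  } else {
    tg <- seq(0, to_ms + 2000, by = 1)  # 1 ms grid
    if (prot$stim == "sns") {
      hr <- sns_modulation(pmax(tg / 1000 - prot$onset_s, 0),
                           cfg$modulation)$hr_bpm
    } else {
      hr <- rep(cfg$modulation$hr_baseline_bpm, length(tg))
    }
    cum <- (cumsum(hr) - hr) / 60000  # beats elapsed up to each grid point
    nb <- floor(cum[length(cum)])
    acts <- c(0, stats::approx(cum, tg, xout = seq_len(nb), ties = "ordered")$y)
  }
  acts[acts >= from_ms & acts <= to_ms]
}

# Per-beat duration for every pixel group, honoring the stimulus model.
# `base_dur` is the per-group baseline duration; `sns_scale` the per-group
# regional response scale; returns a length(base_dur) vector.
beat_duration <- function(t_act_ms, base_dur, channel, cfg, sns_scale,
                          delta_remote_ms) {
  prot <- cfg$protocol
  m <- cfg$modulation
  ts <- t_act_ms / 1000
  if (prot$stim == "sns" && channel == "vm") {
    frac <- min(max(ts - prot$onset_s, 0) / m$sns_plateau_s, 1)
    base_dur + delta_remote_ms * frac * sns_scale
  } else if (prot$stim == "iso" && ts >= prot$onset_s) {
    pct <- if (channel == "vm") m$apd_iso_pct else m$catd_iso_pct
    base_dur * (1 + pct / 100)
  } else {
    base_dur
  }
}

#' Generate a synthetic dual-dye optical mapping movie with ground truth
#'
#' Deterministic for a fixed seed.  Pixels are grouped by their (quantized)
#' infarct blend weight, so each frame grid carries at most a few dozen
#' distinct noiseless waveforms; additive i.i.d. Gaussian noise of SD
#' `noise_sd` is then applied per pixel-frame.
#'
#' @param cfg a [movie_config()].
#' @return a list with elements `movie` (a `movie_stack`: per-channel
#'   pixel-by-frame matrices in column-major pixel order plus acquisition
#'   metadata) and `truth` (a `ground_truth`: per-pixel true baseline APD80 /
#'   CaTD80 / rise-time / SNR maps, infarct and tissue masks, beat activation
#'   times, and the resolved stimulus-response fields needed to evaluate the
#'   true maps at any protocol time, see [true_metric_map()]).
#' @export
generate_movie <- function(cfg) {
  stopifnot(inherits(cfg, "movie_config"))
  set.seed(cfg$seed)
  nr <- cfg$grid[1]; nc <- cfg$grid[2]
  npix <- nr * nc
  dt <- 1000 / cfg$sampling_rate_hz
  t0 <- cfg$t_start_s * 1000
  nT <- round(cfg$duration_s * 1000 / dt)
  tms <- t0 + (seq_len(nT) - 1) * dt

  w_map <- infarct_weight_map(cfg$grid, cfg$infarct)
  w <- as.vector(w_map)
  inf <- if (is.null(cfg$infarct)) infarct_geometry(radius_px = 0) else
    cfg$infarct
  uw <- sort(unique(w))
  groups <- lapply(uw, function(u) which(w == u))

  sns_scale_u <- 1 + (inf$sns_response_scale - 1) * uw
  # remote delta resolved so the whole-heart mean delta equals the model value
  sns_scale_all <- 1 + (inf$sns_response_scale - 1) * w
  delta_remote <- cfg$modulation$apd_sns_delta_ms / mean(sns_scale_all)

  # latest-starting beat that can still overlap the recorded interval
  lead_ms <- 1.5 * max(cfg$vm$apd80_ms, cfg$ca$apd80_ms) + 300
  acts <- beat_schedule(cfg, t0 - lead_ms, t0 + nT * dt + 1)

  # rate adaptation under pacing: durations scale by (pcl / rr0)^alpha and
  # saturate at 75% of the cycle length (the transient must return to
  # diastole before the next stimulus)
  pace_scale <- 1
  dur_cap <- Inf
  if (cfg$protocol$mode == "paced") {
    rr0 <- 60000 / cfg$modulation$hr_baseline_bpm
    pace_scale <- min(1, (cfg$protocol$pcl_ms / rr0) ^
                        cfg$modulation$pacing_apd_exponent)
    dur_cap <- 0.75 * cfg$protocol$pcl_ms
  }

  chans <- list()
  for (ch in cfg$channels) {
    p <- cfg[[ch]]
    amp_u <- p$amplitude * (1 - (1 - inf$snr_scale) * uw)
    # upstroke slowing is an action-potential phenotype; Ca2+ transients in
    # the scar keep their rise but lose amplitude
    rise_u <- if (ch == "vm")
      p$upstroke_rise_ms * (1 + (inf$rise_slow_factor - 1) * uw)
    else rep(p$upstroke_rise_ms, length(uw))
    dur_u <- pmin(pace_scale *
      (p$apd80_ms + if (ch == "vm") inf$apd_offset_ms * uw
       else numeric(length(uw))), dur_cap)
    sig <- matrix(p$baseline, npix, nT)
    for (gi in seq_along(uw)) {
      tr <- numeric(nT)
      for (a in acts) {
        d <- beat_duration(a, dur_u[gi], ch, cfg, sns_scale_u[gi],
                           delta_remote)
        lo <- a - 3 * rise_u[gi] - 2
        hi <- a + d + 10 * p$repol_shape
        j <- which(tms >= lo & tms <= hi)
        if (length(j))
          tr[j] <- tr[j] + beat_shape(tms[j], a, d, rise_u[gi],
                                      p$repol_shape)
      }
      sig[groups[[gi]], ] <- matrix(p$baseline + amp_u[gi] * tr,
                                    length(groups[[gi]]), nT, byrow = TRUE)
    }
    if (cfg$noise_sd > 0)
      sig <- sig + matrix(stats::rnorm(npix * nT, 0, cfg$noise_sd), npix, nT)
    if (cfg$drift_per_s != 0)
      sig <- sig + matrix(cfg$drift_per_s * (tms - t0) / 1000, npix, nT,
                          byrow = TRUE)
    if (cfg$polarity == "inverted") {
      rng <- range(sig)
      sig <- (rng[1] + rng[2]) - sig
    }
    chans[[ch]] <- sig
  }

  movie <- structure(list(
    channels = chans, nrow = nr, ncol = nc,
    sampling_rate_hz = cfg$sampling_rate_hz,
    pixel_pitch_mm = cfg$pixel_pitch_mm,
    polarity = cfg$polarity, protocol = cfg$protocol,
    t_start_s = cfg$t_start_s, seed = cfg$seed,
    stim_times_ms = if (cfg$protocol$mode == "paced")
      acts[acts >= t0 & acts < t0 + nT * dt] else NULL),
    class = "movie_stack")

  # per-pixel infarct values
  amp_map <- matrix(cfg$vm$amplitude * (1 - (1 - inf$snr_scale) * w), nr, nc)
  truth <- structure(list(
    apd80_map = matrix(pmin(pace_scale *
      (cfg$vm$apd80_ms + inf$apd_offset_ms * w), dur_cap), nr, nc),
    catd80_map = matrix(pmin(pace_scale * cfg$ca$apd80_ms, dur_cap), nr, nc),
    rise_map = matrix(cfg$vm$upstroke_rise_ms *
                        (1 + (inf$rise_slow_factor - 1) * w), nr, nc),
    snr_map = if (cfg$noise_sd > 0) amp_map / cfg$noise_sd else
      matrix(Inf, nr, nc),
    amplitude_map = amp_map,
    infarct_mask = suppressWarnings(infarct_weight_map(cfg$grid,
      if (is.null(cfg$infarct)) NULL else {
        g <- cfg$infarct; g$border_px <- 0; g
      })) >= 1,   # clip warning already raised for the movie itself
    tissue_mask = matrix(TRUE, nr, nc),
    activation_times_ms = acts[acts >= t0 & acts < t0 + nT * dt],
    sns_response_map = matrix(sns_scale_all, nr, nc),
    apd_sns_delta_remote_ms = delta_remote,
    modulation = cfg$modulation, protocol = cfg$protocol,
    grid = cfg$grid), class = "ground_truth")

  list(movie = movie, truth = truth)
}

#' True metric map at a given protocol time
#'
#' Evaluates the generator's noiseless per-pixel APD80 or CaTD80 at protocol
#' time `t_s`, applying the SNS ramp (with its regional response scaling) or
#' the isoproterenol step exactly as the generator does.
#'
#' @param truth a `ground_truth` from [generate_movie()].
#' @param metric `"apd80"` or `"catd80"`.
#' @param t_s protocol-clock time (s).
#' @return a matrix (ms).
#' @export
true_metric_map <- function(truth, metric = c("apd80", "catd80"), t_s = 0) {
  metric <- match.arg(metric)
  base <- if (metric == "apd80") truth$apd80_map else truth$catd80_map
  prot <- truth$protocol
  m <- truth$modulation
  if (prot$stim == "sns" && metric == "apd80") {
    frac <- min(max(t_s - prot$onset_s, 0) / m$sns_plateau_s, 1)
    base + truth$apd_sns_delta_remote_ms * frac * truth$sns_response_map
  } else if (prot$stim == "iso" && t_s >= prot$onset_s) {
    pct <- if (metric == "apd80") m$apd_iso_pct else m$catd_iso_pct
    base * (1 + pct / 100)
  } else {
    base
  }
}

#' @export
print.movie_stack <- function(x, ...) {
  cat(sprintf("<movie_stack> %d x %d px, %d frames @ %g Hz, channels: %s\n",
              x$nrow, x$ncol, ncol(x$channels[[1]]), x$sampling_rate_hz,
              paste(names(x$channels), collapse = ", ")))
  cat(sprintf("  protocol: %s / stim %s; t_start %g s; polarity %s\n",
              x$protocol$mode, x$protocol$stim, x$t_start_s, x$polarity))
  invisible(x)
}

#' Extract one pixel's trace from a movie
#'
#' @param movie a `movie_stack`.
#' @param row,col pixel coordinates (1-based).
#' @param channel `"vm"` or `"ca"`.
#' @return a [pixel_trace()].
#' @export
movie_trace <- function(movie, row, col, channel = "vm") {
  stopifnot(inherits(movie, "movie_stack"))
  p <- (col - 1) * movie$nrow + row
  pixel_trace(movie$channels[[channel]][p, ],
              sampling_rate_hz = movie$sampling_rate_hz,
              polarity = movie$polarity)
}
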