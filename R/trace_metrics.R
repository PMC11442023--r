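#' A single-pixel fluorescence trace
#'
#' @param samples numeric vector of fluorescence samples (>= 2, finite values
#'   expected; non-finite samples propagate as missing metrics downstream).
#' @param sampling_rate_hz sampling rate (Hz).
#' @param polarity `"upright"` (depolarization increases signal) or
#'   `"inverted"` (e.g. raw RH237 voltage fluorescence).
#' @return an object of class `pixel_trace`.
#' @export
pixel_trace <- function(samples, sampling_rate_hz = 1000,
                        polarity = c("upright", "inverted")) {
  polarity <- match.arg(polarity)
  samples <- as.numeric(samples)
  if (length(samples) < 2) stop("a trace needs >= 2 samples", call. = FALSE)
  if (sampling_rate_hz <= 0)
    stop("'sampling_rate_hz' must be positive", call. = FALSE)
  structure(list(samples = samples, sampling_rate_hz = sampling_rate_hz,
                 polarity = polarity), class = "pixel_trace")
}

# running mean / min with window k (centered, edges truncated)
runmean <- function(x, k) {
  n <- length(x)
  if (k <= 1 || n <= 4) return(x)
  k <- min(k, n)
  cs <- cumsum(c(0, x))
  half <- k %/% 2
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

runmin <- function(x, k) {
  n <- length(x)
  half <- min(k %/% 2, n)
  out <- x
  for (s in seq_len(half)) {
    out <- pmin(out, c(x[-seq_len(s)], rep(x[n], s)))
    out <- pmin(out, c(rep(x[1], s), x[seq_len(n - s)]))
  }
  out
}

# Linear interpolation time (ms, origin = first sample) of the first upward
# crossing of `level` in v[1..imax]; NA if none (0 if already above at start).
cross_up_first <- function(v, level, imax, dt) {
  if (v[1] >= level) return(0)
  i <- which(v[2:imax] >= level & v[seq_len(imax - 1)] < level)
  if (!length(i)) return(NA_real_)
  i <- i[1] + 1
  (i - 2 + (level - v[i - 1]) / (v[i] - v[i - 1])) * dt
}

# Last upward crossing of `level` before sample `imax`, ignoring re-crossings
# that follow excursions shallower than `hyst` (noise dips are not notches).
cross_up_last <- function(v, level, imax, dt, hyst = 0) {
  if (imax < 2) return(if (v[1] >= level) 0 else NA_real_)
  i <- which(v[2:imax] >= level & v[seq_len(imax - 1)] < level) + 1
  if (!length(i)) return(if (v[1] >= level) 0 else NA_real_)
  pick <- i[1]
  if (length(i) > 1) {
    for (j in i[-1])
      if (min(v[pick:j]) < level - hyst) pick <- j
  }
  (pick - 2 + (level - v[pick - 1]) / (v[pick] - v[pick - 1])) * dt
}

# index of the maximum with tolerant tie-breaking to the earliest candidate
# (exact grid ties survive tiny contamination, e.g. a previous beat's tail)
argmax_tol <- function(d, rtol = 1e-4) {
  m <- max(d)
  which(d >= m - rtol * abs(m) - 1e-12)[1]
}

na_beat <- function() {
  list(baseline = NA_real_, amplitude = NA_real_, activation_ms = NA_real_,
       trise_ms = NA_real_, dur80_ms = NA_real_, peak_ms = NA_real_)
}

# last index j <= ipk with v[j] <= level (the upstroke "foot"); 1 if none
upstroke_foot <- function(v, level, ipk) {
  below <- which(v[seq_len(ipk)] <= level)
  if (!length(below)) 1L else below[length(below)]
}

# Core beat measurement on one beat-window slice `v` (times relative to the
# window start).  Conventions:
#  * the upstroke spans from the "foot" (last sample at or below baseline +
#    5% of amplitude before the peak) to the peak; crossings are searched
#    only there, so diastolic noise cannot produce spurious early crossings;
#  * activation = maximum forward difference on the upstroke; ties broken to
#    the earliest pair and reported at the later sample of the pair;
#  * baseline = mean of a pre-upstroke diastolic window ending 2 rise times
#    (at least 6 ms) before activation, reaching back at most 60 ms; when the
#    window has no room, the minimum of the smoothed pre-peak segment is used;
#  * rise time = first 10% to last 90% upward crossing on the upstroke,
#    linearly interpolated;
#  * duration80 = first post-peak downward crossing of baseline + 0.2 x
#    amplitude (linear interpolation) minus activation time; NA when the
#    signal does not return below that level within the window.
measure_beat <- function(v, dt) {
  if (any(!is.finite(v))) return(na_beat())
  n <- length(v)
  ipk <- which.max(v)
  if (ipk < 2 || n < 3) return(na_beat())
  pre <- v[seq_len(ipk - 1)]
  b0 <- if (length(pre) <= 4) min(pre) else min(runmean(pre, 5))
  amp0 <- v[ipk] - b0
  if (amp0 <= 0) return(na_beat())

  # provisional upstroke / rise to place the baseline window
  f0 <- upstroke_foot(v, b0 + 0.05 * amp0, ipk)
  if (f0 >= ipk) f0 <- ipk - 1L
  iact0 <- f0 + argmax_tol(diff(v[f0:ipk]))
  up0 <- v[f0:ipk]
  t10 <- cross_up_first(up0, b0 + 0.1 * amp0, length(up0), dt)
  t90 <- cross_up_last(up0, b0 + 0.9 * amp0, length(up0), dt,
                       hyst = 0.1 * amp0)
  rise0 <- if (is.na(t10) || is.na(t90)) 2 * dt else max(t90 - t10, dt)

  jhi <- iact0 - max(ceiling(6 / dt), ceiling(2 * rise0 / dt))
  jlo <- max(1L, iact0 - ceiling(60 / dt))
  b <- if (jhi - jlo >= 3) mean(v[jlo:jhi]) else b0
  amp <- v[ipk] - b
  if (amp <= 0) return(na_beat())

  foot <- upstroke_foot(v, b + 0.05 * amp, ipk)
  if (foot >= ipk) foot <- ipk - 1L
  d <- diff(v[foot:ipk])
  iact <- foot + argmax_tol(d)       # earliest tie, later sample of the pair
  act_ms <- (iact - 1) * dt
  up <- v[foot:ipk]
  t10 <- cross_up_first(up, b + 0.1 * amp, length(up), dt)
  t90 <- cross_up_last(up, b + 0.9 * amp, length(up), dt,
                       hyst = 0.1 * amp)
  trise <- if (is.na(t10) || is.na(t90) || t90 < t10) NA_real_ else t90 - t10

  th <- b + 0.2 * amp
  post <- v[ipk:n]
  dur <- NA_real_
  if (length(post) >= 2) {
    i <- which(post[-1] < th & post[-length(post)] >= th)
    if (length(i)) {
      i <- i[1] + 1
      tc <- (ipk - 1 + i - 2 +
               (post[i - 1] - th) / (post[i - 1] - post[i])) * dt
      dur <- tc - act_ms
    }
  }
  list(baseline = b, amplitude = amp, activation_ms = act_ms,
       trise_ms = trise, dur80_ms = dur, peak_ms = (ipk - 1) * dt)
}

#' Condition a pixel trace
#'
#' Normalizes polarity to upright (reflection about the sample mid-range,
#' an exact involution) and optionally removes slow baseline drift: beats are
#' detected on a rolling-minimum-detrended copy, a diastolic anchor point is
#' taken just before each upstroke, and the piecewise-linear baseline through
#' the anchors is subtracted (exact for linear drift).
#'
#' With all options off an upright trace passes through unchanged.  A constant
#' trace passes through and is flagged zero-amplitude downstream (empty beat
#' set, missing metrics).
#'
#' @param trace a [pixel_trace()].
#' @param polarity_normalize flip inverted traces upright (default TRUE).
#' @param baseline_correct subtract the diastolic baseline (default FALSE).
#' @param baseline_win_ms rolling-minimum window for drift-tolerant beat
#'   detection (ms); must exceed the longest diastolic gap.
#' @return a `pixel_trace`, polarity `"upright"`.
#' @export
preprocess <- function(trace, polarity_normalize = TRUE,
                       baseline_correct = FALSE, baseline_win_ms = 300) {
  stopifnot(inherits(trace, "pixel_trace"))
  x <- trace$samples
  if (polarity_normalize && trace$polarity == "inverted")
    x <- (max(x) + min(x)) - x
  dt <- 1000 / trace$sampling_rate_hz
  if (baseline_correct) {
    k <- max(3, round(baseline_win_ms / dt))
    det <- x - runmin(x, k)
    beats <- segment_beats(pixel_trace(det, trace$sampling_rate_hz))
    if (nrow(beats) >= 1) {
      node_i <- node_v <- numeric(nrow(beats))
      for (b in seq_len(nrow(beats))) {
        hi <- max(beats$start_idx[b],
                  beats$act_idx[b] - ceiling(6 / dt))
        seg <- beats$start_idx[b]:hi
        j <- seg[which.min(det[seg])]
        node_i[b] <- j
        node_v[b] <- stats::median(x[max(1, j - 2):min(length(x), j + 2)])
      }
      base <- stats::approx(node_i, node_v, xout = seq_along(x),
                            rule = 2, ties = "ordered")$y
      x <- x - base
    }
  }
  pixel_trace(x, trace$sampling_rate_hz, "upright")
}

#' Segment a trace into beat windows
#'
#' One window per suprathreshold depolarization: upward crossings of
#' baseline + `threshold_frac` x amplitude, where baseline and amplitude are
#' the 5th percentile and the 5th-to-95th percentile range of the trace
#' (robust to occasional alternans of beat amplitude), with a refractory
#' period between accepted crossings.  Traces whose robust amplitude is
#' within `min_snr_detect` noise SDs (noise estimated from the median absolute
#' first difference) yield an empty window set rather than spurious beats.
#' For paced recordings, windows can instead be anchored at annotated stimulus
#' times.
#'
#' @param trace a preprocessed [pixel_trace()].
#' @param stim_times_ms optional annotated stimulus times (ms from the first
#'   sample); when given, thresholding is skipped.
#' @param threshold_frac detection level as a fraction of the robust
#'   amplitude.
#' @param refractory_ms minimum spacing between detected beats (ms).
#' @param min_snr_detect minimum robust amplitude / noise SD to accept any
#'   beat.
#' @return a data.frame with one row per beat: `start_idx`, `end_idx`,
#'   `act_idx` (1-based sample indices), `activation_ms`, `peak_ms` (ms from
#'   the first sample), `baseline`, `amplitude`.  Zero rows when no beat is
#'   found (not an error).
#' @export
segment_beats <- function(trace, stim_times_ms = NULL, threshold_frac = 0.5,
                          refractory_ms = 100, min_snr_detect = 6) {
  stopifnot(inherits(trace, "pixel_trace"))
  x <- trace$samples
  n <- length(x)
  dt <- 1000 / trace$sampling_rate_hz
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      act_idx = integer(), activation_ms = numeric(),
                      peak_ms = numeric(), baseline = numeric(),
                      amplitude = numeric())
  if (!is.null(stim_times_ms)) {
    cross <- round(stim_times_ms / dt) + 1L
    cross <- cross[cross >= 1 & cross <= n]
  } else {
    if (any(!is.finite(x))) return(empty)
    q <- stats::quantile(x, c(0.05, 0.95), names = FALSE, type = 7)
    amp_r <- q[2] - q[1]
    if (amp_r <= 0) return(empty)
    sigma <- stats::mad(diff(x)) / sqrt(2)
    if (sigma > 0 && amp_r < min_snr_detect * sigma) return(empty)
    th <- q[1] + threshold_frac * amp_r
    cross <- which(x[-1] >= th & x[-n] < th) + 1L
    if (length(cross) > 1) {     # refractory filter
      keep <- cross[1]
      for (cc in cross[-1])
        if ((cc - keep[length(keep)]) * dt >= refractory_ms)
          keep <- c(keep, cc)
      cross <- keep
    }
  }
  if (!length(cross)) return(empty)
  gaps <- diff(c(1L, cross))
  pre <- pmin(ceiling(60 / dt), pmax(floor(0.35 * gaps), 1L))
  starts <- pmax(cross - pre, 1L)
  ends <- c(starts[-1] - 1L, min(n, cross[length(cross)] +
                                   ceiling(600 / dt)))
  out <- empty[rep(1L, length(cross)), , drop = FALSE]
  out <- data.frame(start_idx = starts, end_idx = ends,
                    act_idx = NA_integer_, activation_ms = NA_real_,
                    peak_ms = NA_real_, baseline = NA_real_,
                    amplitude = NA_real_)
  for (b in seq_len(nrow(out))) {
    m <- measure_beat(x[starts[b]:ends[b]], dt)
    if (!is.na(m$activation_ms)) {
      out$act_idx[b] <- starts[b] + round(m$activation_ms / dt)
      out$activation_ms[b] <- (starts[b] - 1) * dt + m$activation_ms
      out$peak_ms[b] <- (starts[b] - 1) * dt + m$peak_ms
    }
    out$baseline[b] <- m$baseline
    out$amplitude[b] <- m$amplitude
  }
  rownames(out) <- NULL
  out
}

beat_slice_measure <- function(beat, trace) {
  stopifnot(inherits(trace, "pixel_trace"))
  beat <- as.list(beat)
  dt <- 1000 / trace$sampling_rate_hz
  m <- measure_beat(trace$samples[beat$start_idx:beat$end_idx], dt)
  m$offset_ms <- (beat$start_idx - 1) * dt
  m
}

#' Activation time of one beat
#'
#' Time of the maximum discrete forward difference on the upstroke; ties are
#' broken to the earliest pair and reported at the later sample of the pair.
#'
#' @param beat one row of the data.frame returned by [segment_beats()].
#' @param trace the [pixel_trace()] the beat was segmented from.
#' @return activation time in ms from the first sample of the trace; `NA` for
#'   a zero-amplitude beat.
#' @export
activation_time <- function(beat, trace) {
  m <- beat_slice_measure(beat, trace)
  if (is.na(m$activation_ms)) NA_real_ else m$offset_ms + m$activation_ms
}

#' 10--90% upstroke rise time of one beat
#'
#' Time from the first 10% to the last 90% upward crossing of the beat
#' amplitude before the peak, linearly interpolated between samples.
#'
#' @inheritParams activation_time
#' @return rise time in ms; `NA` for a zero-amplitude beat.
#' @export
rise_time <- function(beat, trace) beat_slice_measure(beat, trace)$trise_ms

#' APD80 / CaTD80 of one beat
#'
#' Time of the first post-peak crossing of baseline + 0.2 x amplitude
#' (linear interpolation) minus the activation time.  Baseline and amplitude
#' are per-beat quantities, which makes the result invariant to affine
#' intensity transforms of the trace.
#'
#' @inheritParams activation_time
#' @return duration in ms; `NA` when the signal does not return below the 80%
#'   repolarization level within the window (such pixels are excluded from
#'   maps).
#' @export
duration80 <- function(beat, trace) beat_slice_measure(beat, trace)$dur80_ms

# diastolic sample chunks (list of index vectors) for a set of beat windows
diastolic_chunks <- function(beats, trace) {
  dt <- 1000 / trace$sampling_rate_hz
  n <- length(trace$samples)
  chunks <- list()
  for (b in seq_len(nrow(beats))) {
    m <- beat_slice_measure(beats[b, ], trace)
    w_end <- beats$end_idx[b]
    if (!is.na(m$dur80_ms) && !is.na(m$activation_ms)) {
      from <- beats$start_idx[b] +
        round((m$activation_ms + m$dur80_ms + 30) / dt)
      to <- w_end - ceiling(5 / dt)
      if (to - from < ceiling(8 / dt)) {         # short diastole fallback
        from <- max(beats$start_idx[b], w_end - ceiling(18 / dt))
        to <- w_end - ceiling(5 / dt)
      }
    } else {
      from <- max(beats$start_idx[b], w_end - ceiling(18 / dt))
      to <- w_end - ceiling(5 / dt)
    }
    if (to > from && to <= n) chunks[[length(chunks) + 1]] <- from:to
  }
  chunks
}

# pooled SD of linearly detrended chunks (df-corrected)
detrended_sd <- function(x, chunks) {
  rss <- 0; ntot <- 0; nch <- 0
  for (idx in chunks) {
    v <- x[idx]
    if (length(v) < 4 || any(!is.finite(v))) next
    tt <- seq_along(v)
    fit <- stats::lm.fit(cbind(1, tt), v)
    rss <- rss + sum(fit$residuals^2)
    ntot <- ntot + length(v)
    nch <- nch + 1
  }
  if (ntot - 2 * nch < 2) return(NA_real_)
  sqrt(rss / (ntot - 2 * nch))
}

#' Signal-to-noise ratio of a trace
#'
#' Mean beat amplitude divided by the standard deviation of the linearly
#' detrended signal in diastolic windows.  The SD is floored at 1e-12 and the
#' ratio capped at 1e6 (noiseless traces report the cap).  This definition is
#' the one the infarct criterion (SNR between 5 and 10) is calibrated
#' against: attenuating the beat amplitude at fixed sensor noise moves a pixel
#' into the band.
#'
#' @param trace a [pixel_trace()].
#' @param beats beat windows from [segment_beats()]; diastolic windows are the
#'   post-repolarization spans of each window.
#' @param diastolic_idx optional explicit diastolic sample indices (vector or
#'   list of vectors), used instead of the windows derived from `beats`.
#' @return the SNR (dimensionless); `NA` when no diastolic window and no beat
#'   amplitude are available.
#' @export
snr <- function(trace, beats = NULL, diastolic_idx = NULL) {
  stopifnot(inherits(trace, "pixel_trace"))
  if (is.null(diastolic_idx)) {
    if (is.null(beats) || nrow(beats) == 0) return(NA_real_)
    chunks <- diastolic_chunks(beats, trace)
  } else {
    chunks <- if (is.list(diastolic_idx)) diastolic_idx else
      list(diastolic_idx)
  }
  if (!length(chunks)) return(NA_real_)
  if (is.null(beats) || nrow(beats) == 0 || all(is.na(beats$amplitude)))
    return(NA_real_)
  amp <- mean(beats$amplitude, na.rm = TRUE)
  s <- detrended_sd(trace$samples, chunks)
  if (is.na(s)) return(NA_real_)
  min(amp / max(s, 1e-12), 1e6)
}

#' Heart-rate time course from activation times
#'
#' 60000 / mean inter-activation interval within a sliding window.
#'
#' @param activation_times_ms beat activation times (ms), >= 2.
#' @param window_s sliding window width (s).
#' @param step_s window step (s).
#' @return a data.frame with `time_s` (window centers) and `hr_bpm`; windows
#'   holding fewer than two activations are `NA`.
#' @export
heart_rate <- function(activation_times_ms, window_s = 10, step_s = 1) {
  a <- sort(activation_times_ms)
  if (length(a) < 2) stop("need >= 2 activations", call. = FALSE)
  centers <- seq(a[1] / 1000, a[length(a)] / 1000, by = step_s)
  hr <- vapply(centers, function(ct) {
    w <- a[a >= (ct - window_s / 2) * 1000 & a <= (ct + window_s / 2) * 1000]
    if (length(w) < 2) NA_real_ else 60000 / mean(diff(w))
  }, numeric(1))
  data.frame(time_s = centers, hr_bpm = hr)
}
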