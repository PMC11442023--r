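#' Waveform parameters for a synthetic optical action potential or Ca2+ transient
#'
#' The synthetic waveform is the product of a rising logistic (the upstroke)
#' and a falling logistic (repolarization), scaled to `amplitude` above
#' `baseline`.  The parameterization is solved so that the duration measured
#' as the 80%-repolarization crossing minus activation time equals
#' `apd80_ms` analytically: the upstroke slope is `log(81)/upstroke_rise_ms`
#' (which makes the 10--90% rise exactly `upstroke_rise_ms`), activation (the
#' maximum-derivative point) sits at the upstroke center, and the
#' repolarization half-decay point is placed at
#' `apd80_ms - repol_shape * log(4)` after activation so that the falling limb
#' crosses 20% of amplitude exactly `apd80_ms` after activation.
#'
#' The closed form is exact up to the (tiny) deficit of the waveform peak
#' below `amplitude`.  Within the recommended regime
#' `apd80_ms > 2 * upstroke_rise_ms + 4 * repol_shape` the residual error of
#' the measured duration is below 0.15 ms; the constructor warns outside it.
#'
#' @param apd80_ms duration from activation to 80% repolarization (ms); for a
#'   Ca2+ transient this is the CaTD80.
#' @param upstroke_rise_ms 10--90% upstroke rise time (ms).
#' @param amplitude peak fluorescence above baseline (arbitrary units).
#' @param baseline diastolic fluorescence level (arbitrary units).
#' @param repol_shape steepness scale of the repolarization sigmoid (ms); the
#'   final decay has slope `0.2 * 0.8 / repol_shape` per ms at the 80%
#'   crossing.
#' @return an object of class `waveform_params`.
#' @seealso [ap_waveform()]
#' @export
#' @examples
#' p <- waveform_params(apd80_ms = 180, upstroke_rise_ms = 5)
#' t <- seq(0, 400, by = 1)
#' v <- ap_waveform(t, p, activation_ms = 50)
waveform_params <- function(apd80_ms = 180, upstroke_rise_ms = 5,
                            amplitude = 1, baseline = 0, repol_shape = 12) {
  if (!is.finite(apd80_ms) || apd80_ms <= 0)
    stop("'apd80_ms' must be a positive duration", call. = FALSE)
  if (!is.finite(upstroke_rise_ms) || upstroke_rise_ms <= 0)
    stop("'upstroke_rise_ms' must be a positive duration", call. = FALSE)
  if (!is.finite(amplitude) || amplitude <= 0)
    stop("'amplitude' must be positive", call. = FALSE)
  if (!is.finite(repol_shape) || repol_shape <= 0)
    stop("'repol_shape' must be positive", call. = FALSE)
  if (apd80_ms < 2 * upstroke_rise_ms + 4 * repol_shape)
    warning("apd80_ms < 2*upstroke_rise_ms + 4*repol_shape: ",
            "the analytic 80%-crossing placement degrades for such brief ",
            "waveforms", call. = FALSE)
  structure(list(apd80_ms = apd80_ms,
                 upstroke_rise_ms = upstroke_rise_ms,
                 amplitude = amplitude,
                 baseline = baseline,
                 repol_shape = repol_shape),
            class = "waveform_params")
}

#' Evaluate a single synthetic action potential / Ca2+ transient
#'
#' Returns `baseline` exactly for `t < activation_ms - 3 * upstroke_rise_ms`
#' (the pre-stimulus support cut; the suppressed logistic tail there is below
#' `2e-6 * amplitude`).
#'
#' @param t time (ms), vectorized; must be non-negative.
#' @param p a [waveform_params()] object.
#' @param activation_ms time of the maximum upstroke derivative (ms).
#' @return fluorescence values, same length as `t`.
#' @export
ap_waveform <- function(t, p, activation_ms = 0) {
  stopifnot(inherits(p, "waveform_params"))
  if (any(t < 0)) stop("'t' must be non-negative", call. = FALSE)
  p$baseline + p$amplitude * beat_shape(t, activation_ms, p$apd80_ms,
                                        p$upstroke_rise_ms, p$repol_shape)
}

# Unit-amplitude beat shape; `act`, `dur`, `rise`, `shape` may be vectors
# recycled against `t`.  Zero before the support cut at act - 3*rise.
beat_shape <- function(t, act, dur, rise, shape) {
  k <- log(81) / rise
  t_half <- act + dur - shape * log(4)
  up <- stats::plogis(k * (t - act))
  rep_ <- stats::plogis(-(t - t_half) / shape)
  out <- up * rep_
  out[t < act - 3 * rise] <- 0
  out
}

#' Sympathetic nerve stimulation modulation model
#'
#' Describes how heart rate and action potential duration respond to a
#' stimulus.  Under sympathetic nerve stimulation (SNS) the heart rate ramps
#' linearly from `hr_baseline_bpm` to `hr_baseline_bpm + hr_sns_delta_bpm`
#' over `hr_ramp_s` seconds and then plateaus, and the APD80 offset ramps
#' linearly to `apd_sns_delta_ms` at `sns_plateau_s` (60 s, the stimulation
#' duration used for sinus-rhythm SNS).  Isoproterenol is modeled as a step:
#' from `onset_s` on, APD80 and CaTD80 are scaled by `1 + apd_iso_pct/100`
#' and `1 + catd_iso_pct/100`.
#'
#' @param hr_baseline_bpm sinus rate before stimulation (beats/min).
#' @param hr_sns_delta_bpm SNS-driven rate increase at plateau (beats/min).
#' @param hr_ramp_s seconds from SNS onset to the rate plateau.
#' @param apd_sns_delta_ms whole-heart APD80 change reached at
#'   `sns_plateau_s` of SNS (ms; negative = shortening).
#' @param sns_plateau_s seconds from SNS onset at which the APD delta
#'   plateaus.
#' @param catd_iso_pct,apd_iso_pct percent change of CaTD80 / APD80 under
#'   isoproterenol (step at onset).
#' @param onset_s stimulus onset on the protocol clock (s).
#' @param pacing_apd_exponent rate-adaptation exponent for paced recordings:
#'   at a pacing cycle length `pcl` shorter than the baseline sinus cycle
#'   length `rr0`, all durations scale by `(pcl / rr0) ^ pacing_apd_exponent`
#'   (a phenomenological restitution surrogate so that action potentials fit
#'   within fast pacing cycles).  Sinus-rhythm durations come directly from
#'   the waveform parameters and the SNS/Iso responses.
#' @return an object of class `modulation_model`.
#' @export
modulation_model <- function(hr_baseline_bpm = 150, hr_sns_delta_bpm = 100,
                             hr_ramp_s = 10, apd_sns_delta_ms = -30.7,
                             sns_plateau_s = 60,
                             catd_iso_pct = -33.04, apd_iso_pct = -15,
                             onset_s = 0, pacing_apd_exponent = 0.35) {
  if (!is.finite(hr_ramp_s) || hr_ramp_s <= 0)
    stop("'hr_ramp_s' must be positive", call. = FALSE)
  if (!is.finite(hr_baseline_bpm) || hr_baseline_bpm <= 0)
    stop("'hr_baseline_bpm' must be positive", call. = FALSE)
  if (!is.finite(sns_plateau_s) || sns_plateau_s <= 0)
    stop("'sns_plateau_s' must be positive", call. = FALSE)
  structure(list(hr_baseline_bpm = hr_baseline_bpm,
                 hr_sns_delta_bpm = hr_sns_delta_bpm,
                 hr_ramp_s = hr_ramp_s,
                 apd_sns_delta_ms = apd_sns_delta_ms,
                 sns_plateau_s = sns_plateau_s,
                 catd_iso_pct = catd_iso_pct,
                 apd_iso_pct = apd_iso_pct,
                 onset_s = onset_s,
                 pacing_apd_exponent = pacing_apd_exponent),
            class = "modulation_model")
}

#' Heart-rate and APD response at a given time since SNS onset
#'
#' @param t_since_onset seconds since SNS onset (vectorized, >= 0; values
#'   below 0 are treated as pre-stimulus).
#' @param m a [modulation_model()].
#' @return a list with `hr_bpm` and `apd_delta_ms`, each the length of
#'   `t_since_onset`; both ramp continuously and plateau.
#' @export
#' @examples
#' m <- modulation_model()
#' sns_modulation(0, m)   # baseline, no APD change
#' sns_modulation(60, m)  # full APD shortening
sns_modulation <- function(t_since_onset, m) {
  stopifnot(inherits(m, "modulation_model"))
  if (any(t_since_onset < 0 & is.finite(t_since_onset)))
    t_since_onset <- pmax(t_since_onset, 0)
  hr_frac <- pmin(t_since_onset / m$hr_ramp_s, 1)
  apd_frac <- pmin(t_since_onset / m$sns_plateau_s, 1)
  list(hr_bpm = m$hr_baseline_bpm + m$hr_sns_delta_bpm * hr_frac,
       apd_delta_ms = m$apd_sns_delta_ms * apd_frac)
}
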