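---
title: "Methods: optical mapping metrics, segmentation, and synthetic ground truth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optical mapping metrics, segmentation, and synthetic ground truth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optimap)
```

This vignette is the package's account of what it computes and why the
conventions were chosen the way they are.  It states no empirical result
that the test suite and `scripts/acceptance.R` do not themselves compute.

## The measurement chain

Dual-dye optical mapping records transmembrane potential (V~m~) and
intracellular Ca^2+^ fluorescence on a pixel grid (nominally 100 × 100 at
1 kHz over 31 × 31 mm, i.e. 0.31 mm pitch).  For each pixel and beat the
package measures:

* **Activation time** — the sample of maximum discrete forward difference
  on the upstroke.  The max-dF/dt marker is the common optical-mapping
  convention for local depolarization.  Exact ties (which occur whenever a
  symmetric upstroke is sampled symmetrically) are broken to the earliest
  pair and reported at the later sample of the pair; a small relative
  tolerance (1e-4) on the maximum keeps that rule stable against
  floating-point contamination, e.g. the tail of the previous beat.
* **T~rise~** — the 10–90 % upstroke interval, linearly interpolated at the
  level crossings.  The search is confined to the upstroke, defined as the
  span from the last pre-peak sample at or below baseline + 5 % of
  amplitude (the "foot") to the peak; without that restriction, diastolic
  noise produces spurious early 10 % crossings at low SNR.  For
  non-monotone upstrokes the first 10 % and the last 90 % crossing are
  used, with a hysteresis of 10 % of amplitude so that only genuine notches
  (not noise dips) move the 90 % crossing later.
* **APD~80~ / CaTD~80~** — the first post-peak crossing of
  baseline + 0.2 × amplitude, linearly interpolated, minus the activation
  time.  Baseline and amplitude are per-beat quantities (baseline = mean of
  a diastolic window ending two rise times before activation, reaching back
  at most 60 ms; amplitude = peak − baseline), which makes the durations
  exactly invariant to gain and offset and robust to slow drift.  Pixels
  whose signal never returns below the 80 % level inside the beat window
  report a missing value and become holes in the maps — never zeros.
* **SNR** — mean beat amplitude divided by the SD of the linearly detrended
  signal in diastolic windows, floored at 1e-12 and capped at 1e6.  The
  formula is stated prominently because absolute SNR values are
  definition-dependent: this definition makes the infarct criterion band
  (SNR between 5 and 10) reachable by pure amplitude attenuation at fixed
  sensor noise, which is how scar tissue actually presents in these
  recordings.

Maps are assembled by locating beats once on the spatial-mean reference
trace and measuring every pixel inside common beat-aligned windows.  By
default the selected beats are **ensemble-averaged** into one waveform per
pixel before measurement, with a 3-sample moving average applied before
level crossings are read off.  Averaging the waveform rather than the
per-beat metrics is what mapping software does and is decisive at realistic
SNR: level crossings on noisy single beats are first-passage times and
hence biased early, whereas the ensemble suppresses the noise by the square
root of the beat count.  The cost on noiseless waveforms is below 0.05 ms
for the 80 % crossing and below 0.5 ms for the rise time; both are checked
by tests.  A `per_beat` mode (metric per beat, then mean) is available for
protocols where the metric changes within the window.

The pre-activation span of each window is at most 60 ms but never reaches
into the previous beat's repolarization; at a 200-ms pacing cycle length
with a ~150-ms action potential this leaves a genuine diastolic baseline.
With the Ca^2+^ transient, whose sigmoid decay is slower, the last few
percent of decay do bleed into the next baseline window at fast pacing;
this biases paced CaTD~80~ a few ms short.  The bias is common to both arms
of any baseline-vs-stimulation comparison (which is what paced segments are
used for) and absent in sinus rhythm, where the acceptance-grade recovery
experiments run.

## Segmentation

* **Tissue** — SNR ≥ 5, connected components ≥ 10 px.
* **Infarct** — SNR inside [5, 10] (endpoints inclusive) *and*
  T~rise~ > 15 ms (strict), intersected with tissue, components ≥ 10 px.
  The band endpoints and strict rise threshold are the literal reading of
  the criterion; where a looser "SNR < 15" convention is wanted (it appears
  as an alternative description of the same phenotype), the option
  `snr_criterion = "below_15"` provides it — the band is the default.
* **Remote** — pixels taken farthest-first from the infarct centroid,
  restricted to the basal half of the tissue bounding box along the
  apex–base axis (default: image vertical, base at top — the axis is a
  convention, not a measurement), excluding a 10-px dilation of the
  infarct, until the infarct pixel count is matched.  Equidistant
  candidates resolve in row-major order so masks are bit-reproducible.
  Sham hearts, which have no criterion-defined infarct, use configured
  anatomical ROIs (remote at the base, pseudo-infarct at the LV apex).

**APD dispersion** is (95th − 5th percentile of pixel APDs) divided by the
tissue area.  Percentiles interpolate linearly at rank q·(n−1)
(`quantile` type 7); "area of tissue in the field of view" is the tissue
*mask* area (pixel count × pitch², in cm²), not the full field of view —
the literal reading of the definition.  Dispersion is therefore invariant
to adding a constant to every APD and scales linearly with a multiplicative
spread; both are tested properties.

## Statistics

The three small-sample procedures are implemented from first principles and
cross-checked against independent references in the tests:

* **Fisher exact 2×2** — full hypergeometric enumeration; the two-sided p
  sums the probabilities of all tables no more probable than the observed
  one (relative tolerance 1e-7 for floating-point ties).  This
  probability-mass rule is the mainstream convention.
* **t from summary statistics** — pooled (Sp², df = n₁+n₂−2) and Welch
  variants; the two-sided p is evaluated through an in-package regularized
  incomplete beta (Lentz continued fraction), accurate to ~1e-12 and tested
  against the reference t CDF to 1e-9.
* **Exact Mann–Whitney** — midranks for ties; for combined n ≤ 25 the null
  is the exact permutation distribution of the rank sum over all
  choose(n₁+n₂, n₁) labelings, computed by dynamic programming over doubled
  ranks (identical to full enumeration, including under ties); two-sided p
  doubles the smaller tail and caps at 1.  Larger samples fall back to the
  tie-corrected normal approximation and say so.

Two-way repeated-measures / mixed-effects ANOVA with Sidak correction, used
in the source study for its multi-timepoint comparisons, is deliberately
not implemented: it is an off-the-shelf procedure available in standard
software and not part of this package's contribution.

## The synthetic generator

No raw movies of this kind are publicly deposited, so the generator is the
package's test bed; its defaults *are* the study conditions and are not
tuned per experiment.

**Waveform.**  Each beat is a rising logistic times a falling logistic:
the upstroke slope is log(81)/T~rise~ (making the 10–90 % rise exactly
T~rise~), activation sits at the upstroke center, and the repolarization
half-decay point is placed at APD₈₀ − s·log 4 after activation (s =
`repol_shape`), so the 80 % crossing lands at the nominal APD₈₀
analytically, not by search.  The residual error from the finite peak
deficit is below 0.15 ms in the default regime (APD₈₀ > 2·T~rise~ + 4·s;
the constructor warns outside it), verified against brute-force crossing
searches.

**Defaults and why.**  Sampling 1 kHz, grid 100 × 100, pitch 0.31 mm (the
acquisition geometry).  APD₈₀ 180 ms and sinus rate 150 bpm: no absolute
baselines are printed for this preparation, so these are invented,
physiologically ordinary rabbit values, stated here as such.  CaTD₈₀
240 ms (CaTD₈₀ exceeds APD₈₀).  V~m~ rise 5 ms, Ca rise 12 ms; repol shape
12 ms (V~m~) / 18 ms (Ca).  Amplitude 1 with additive i.i.d. Gaussian noise
SD 0.03 per pixel-frame, giving remote SNR ≈ 33.  The infarct is a disc at
the LV apex (center at 75 % of rows, radius 15 % of the grid) with
amplitude scaled by 0.225 (SNR ≈ 7.5, mid criterion band), V~m~ upstroke
slowed 4× (T~rise~ 20 ms > 15), APD₈₀ offset +10 ms, and a 3-px border
annulus over which all parameters blend linearly (weights quantized to
1/32, which also caps the number of distinct waveforms per movie).  Ca
transients in the scar lose amplitude but keep their rise: the slowed
upstroke is an action-potential phenotype.

**Protocols.**  SNS ramps heart rate by +100 bpm over 10 s and the APD₈₀
offset linearly to its plateau at 60 s — the printed whole-heart effect
sizes (−30.7 ms sham, −24.3 ms MI) are direct generator inputs.  In MI
hearts the infarct responds at 0.6× the remote response (sympathetic
effect attenuated in scar); the remote delta is solved so the whole-heart
mean still equals the printed value, and the regional difference is what
makes APD dispersion rise under SNS in MI movies and stay flat in sham —
the behavior the pipeline tests check.  Isoproterenol is a step to a new
plateau: CaTD₈₀ −33.04 % (sham) / −42.60 % (MI) and APD₈₀ −15 % (no APD
percentage is printed; −15 % is an invented, plausible β-adrenergic
shortening).  Pacing places beats at the stated cycle length (200 ms for
rate-matched comparisons); since the generator has no ionic restitution,
paced durations scale phenomenologically by (PCL/RR₀)^0.35 and saturate at
75 % of the cycle so transients return to diastole — a surrogate for rate
adaptation, not a biophysical claim.

**What the generator does not emulate** — and hence what passing recovery
tests do and do not show: no biophysical ionic models, no conduction
(activation is spatially uniform by default), no motion artifact, no
photobleaching by default (a linear drift flag exists), noise is white and
Gaussian rather than shot-limited or spatially correlated, and the infarct
is a clean disc rather than an irregular scar with peninsulas.  Recovery
results therefore validate the *measurement chain* — that the estimators
return the truth they were pointed at, at realistic SNR — not the
biological variability of real hearts.

## Numerical choices and degenerate inputs

Linear interpolation at every level crossing; missing values propagate as
map holes.  Beat detection thresholds at 50 % of a robust (5th–95th
percentile) amplitude with a 100-ms refractory period, and refuses to
report beats when that amplitude is within 6 noise SDs (median absolute
first difference), so flat or noise-only traces yield an empty beat set
rather than artifacts.  Constant traces pass through preprocessing and are
flagged zero-amplitude downstream.  All-zero contingency tables, empty
tissue masks, empty beat selections and empty protocol windows raise
errors naming the problem; degenerate zero-variance t-tests return the
documented sentinels (p = 1 for equal means, p = 0 with infinite t
otherwise).

Movies serialize as one multi-frame TIFF per channel plus a JSON sidecar
(sampling rate, pitch, polarity, protocol, seed, per-channel offset/scale);
metric maps as 32-bit TIFF with a reserved code for missing pixels; masks
as 8-bit TIFF; results as long-format CSV; configuration as YAML.  The
TIFF writer stores 32-bit integer samples scaled to [0, 1], so round trips
are exact to 1/(2³² − 1) (~2e-10 relative) — quantization-limited rather
than bit-exact, and tested at 1e-8.  Voltage dyes whose fluorescence falls
on depolarization are handled by a polarity flag; normalization reflects
the trace about its sample mid-range, an exact involution.

## Problem sizes used in tests

Unit and property tests run on small grids (6×6 to 60×60) and short
segments so the suite stays fast; the acceptance-grade recovery
experiments run at the full acquisition scale (100 × 100 px, 1 kHz) with
five seeds per condition, using a 2.4-s baseline segment and a late-SNS
segment covering 56.8–60 s of stimulation (beats from the last 2 s are
measured, so the ramp bias is a fraction of a ms).  The Mann–Whitney null
calibration uses 10⁴ replicates at n = 5/5.

## Known limitations

Rise-time estimates degrade at low SNR even with ensemble averaging — level
crossings in noise are biased — so infarct-pixel T~rise~ is upward-biased
at the default noise level.  This does not harm the classifier (the bias
pushes scar pixels deeper into the T~rise~ > 15 ms region and remote pixels
are excluded by their SNR alone), but the rise *map* should be read
qualitatively in low-SNR regions.  Paced CaTD₈₀ carries the few-ms
common-mode bias described above.  The remote-region rule assumes the
apex–base axis is the image vertical; real preparations may need the
`base` option.  Sub-millisecond activation refinement is deliberately off:
all times are quantized to the 1-kHz frame clock plus linear interpolation
at level crossings.
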