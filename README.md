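# optimap

Simulation and analysis of dual-dye cardiac optical mapping recordings, with
the small-sample statistics and histology quantification that accompany a
typical infarct electrophysiology study.

Optical mapping images a perfused heart with voltage- and Ca²⁺-sensitive
dyes (here nominally 100 × 100 pixels at 1 kHz over a 31 × 31 mm field of
view).  From each pixel's fluorescence trace the package measures, per beat:

- **activation time** — the maximum upstroke derivative (max dF/dt),
- **T_rise** — the 10–90 % upstroke rise time, interpolated between samples,
- **APD₈₀ / CaTD₈₀** — time of 80 % repolarization (first post-peak crossing
  of baseline + 0.2 × amplitude) minus activation time,
- **SNR** — mean beat amplitude over the SD of the detrended diastolic
  signal.

On top of the per-pixel maps it implements the study-level quantities:

- **region segmentation** — tissue (SNR ≥ 5); infarct (SNR in [5, 10]
  *and* T_rise > 15 ms, components ≥ 10 px); remote (same pixel count as the
  infarct, farthest from it, in the basal half, outside a 10 px exclusion
  zone); anatomical ROIs for sham hearts,
- **APD dispersion** — (95th − 5th percentile of pixel APDs) ÷ tissue area,
  in ms/cm², a re-entry substrate proxy,
- **protocol responses** — heart-rate and APD₈₀ time courses under
  sympathetic nerve stimulation (SNS, ramping to plateau), isoproterenol
  step responses, rate-matched pacing (PCL 200 ms),
- **statistics from first principles** — exact Fisher 2×2 (hypergeometric
  enumeration, probability-mass two-sided rule), pooled/Welch t-tests from
  summary statistics (p through an in-package regularized incomplete beta),
  exact Mann–Whitney (dynamic-programming permutation null, midranks for
  ties, doubled smaller tail),
- **histology** — percent-positive area of immunofluorescence images (Otsu
  or fixed threshold), e.g. TH⁺ sympathetic nerve density and CSPG⁺ area.

Because no raw recordings of this kind are publicly deposited, the package
includes a first-class synthetic generator: dual-channel movies built from a
logistic-upstroke × sigmoid-repolarization waveform whose APD₈₀ is an exact
analytic input, with an infarct disc (attenuated amplitude, slowed upstroke,
APD offset, blended border zone), SNS/Iso protocol modulation, and additive
Gaussian sensor noise — all with per-pixel ground truth for recovery
testing.

## Worked example

```r
library(optimap)

# synthetic infarcted heart, sinus rhythm, default noise
sim  <- generate_movie(sim_preset("mi", "sinus", seed = 1,
                                  duration_s = 2.4, channels = "vm"))
maps <- build_maps(sim$movie, "vm")
tis  <- tissue_mask(maps$snr)
inf  <- infarct_mask(maps$snr, maps$trise, tissue = tis)
mask_overlap(inf, sim$truth$infarct_mask)$jaccard
#> [1] 0.9410151

apd_dispersion(maps$apd80, tis, pixel_pitch_mm = 0.31)
#> APD dispersion: 8.7 ms (p5 178.1, p95 186.8) / 9.5994 cm^2 = 0.9 ms/cm^2

# the printed arrhythmia-incidence comparison: VT/VF in 5/8 MI vs 0/4 sham
fisher_exact_2x2(matrix(c(5, 0, 3, 4), 2))$p.value
#> [1] 0.08080808

# TH+ nerve density, infarct vs remote (% area, mean +- SD, n = 6/6)
t_test_from_summary(summary_stats(0.56, 0.40, 6),
                    summary_stats(6.41, 2.78, 6))$p.value
#> [1] 0.0004627016
```

The Jaccard index says the criterion-based infarct mask recovers 94 % of the
true infarct disc (union-normalized) at the default noise level; the
dispersion line reports the 5th–95th percentile APD range normalized by the
9.6 cm² tissue area; the Fisher and t-test p-values match the printed
values (0.08 and 0.0005) at their reported precision.

## Layout

- `R/` — waveform & movie generator, trace metrics, maps & segmentation,
  dispersion, statistics, histology, I/O and pipeline
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/optical-mapping-methods.Rmd` — the methods vignette: model,
  conventions, parameter defaults and their rationale, limitations
- `inst/cli/optimap` — command-line front end
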