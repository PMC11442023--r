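test_that("preprocess is the identity for upright traces and an exact
           involution for inverted ones", {
  v <- beat_train(4)
  tr <- pixel_trace(v, 1000)
  expect_identical(preprocess(tr)$samples, v)
  inv <- pixel_trace((max(v) + min(v)) - v, 1000, polarity = "inverted")
  expect_equal(preprocess(inv)$samples, preprocess(tr)$samples)
})

test_that("baseline correction recovers beat amplitudes under linear drift", {
  v <- beat_train(8, pcl_ms = 200, apd_ms = 120)
  drift <- 0.01 * seq_along(v)               # 0.01 per frame
  cor <- preprocess(pixel_trace(v + drift, 1000), baseline_correct = TRUE)
  b0 <- segment_beats(pixel_trace(v, 1000))
  b1 <- segment_beats(cor)
  expect_equal(nrow(b1), nrow(b0))
  mid <- 3:6                                 # away from interpolation edges
  expect_all_equal(b1$amplitude[mid] / b0$amplitude[mid], 1, 0.01)
})

test_that("beat segmentation finds regular trains, alternans, and nothing in
           noise or constant traces", {
  b <- segment_beats(pixel_trace(beat_train(10, pcl_ms = 200,
                                            apd_ms = 120), 1000))
  expect_equal(nrow(b), 10)
  expect_all_equal(diff(b$start_idx), 200, 0)
  expect_all_equal(diff(b$activation_ms), 200, 1)

  alt <- beat_train(10, pcl_ms = 400, apd_ms = 150, amps = c(1, 0.5))
  ba <- segment_beats(pixel_trace(alt, 1000))
  expect_equal(nrow(ba), 10)
  expect_equal(sort(round(unique(round(ba$amplitude, 1)), 1)), c(0.5, 1))

  set.seed(42)
  expect_equal(nrow(segment_beats(pixel_trace(rnorm(2000, 0, 0.05), 1000))),
               0)
  expect_equal(nrow(segment_beats(pixel_trace(rep(2, 500), 1000))), 0)
})

test_that("activation time is the max-upstroke-slope sample with the stated
           tie-break", {
  # instantaneous step at 100 ms
  v <- square_pulse(100, 300, 500)
  tr <- pixel_trace(v, 1000)
  b <- segment_beats(tr)
  expect_equal(activation_time(b[1, ], tr), 100)

  # linear ramp over 0-2 ms: constant slope, tie broken to the earliest
  # pair, reported at the later sample -> 1 ms
  vr <- c(0, 0.5, 1, 1 - (seq_len(300) / 300))
  trr <- pixel_trace(vr, 1000)
  br <- data.frame(start_idx = 1, end_idx = length(vr))
  expect_equal(activation_time(br, trr), 1)

  # logistic upstroke centered at 30 ms with k = 0.5 / ms
  t <- 0:200
  vl <- plogis(0.5 * (t - 30)) * plogis(-(t - 150) / 10)
  bl <- data.frame(start_idx = 1, end_idx = length(vl))
  expect_lt(abs(activation_time(bl, pixel_trace(vl, 1000)) - 30), 1)
})

test_that("rise time is the interpolated 10-90% upstroke interval", {
  # linear ramp 0 -> 1 over 20 ms: exactly 16 ms
  v <- c(rep(0, 50), seq(0, 1, length.out = 21), rep(1, 30),
         1 - seq_len(250) / 250)
  b <- data.frame(start_idx = 1, end_idx = length(v))
  expect_equal(rise_time(b, pixel_trace(v, 1000)), 16)

  # one-sample step: sampling-limited
  vs <- square_pulse(100, 300, 500)
  trs <- pixel_trace(vs, 1000)
  bs <- segment_beats(trs)
  expect_lte(rise_time(bs[1, ], trs), 1)

  # logistic slope k: rise = ln(81) / k
  t <- 0:400
  vl <- plogis(0.5 * (t - 60)) * plogis(-(t - 300) / 12)
  bl <- data.frame(start_idx = 1, end_idx = length(vl))
  expect_lt(abs(rise_time(bl, pixel_trace(vl, 1000)) - log(81) / 0.5), 0.2)
})

test_that("duration80 matches closed-form crossings", {
  # ideal square pulse from 100 to 300 ms
  vs <- square_pulse(100, 300, 500)
  trs <- pixel_trace(vs, 1000)
  bs <- segment_beats(trs)
  expect_lt(abs(duration80(bs[1, ], trs) - 200), 1)

  # triangular AP: 2 ms rise, linear decay 1 -> 0 over 200 ms; activation
  # at 1 ms (tie-break), 20% crossing at 162 ms -> APD80 = 161 ms
  vt <- c(0, 0.5, 1, 1 - seq_len(300) / 200)
  vt[vt < 0] <- 0
  bt <- data.frame(start_idx = 1, end_idx = length(vt))
  expect_equal(duration80(bt, pixel_trace(vt, 1000)), 161, tolerance = 1e-6)

  # exponential repolarization, tau = 50 ms: APD80 = tau * ln 5
  ve <- c(rep(0, 100), exp(-(0:400) / 50))
  be <- data.frame(start_idx = 1, end_idx = length(ve))
  expect_lt(abs(duration80(be, pixel_trace(ve, 1000)) - 50 * log(5)), 0.2)
})

test_that("duration80 is invariant to affine intensity transforms", {
  v <- beat_train(5, pcl_ms = 300, apd_ms = 140)
  tr1 <- pixel_trace(v, 1000)
  tr2 <- pixel_trace(3.7 * v - 5, 1000)
  b1 <- segment_beats(tr1)
  b2 <- segment_beats(tr2)
  expect_equal(nrow(b1), nrow(b2))
  for (k in seq_len(nrow(b1))) {
    expect_equal(duration80(b1[k, ], tr1), duration80(b2[k, ], tr2),
                 tolerance = 1e-9)
    expect_equal(rise_time(b1[k, ], tr1), rise_time(b2[k, ], tr2),
                 tolerance = 1e-9)
  }
})

test_that("SNR is amplitude over detrended diastolic SD, floored and capped", {
  # clean square beats with alternating +-0.1 diastole: SNR = 1 / 0.1 = 10
  n <- 1600
  v <- numeric(n)
  acts <- c(400, 800, 1200)
  for (a in acts) v[(a + 1):(a + 150)] <- 1
  dia <- v == 0
  v[dia] <- rep_len(c(0.1, -0.1), sum(dia))
  tr <- pixel_trace(v, 1000)
  beats <- segment_beats(tr, stim_times_ms = acts)
  s <- snr(tr, beats)
  expect_lt(abs(s - 10) / 10, 0.03)

  # halving the amplitude halves the SNR
  v2 <- v
  v2[!dia] <- v2[!dia] * 0.5
  tr2 <- pixel_trace(v2, 1000)
  beats2 <- segment_beats(tr2, stim_times_ms = acts)
  expect_lt(abs(snr(tr2, beats2) - s / 2) / (s / 2), 0.03)

  # noiseless flat-diastole trace hits the cap
  vq <- numeric(n)
  for (a in acts) vq[(a + 1):(a + 150)] <- 1
  trq <- pixel_trace(vq, 1000)
  expect_equal(snr(trq, segment_beats(trq, stim_times_ms = acts)), 1e6)

  # no usable beats -> missing value
  expect_true(is.na(snr(trq, NULL)))
})

test_that("heart rate is 60000 over the mean inter-activation interval", {
  hr <- heart_rate(seq(0, 10000, by = 500), window_s = 4)
  expect_all_equal(hr$hr_bpm[!is.na(hr$hr_bpm)], 120, 1e-9)
  hr2 <- heart_rate(seq(0, 12000, by = 200), window_s = 4)
  expect_all_equal(hr2$hr_bpm[!is.na(hr2$hr_bpm)], 300, 1e-9)
  hr3 <- heart_rate(seq(0, 12000, by = 400), window_s = 4)
  expect_all_equal(hr3$hr_bpm[!is.na(hr3$hr_bpm)], 150, 1e-9)
  expect_error(heart_rate(100), ">= 2")
})
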