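# Constructed trace fixtures shared across test files.  All are built from
# closed forms so expected metric values are known exactly.

# logistic-upstroke / sigmoid-repolarization beat train sampled at 1 kHz
beat_train <- function(n_beats = 10, pcl_ms = 400, apd_ms = 150,
                       rise_ms = 5, amps = 1, baseline = 0, shape = 12,
                       first_act_ms = 200, n_ms = NULL) {
  if (is.null(n_ms)) n_ms <- first_act_ms + n_beats * pcl_ms
  t <- seq(0, n_ms - 1)
  v <- rep(baseline, length(t))
  amps <- rep_len(amps, n_beats)
  for (k in seq_len(n_beats)) {
    act <- first_act_ms + (k - 1) * pcl_ms
    v <- v + amps[k] * optimap:::beat_shape(t, act, apd_ms, rise_ms, shape)
  }
  v
}

# square action potential: value 1 on [on_ms, off_ms], else 0 (1 kHz)
square_pulse <- function(on_ms, off_ms, n_ms) {
  t <- seq(0, n_ms - 1)
  as.numeric(t >= on_ms & t <= off_ms)
}

# brute-force APD80: activation at max forward difference, crossing of
# baseline + 0.2 * (peak - baseline) found on a fine grid by direct search
brute_force_apd80 <- function(fun, act_hint, t_max, dt = 0.005) {
  tg <- seq(0, t_max, by = dt)
  v <- fun(tg)
  b <- min(v)
  pk <- max(v)
  th <- b + 0.2 * (pk - b)
  ipk <- which.max(v)
  d <- diff(v[tg <= act_hint + 50])
  act <- tg[which.max(d) + 1]
  post <- which(tg > tg[ipk])
  i <- post[which(v[post] < th)[1]]
  # linear interpolation between the bracketing fine-grid samples
  tc <- tg[i - 1] + dt * (v[i - 1] - th) / (v[i - 1] - v[i])
  tc - act
}

expect_all_equal <- function(x, value, tol) {
  expect_true(all(abs(x - value) <= tol),
              label = sprintf("max |x - %g| = %g", value,
                              max(abs(x - value))))
}
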