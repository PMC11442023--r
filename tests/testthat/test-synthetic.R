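test_that("generated movies are bit-identical for a fixed seed", {
  cfg <- movie_config(grid = c(8, 8), duration_s = 1.2, seed = 11)
  a <- generate_movie(cfg)
  b <- generate_movie(cfg)
  expect_identical(a$movie$channels$vm, b$movie$channels$vm)
  expect_identical(a$movie$channels$ca, b$movie$channels$ca)
  expect_identical(a$truth$apd80_map, b$truth$apd80_map)
})

test_that("ground-truth APD80 equals the brute-force crossing of the
           noiseless waveform at remote, border and core pixels", {
  # 10 kHz sampling so the crossing search is not quantization-limited
  cfg <- sim_preset("mi", "sinus", seed = 2, grid = c(20, 20),
                    duration_s = 1.4, noise_sd = 0, channels = "vm",
                    sampling_rate_hz = 10000)
  sim <- generate_movie(cfg)
  w <- optimap:::infarct_weight_map(cfg$grid, cfg$infarct)
  picks <- c(which(w == 0)[1], which(w > 0.3 & w < 0.7)[1], which(w == 1)[1])
  acts <- sim$truth$activation_times_ms
  a <- acts[acts >= 300][1]
  for (p in picks) {
    tr <- sim$movie$channels$vm[p, ]
    # single-beat slice starting 50 ms before this beat's activation
    fun <- function(t) approx((seq_along(tr) - 1) / 10, tr,
                              xout = t + a - 50)$y
    apd <- brute_force_apd80(fun, 50, 440, dt = 0.01)
    expect_lt(abs(apd - sim$truth$apd80_map[p]), 0.5)
  }
})

test_that("infarct SNR follows the amplitude/noise algebra and lands in the
           classifier band", {
  cfg <- sim_preset("mi", "sinus", seed = 5, grid = c(30, 30),
                    duration_s = 2, noise_sd = 0.02, channels = "vm")
  cfg$infarct$snr_scale <- 0.1
  sim <- generate_movie(cfg)
  core <- sim$truth$infarct_mask
  expect_equal(unique(sim$truth$snr_map[!as.logical(
    optimap:::infarct_weight_map(cfg$grid, cfg$infarct) > 0)]), 50)
  expect_equal(unique(sim$truth$snr_map[core]), 5)
  maps <- build_maps(sim$movie, "vm")
  expect_lt(abs(median(maps$snr[!core]) - 50) / 50, 0.15)
  expect_lt(abs(median(maps$snr[core]) - 5) / 5, 0.25)
})

test_that("an infarct disc reaching past the grid edge is clipped with a
           warning", {
  inf <- infarct_geometry(center_px = c(5, 5), radius_px = 10)
  expect_warning(
    generate_movie(movie_config(grid = c(20, 20), duration_s = 0.6,
                                infarct = inf, channels = "vm", seed = 1)),
    "clipped")
})

test_that("increasing noise never increases expected pixelwise SNR", {
  snr_at <- function(noise_sd) {
    vals <- vapply(1:20, function(s) {
      cfg <- movie_config(grid = c(6, 6), duration_s = 1.6,
                          noise_sd = noise_sd, channels = "vm", seed = s)
      maps <- build_maps(generate_movie(cfg)$movie, "vm")
      mean(maps$snr)
    }, numeric(1))
    mean(vals)
  }
  s <- vapply(c(0.02, 0.04, 0.08), snr_at, numeric(1))
  expect_true(all(diff(s) < 0))
})

test_that("synthetic histology images hit the requested positive fraction", {
  h0 <- generate_histology_image(c(64, 64), 0, noise_sd = 0, seed = 1)
  expect_equal(sum(h0$positive_mask), 0)
  expect_equal(as.numeric(
    positive_area_fraction(h0$image, "fixed", threshold = 0.5)), 0)

  h25 <- generate_histology_image(c(64, 64), 0.25, noise_sd = 0, seed = 2)
  expect_equal(h25$positive_fraction, 0.25)
  expect_equal(as.numeric(
    positive_area_fraction(h25$image, "fixed", threshold = 0.5)), 25)

  # printed TH+ remote preset recovers within half a percentage point
  fr <- histology_presets()$th_remote
  rec <- vapply(1:3, function(s) {
    h <- generate_histology_image(c(128, 128), fr, seed = s)
    as.numeric(positive_area_fraction(h$image, "otsu"))
  }, numeric(1))
  expect_all_equal(rec, 100 * fr, 0.5)

  expect_error(generate_histology_image(c(10, 10), 1.2, seed = 1), "0, 1")
  expect_error(generate_histology_image(c(10, 10), 0.5), "seed")
  a <- generate_histology_image(c(32, 32), 0.1, seed = 9)
  b <- generate_histology_image(c(32, 32), 0.1, seed = 9)
  expect_identical(a$image, b$image)
})
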