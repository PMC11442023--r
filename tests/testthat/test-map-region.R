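test_that("noiseless homogeneous movies recover generator parameters within
           one sample interval", {
  cfg <- movie_config(grid = c(10, 10), duration_s = 1.6, noise_sd = 0,
                      seed = 3)
  sim <- generate_movie(cfg)
  m_vm <- build_maps(sim$movie, "vm")
  m_ca <- build_maps(sim$movie, "ca")
  expect_all_equal(m_vm$apd80, 180, 0.5)
  expect_all_equal(m_ca$catd80, 240, 0.5)
  expect_all_equal(m_vm$trise, 5, 1)
  expect_all_equal(m_ca$trise, 12, 1)
  expect_all_equal(m_vm$activation, 0, 1)
})

test_that("a NaN-poisoned pixel is missing in all maps without affecting
           its neighbours", {
  cfg <- movie_config(grid = c(6, 6), duration_s = 1.2, noise_sd = 0,
                      channels = "vm", seed = 4)
  sim <- generate_movie(cfg)
  sim$movie$channels$vm[8, 600] <- NaN
  maps <- build_maps(sim$movie, "vm")
  expect_true(is.na(maps$apd80[8]))
  expect_true(is.na(maps$trise[8]))
  expect_true(is.na(maps$snr[8]))
  expect_all_equal(maps$apd80[-8], 180, 0.5)
})

test_that("empty beat selections are rejected", {
  cfg <- movie_config(grid = c(4, 4), duration_s = 1.2, noise_sd = 0,
                      channels = "vm", seed = 4)
  sim <- generate_movie(cfg)
  expect_error(build_maps(sim$movie, "vm", time_range_s = c(50, 60)),
               "empty beat selection")
})

test_that("the infarct criterion is applied literally: SNR band inclusive,
           rise threshold strict", {
  snr <- matrix(c(8, 8, 12, 10, 5, 4), 2, 3)
  rise <- matrix(c(20, 10, 20, 15, 16, 20), 2, 3)
  m <- infarct_mask(snr, rise, min_component_px = 0)
  expect_equal(as.vector(m),
               c(TRUE,   # SNR 8, rise 20
                 FALSE,  # SNR 8, rise 10  (rise not > 15)
                 FALSE,  # SNR 12 outside band
                 FALSE,  # SNR 10.0, rise 15.0 (boundary: rise not strict >)
                 TRUE,   # SNR 5 inclusive low edge, rise 16
                 FALSE)) # SNR 4 below band
  # alternative criterion from the figure-legend convention
  m2 <- infarct_mask(snr, rise, snr_criterion = "below_15",
                     min_component_px = 0)
  expect_equal(as.vector(m2), c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
})

test_that("tissue and infarct masks drop small connected components", {
  s <- matrix(1, 20, 20)
  s[5:7, 5:7] <- 50                       # 9-pixel island < 10
  expect_warning(t1 <- tissue_mask(s), "empty")
  expect_equal(sum(t1), 0)
  s[10:15, 10:15] <- 50                   # 36-pixel component survives
  t2 <- tissue_mask(s)
  expect_equal(sum(t2), 36)
  expect_false(any(t2[5:7, 5:7]))
  expect_equal(sum(tissue_mask(matrix(50, 12, 12))), 144)
})

test_that("infarct mask is monotone in the rise threshold and reproducible", {
  set.seed(7)
  snr <- matrix(runif(400, 0, 20), 20, 20)
  rise <- matrix(runif(400, 0, 40), 20, 20)
  m15 <- infarct_mask(snr, rise, rise_threshold_ms = 15, min_component_px = 0)
  m10 <- infarct_mask(snr, rise, rise_threshold_ms = 10, min_component_px = 0)
  expect_true(all(m10[m15]))              # relaxing never removes pixels
  expect_identical(m15, infarct_mask(snr, rise, rise_threshold_ms = 15,
                                     min_component_px = 0))
})

test_that("remote region matches infarct size, stays basal, and avoids the
           exclusion zone", {
  tis <- matrix(TRUE, 40, 40)
  inf <- matrix(FALSE, 40, 40)
  ij <- which(
    outer((1:40 - 34)^2, (1:40 - 20)^2, `+`) <= 5.6^2, arr.ind = TRUE)
  inf[ij] <- TRUE                          # apical disc, ~100 px
  expect_gte(sum(inf), 90)
  rem <- remote_mask(tis, inf, exclusion_px = 10)
  expect_equal(sum(rem), sum(inf))
  expect_true(all(row(rem)[rem] <= 20))    # basal half (base at top)
  di <- which(inf, arr.ind = TRUE)
  dr <- which(rem, arr.ind = TRUE)
  dmin <- min(sqrt(outer(dr[, 1], di[, 1], `-`)^2 +
                     outer(dr[, 2], di[, 2], `-`)^2))
  expect_gt(dmin, 10)
  expect_identical(rem, remote_mask(tis, inf, exclusion_px = 10))
})

test_that("sham hearts use the configured anatomical ROIs", {
  tis <- matrix(TRUE, 30, 30)
  roi <- sham_rois(c(30, 30), size_px = 64)
  rem <- remote_mask(tis, matrix(FALSE, 30, 30), sham_roi = roi)
  expect_identical(rem, roi$remote)
  expect_equal(sum(roi$remote), 64)
  expect_true(all(row(roi$remote)[roi$remote] <= 15))     # base at top
  expect_true(all(row(roi$infarct)[roi$infarct] > 15))    # apex at bottom
  expect_error(remote_mask(tis, matrix(FALSE, 30, 30)), "sham_roi")
  expect_error(remote_mask(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)),
               "empty")
})

test_that("MI-preset movies put infarct pixels in the criterion band", {
  sim <- generate_movie(sim_preset("mi", "sinus", seed = 8, grid = c(50, 50),
                                   duration_s = 2.4, channels = "vm"))
  maps <- build_maps(sim$movie, "vm")
  core <- sim$truth$infarct_mask
  expect_gt(median(maps$trise[core]), 15)
  expect_true(all(median(maps$snr[core]) >= 5,
                  median(maps$snr[core]) <= 10))
  expect_lt(median(maps$trise[!core]), 15)
  expect_gt(median(maps$snr[!core]), 10)
})
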