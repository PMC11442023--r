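test_that("dispersion of a uniform map is zero and the staircase fixture
           matches hand arithmetic", {
  u <- apd_dispersion(matrix(150, 10, 10), pixel_pitch_mm = 0.31)
  expect_equal(u$dispersion, 0)

  # 100 pixels, APDs 100..199 ms, pitch 0.31 mm:
  # p5 = 104.95, p95 = 194.05, range = 89.1 ms, area = 100 * 0.31^2 mm^2
  d <- apd_dispersion(matrix(100:199, 10, 10), pixel_pitch_mm = 0.31)
  expect_equal(d$p5_ms, 104.95)
  expect_equal(d$p95_ms, 194.05)
  expect_equal(d$range_ms, 89.1)
  expect_equal(d$area_cm2, 0.0961)
  expect_equal(d$dispersion, 89.1 / 0.0961)
})

test_that("dispersion halves when tissue area doubles at a fixed APD
           distribution", {
  one <- apd_dispersion(matrix(100:199, 10, 10), pixel_pitch_mm = 0.31)
  two <- apd_dispersion(matrix(rep(100:199, 2), 10, 20),
                        pixel_pitch_mm = 0.31)
  expect_equal(two$range_ms, one$range_ms)
  expect_equal(two$dispersion, one$dispersion / 2)
})

test_that("dispersion is shift-invariant and scales with multiplicative
           spread", {
  set.seed(3)
  m <- matrix(rnorm(144, 180, 12), 12, 12)
  d0 <- apd_dispersion(m, pixel_pitch_mm = 0.31)
  d_shift <- apd_dispersion(m + 37, pixel_pitch_mm = 0.31)
  expect_equal(d_shift$dispersion, d0$dispersion)
  med <- median(m)
  d_spread <- apd_dispersion(med + 2.5 * (m - med), pixel_pitch_mm = 0.31)
  expect_equal(d_spread$dispersion, 2.5 * d0$dispersion)
  expect_gte(d0$dispersion, 0)
})

test_that("percentiles agree with a sort-and-interpolate brute-force oracle", {
  oracle_q <- function(x, q) {           # linear interpolation at rank q(n-1)
    s <- sort(x)
    r <- q * (length(s) - 1)
    lo <- floor(r)
    s[lo + 1] + (r - lo) * (s[min(lo + 2, length(s))] - s[lo + 1])
  }
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:1000, 1)
    x <- rnorm(n, 150, 30)
    d <- apd_dispersion(matrix(x, nrow = 1), pixel_pitch_mm = 0.31)
    expect_equal(d$p5_ms, oracle_q(x, 0.05))
    expect_equal(d$p95_ms, oracle_q(x, 0.95))
  }
})

test_that("degenerate maps give a missing-value dispersion", {
  d <- apd_dispersion(matrix(c(150, NA, NA, NA), 2, 2),
                      pixel_pitch_mm = 0.31)
  expect_true(is.na(d$dispersion))
  expect_equal(d$n_pixels, 1)
})

test_that("protocol deltas report window means, differences and percent
           change", {
  t <- seq(0, 100, by = 1)
  x <- ifelse(t < 50, 180, 149.3)
  pd <- protocol_delta(t, x, c(0, 40), c(60, 100))
  expect_equal(pd$delta, -30.7)
  expect_equal(pd$baseline_value, 180)

  y <- ifelse(t < 50, 300, 172.2)
  pi <- protocol_delta(t, y, c(0, 40), c(60, 100))
  expect_equal(pi$pct_change, -42.6)

  same <- protocol_delta(t, x, c(0, 40), c(0, 40))
  expect_equal(same$delta, 0)
  expect_equal(same$pct_change, 0)
  expect_error(protocol_delta(t, x, c(0, 40), c(200, 300)), "empty window")
})
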