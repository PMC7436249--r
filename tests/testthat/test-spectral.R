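test_that("zero input gives a zero spectrum in both estimators", {
  z <- rep(0, 32)
  expect_true(all(ndct(z, fs = 100, M = 64)$magnitude == 0))
  expect_true(all(fft_spectrum(z, fs = 100, M = 64)$magnitude == 0))
})

test_that("fast cosine projection equals the direct summation", {
  set.seed(11)
  for (case in list(c(L = 16, M = 128), c(L = 64, M = 512),
                    c(L = 33, M = 256))) {
    z <- rnorm(case["L"])
    fast <- ndct(z, fs = 100, M = case["M"])$magnitude
    direct <- ndct_direct(z, case["M"])
    expect_lt(max(abs(fast - direct)) / max(direct), 1e-9)
  }
})

test_that("an extremum-phased tone peaks on its own frequency", {
  # window-edge leakage biases a bare truncated tone by a few mHz; the
  # grid itself resolves ~0.8 mHz
  t <- (0:499) / 100
  sp <- ndct(cos(2 * pi * 0.4 * t), fs = 100, M = 2^17)
  expect_lt(abs(peak_freq(sp, c(0.05, 0.6)) - 0.4), 0.005)
})

test_that("transform length contracts are enforced", {
  expect_error(ndct(rnorm(600), fs = 100, M = 512), "exceeds")
  expect_error(ndct(rnorm(10), fs = 100, M = 100), "power of two")
})

test_that("a grid-aligned tone concentrates in a single FFT bin", {
  fs <- 64
  L <- 64
  t <- (0:(L - 1)) / fs
  sp <- fft_spectrum(cos(2 * pi * 4 * t), fs = fs, M = L)
  mags <- sp$magnitude
  expect_equal(mags[5], L / 2, tolerance = 1e-9) # bin k = 4
  expect_lt(max(mags[-5]), 1e-9 * L)
})

test_that("grid refinement tightens the peak towards the interference floor", {
  t <- (0:499) / 100
  tone <- cos(2 * pi * 0.37 * t) # off every coarse grid
  errs <- vapply(c(9, 11, 13, 17), function(p) {
    abs(peak_freq(ndct(tone, fs = 100, M = 2^p), c(0.05, 0.6)) - 0.37)
  }, numeric(1))
  # grid quantisation dominates at small M; the windowing interference
  # floor (~2e-3 Hz here) takes over once the grid is fine enough
  expect_true(all(errs <= 100 / 2^c(9, 11, 13, 17) + 2e-3))
  expect_lt(errs[4], errs[1])
})

test_that("spectra scale linearly and peak locations are scale-free", {
  z <- std_residual()
  a <- ndct(z, M = 2^14)
  zz <- z
  zz$z <- 3.7 * zz$z
  b <- ndct(zz, M = 2^14)
  expect_equal(b$magnitude, 3.7 * a$magnitude, tolerance = 1e-12)
  expect_identical(peak_freq(a, c(0.05, 0.6)), peak_freq(b, c(0.05, 0.6)))
})

test_that("high-pass suppresses DC and respiration but passes the heartbeat", {
  fs <- 100
  t <- (0:499) / fs
  dc <- highpass_heartbeat(rep(2, 500), fs = fs)
  expect_lt(sqrt(mean(dc^2)), 1e-2 * 2)
  # steady-state attenuation, measured away from the edge transients
  long_t <- (0:2999) / fs
  resp <- highpass_heartbeat(cos(2 * pi * 0.4 * long_t), fs = fs)
  expect_lt(sqrt(mean(resp[1000:2000]^2)) / sqrt(0.5), 10^(-40 / 20))
  heart <- highpass_heartbeat(cos(2 * pi * 1.3 * long_t), fs = fs)
  expect_lt(abs(sqrt(mean(heart[1000:2000]^2)) / sqrt(0.5) - 1), 0.12)
})

test_that("unmeetable high-pass specs raise a design error", {
  expect_error(highpass_heartbeat(rnorm(1000), fs = 1000), "No realisable")
  expect_error(highpass_heartbeat(rnorm(100), fs = 1.5), "cannot support")
})

test_that("filtered residual peaks inside the heartbeat band at 1.3 Hz", {
  z <- std_residual()
  zh <- highpass_heartbeat(z)
  sp <- ndct(zh, M = 2^17)
  expect_lt(abs(peak_freq(sp, c(0.8, 3)) - 1.3), 0.01)
})

test_that("band-limited peak picking recovers constructed tones", {
  fs <- 100
  t <- (0:499) / fs
  est <- estimate_rates(cos(2 * pi * 0.5 * t), fs = fs)
  expect_lt(abs(est$rr - 0.5), 0.005)
  # two-tone record: 3 mm respiration-like at 0.3 Hz, 1 mm heart-like at 1.5 Hz
  z2 <- 3 * cos(2 * pi * 0.3 * t) + cos(2 * pi * 1.5 * t)
  est2 <- estimate_rates(z2, fs = fs)
  expect_lt(abs(est2$rr - 0.3), 0.005)
  expect_lt(abs(est2$hr - 1.5), 0.005)
  expect_true(est2$rr_prominence > 3 && est2$hr_prominence > 3)
})

test_that("rate estimation contracts hold", {
  expect_error(estimate_rates(rnorm(200), fs = 100), "too short")
  nb <- band_config(resp_band = c(0.101, 0.102))
  expect_error(estimate_rates(rnorm(400), fs = 100, bands = nb, M = 1024),
               "no grid frequency")
})

test_that("rate errors follow the signed-percentage definition", {
  expect_identical(rate_error(0.4, 0.4), 0)
  expect_equal(rate_error(0.393, 0.4), -1.75)
  expect_equal(rate_error(0.646, 0.4), 61.5)
  expect_error(rate_error(0.4, 0), "positive")
})

test_that("average absolute error reproduces the published summaries", {
  expect_equal(average_abs_error(c(61.50, 10.17, 13.71, -16.75)), 25.53,
               tolerance = 0.005)
  expect_equal(average_abs_error(c(2.39, 0.99, -1.07, -0.55)), 1.25,
               tolerance = 0.005)
  expect_identical(average_abs_error(c(0, 0, 0, 0)), 0)
  expect_error(average_abs_error(numeric(0)), "non-empty")
})

test_that("error report appends an average row per band and method", {
  df <- tibble::tibble(
    part = rep(1:4, 2),
    band = rep(c("RR", "HR"), each = 4),
    method = "ndct",
    reference = rep(c(0.4, 1.3), each = 4),
    measured = c(0.4 * (1 + c(-1.75, 0.50, 2.57, -3.75) / 100),
                 1.3 * (1 + c(0.48, 0.42, 0.08, -2.49) / 100))
  )
  rep <- rate_error_report(df)
  avg <- rep[rep$part == "Average", ]
  expect_equal(nrow(avg), 2)
  expect_equal(avg$error_pct[avg$band == "RR"], 2.14, tolerance = 0.005)
  expect_equal(avg$error_pct[avg$band == "HR"], 0.87, tolerance = 0.005)
})
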