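test_that("constant baseband accumulates zero phase", {
  iq <- tibble::tibble(t = (0:49) / 100, I = rep(1, 50), Q = rep(0, 50))
  ph <- dacm_phase(iq)
  expect_identical(ph$phi, rep(0, 50))
})

test_that("DACM tracks the arctangent-unwrap oracle on displacement tones", {
  for (p in list(c(3, 0.4), c(1, 1.3), c(2, 0.5))) {
    iq <- synth_motion(motion_params(m_r = p[1], f_r = p[2], m_h = 0, v = 0)) |>
      synth_baseband()
    ph <- dacm_phase(iq)
    expect_lt(max(abs(ph$phi - unwrap_phase(iq$I, iq$Q))), 1e-3)
  }
})

test_that("DACM bias on a rotating carrier shrinks as O(dtheta^2)", {
  # constant-rate phase rotation accumulates the sin(dtheta) truncation
  # coherently; halving the step must quarter the accumulated error
  errs <- vapply(c(50, 100, 200), function(fs) {
    t <- seq(0, 5 - 1 / fs, by = 1 / fs)
    iq <- tibble::tibble(t = t, I = cos(2 * pi * t), Q = sin(2 * pi * t))
    max(abs(dacm_phase(iq)$phi - unwrap_phase(iq$I, iq$Q)))
  }, numeric(1))
  ratios <- errs[-3] / errs[-1]
  expect_true(all(ratios > 3 & ratios < 5))
  # frozen scale at fs = 100: ~0.021 rad over 5 s
  expect_lt(errs[2], 0.025)
})

test_that("phase scaling inverts the Doppler relation", {
  ph <- tibble::tibble(t = (0:99) / 100, phi = rep(0, 100))
  expect_equal(phase_to_displacement(ph)$x, rep(0, 100))
  cfg <- radar_config()
  x <- sin(2 * pi * 0.4 * (0:99) / 100)
  ph2 <- tibble::tibble(t = (0:99) / 100, phi = 4 * pi * x / cfg$wavelength)
  expect_equal(phase_to_displacement(ph2, cfg)$x, x, tolerance = 1e-12)
  expect_equal(phase_to_displacement(ph2, cfg, offset = -2)$x, x - 2,
               tolerance = 1e-12)
})

test_that("round trip recovers stationary-subject displacement within 0.05 mm", {
  truth <- synth_motion(motion_params(v = 0), duration = 10)
  rec <- truth |> synth_baseband() |> demodulate()
  err <- (rec$x - mean(rec$x)) - (truth$x - mean(truth$x))
  expect_lt(max(abs(err)), 0.05)
})

test_that("body-motion ramp induces a bounded trend-like demodulation bias", {
  # the sin(dtheta) increment truncation accumulates along the 30 mm/s
  # ramp; frozen characterisation: ~0.25 mm over 5 s at fs = 100 Hz,
  # absorbed later by the polynomial reference
  truth <- synth_motion()
  rec <- truth |> synth_baseband() |> demodulate()
  err <- (rec$x - mean(rec$x)) - (truth$x - mean(truth$x))
  expect_gt(max(abs(err)), 0.15)
  expect_lt(max(abs(err)), 0.35)
  # the bias is essentially a smooth trend: a cubic explains almost all of it
  fit <- fit_polynomial(tibble::tibble(t = rec$t, x = err), order = 3)
  expect_lt(sqrt(fit$mse), 0.02)
})

test_that("DACM output is invariant to constant phase offsets", {
  m <- synth_motion()
  a <- synth_baseband(m, radar_config(d0 = 0, residual_phase = 0))
  b <- synth_baseband(m, radar_config(d0 = 700, residual_phase = 1.234))
  expect_equal(dacm_phase(a)$phi, dacm_phase(b)$phi, tolerance = 1e-8)
})

test_that("reversing the motion direction negates the demodulated trend", {
  up <- synth_motion(motion_params(direction = 1)) |>
    synth_baseband() |> demodulate()
  dn <- synth_motion(motion_params(direction = -1)) |>
    synth_baseband() |> demodulate()
  slope <- function(tr) stats::coef(stats::lm(x ~ t, data = tr))[2]
  expect_equal(unname(slope(up)), 30, tolerance = 0.05)
  expect_equal(unname(slope(dn)), -30, tolerance = 0.05)
})

test_that("degenerate baseband samples are rejected by index", {
  iq <- tibble::tibble(t = (0:9) / 100, I = rep(1, 10), Q = rep(0, 10))
  iq$I[4] <- 0
  expect_error(dacm_phase(iq), "index 4")
})
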