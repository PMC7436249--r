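test_that("polynomial fit interpolates data of its own degree", {
  t <- (0:199) / 100
  x <- 2 - 3 * t + 0.5 * t^2 - 0.1 * t^3
  fit <- fit_polynomial(tibble::tibble(t = t, x = x), order = 3)
  expect_lt(fit$mse, 1e-16 * mean(x^2))
  expect_equal(fit$fitted$.fitted, x, tolerance = 1e-9)

  line <- tibble::tibble(t = 0:4, x = c(1, 3, 5, 7, 9))
  lf <- fit_polynomial(line, order = 1)
  expect_equal(lf$fitted$.fitted, line$x, tolerance = 1e-12)
  expect_lt(lf$mse, 1e-20)
})

test_that("fit reports its mean squared error and tidies cleanly", {
  fit <- fit_polynomial(std_trace(), order = 3)
  expect_identical(fit$mse, mean((fit$fitted$.fitted - fit$fitted$x)^2))
  td <- tidy(fit)
  expect_equal(td$term, paste0("p", 0:3))
  expect_equal(nrow(glance(fit)), 1)
  expect_named(augment(fit), c("t", "x", ".fitted", ".resid"))
})

test_that("rank-deficient polynomial designs are refused", {
  short <- tibble::tibble(t = (0:2) / 100, x = rnorm(3))
  expect_error(fit_polynomial(short, order = 3), "rank-deficient")
  expect_error(fit_polynomial(short, order = -1), "non-negative")
})

test_that("LMS cancels a reference identical to the desired signal", {
  set.seed(101)
  r <- rnorm(2000)
  fit <- lms_anc(r, r, anc_config(mu = 0.002, taps = 1, passes = 100))
  expect_lt(abs(fit$weights - 1), 1e-3)
  tail_z <- utils::tail(fit$signals$z, 200)
  expect_lt(mean(abs(tail_z)), 1e-3 * sqrt(mean(r^2)))
})

test_that("converged single-tap weight matches the closed-form Wiener solution", {
  set.seed(202)
  r <- rnorm(3000)
  d <- 2 * r
  fit <- lms_anc(d, r, anc_config(mu = 0.002, taps = 1, passes = 100))
  w_star <- sum(d * r) / sum(r^2) # normal-equation solution on the data
  expect_lt(abs(fit$weights - w_star) / abs(w_star), 0.01)
})

test_that("residual identity z = desired - y holds sample-exactly", {
  fit <- std_anc()
  expect_identical(fit$signals$z,
                   fit$signals$desired - fit$signals$y)
})

test_that("sweep-level mean squared residual is non-increasing until the stop", {
  fit <- std_anc()
  expect_true(all(diff(fit$mse_trajectory) <= 1e-12))
  expect_true(fit$converged)
})

test_that("a pure velocity ramp is cancelled to numerical depth", {
  ramp <- synth_motion(motion_params(m_r = 0, m_h = 0, v = 30))
  fit <- cancel_rbm(ramp, order = 1,
                    config = anc_config(taps = 1, passes = 2000, tol = 1e-12))
  tail_z <- utils::tail(fit$signals$z, 100)
  expect_lt(mean(abs(tail_z)), 1e-6 * max(abs(ramp$x)))
})

test_that("order-3 cancellation leaves the respiration line at 0.4 Hz", {
  z <- std_residual()
  sp <- ndct(z, M = 2^17)
  expect_lt(abs(peak_freq(sp, c(0, 0.6)) - 0.4), std_bin())
  # no linear trend survives in the residual
  slope <- stats::coef(stats::lm(z$z ~ z$t))[2]
  expect_lt(abs(slope), 1) # mm/s, vs 30 mm/s in the input
})

test_that("cubic fit localises the respiration peak better than a line fit", {
  trace <- std_trace()
  err_for <- function(ord) {
    fit <- cancel_rbm(trace, order = ord)
    abs(peak_freq(ndct(fit$signals$z, fs = std_fs, M = 2^17),
                  c(0.05, 0.6)) - 0.4)
  }
  expect_lt(err_for(3), err_for(1))
})

test_that("motion direction barely affects the cancelled spectrum", {
  # with the canceller at its optimum the ramp sign is fully absorbed by
  # the reference fit; only the demodulation bias differs
  for (dir in c(1, -1)) {
    tr <- synth_motion(motion_params(direction = dir)) |>
      synth_baseband() |> demodulate()
    fit <- cancel_rbm(tr)
    rr <- peak_freq(ndct(fit$signals$z, fs = std_fs, M = 2^17), c(0.05, 0.6))
    expect_lt(abs(rr - 0.4), 0.01)
  }
  # the flip is likewise absorbed when cancelling the exact motion
  for (dir in c(1, -1)) {
    fit <- cancel_rbm(synth_motion(motion_params(direction = dir)))
    rr <- peak_freq(ndct(fit$signals$z, fs = std_fs, M = 2^17), c(0.05, 0.6))
    expect_lt(abs(rr - 0.4), 0.01)
  }
})

test_that("diverging step sizes are reported, unstable ones warned about", {
  set.seed(5)
  r <- rnorm(500)
  expect_warning(try(lms_anc(r, r, anc_config(mu = 0.2, taps = 8)),
                     silent = TRUE), "unstable")
  expect_error(
    suppressWarnings(lms_anc(2 * r, r, anc_config(mu = 5, taps = 8))),
    "diverged")
})

test_that("anc glance and tidy expose the adaptation summary", {
  fit <- std_anc()
  g <- glance(fit)
  expect_equal(g$taps, 8L)
  expect_equal(g$fit_order, 3L)
  expect_equal(nrow(tidy(fit)), 8)
  expect_named(augment(fit), c("t", "desired", "reference", "y", "z"))
})
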