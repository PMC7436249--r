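#' Polynomial fit of a displacement record
#'
#' Least-squares fit of \eqn{x_f(n) = \sum_{i=0}^{Y} p_i n^i} to a
#' displacement trace, used to construct the body-motion reference for the
#' adaptive canceller. The index variable is centred and rescaled to
#' \eqn{[-1, 1]} internally before the Vandermonde solve — fitting raw
#' sample indices up to several hundred at orders 4–5 is numerically
#' hostile — and the coefficients are reported in that normalised basis;
#' fitted values are basis-independent.
#'
#' @param trace Data frame with columns `t` and `x` (mm).
#' @param order Polynomial order \eqn{Y \ge 0}; must be below the number
#'   of samples.
#'
#' @return An object of class `poly_fit` with elements `order`,
#'   `coefficients` (named `p0`..`pY`, normalised-index basis), `mse`
#'   (mm^2, the mean squared fit error), `n`, and `fitted`, a tibble
#'   `t`, `x`, `.fitted`, `.resid`. Supports [tidy()], [glance()] and
#'   [augment()].
#' @examples
#' fit <- synth_motion() |> fit_polynomial(order = 3)
#' glance(fit)
#' @export
fit_polynomial <- function(trace, order = 3) {
  sig <- as_signal(trace, col = if ("x" %in% names(trace)) "x" else NULL)
  n <- length(sig$x)
  if (order < 0 || order != round(order))
    abort("`order` must be a non-negative integer.")
  if (n <= order)
    abort(sprintf(
      "Cannot fit order %d with only %d samples (rank-deficient design).",
      order, n))
  s <- seq(-1, 1, length.out = n)
  fit <- if (order == 0) {
    stats::lm(sig$x ~ 1)
  } else {
    stats::lm(sig$x ~ stats::poly(s, degree = order, raw = TRUE))
  }
  fitted_x <- unname(stats::fitted(fit))
  coefs <- unname(stats::coef(fit))
  coefs[is.na(coefs)] <- 0
  names(coefs) <- paste0("p", 0:order)
  structure(
    list(
      order = as.integer(order),
      coefficients = coefs,
      mse = mean((fitted_x - sig$x)^2),
      n = n,
      fitted = signal_tibble(sig$t, sig$fs, x = sig$x,
                             .fitted = fitted_x,
                             .resid = sig$x - fitted_x)
    ),
    class = "poly_fit"
  )
}

#' LMS adaptive noise cancellation
#'
#' Runs the adaptive-noise-cancellation loop: at each sample the filter
#' output is \eqn{y(n) = \mathbf{w}(n)^T \mathbf{x}_f(n)} over the lagged
#' (zero-padded) reference window, the residual is
#' \eqn{z(n) = \hat x(n) - y(n)}, and the weights update as
#' \eqn{\mathbf{w}(n+1) = \mathbf{w}(n) + 2\mu\,\mathbf{x}_f(n) z(n)}.
#' The record is swept repeatedly with weights carried over; sweeping
#' stops once the sweep-level mean of \eqn{z^2} stops decreasing by more
#' than `config$tol` (relative), i.e. at the minimum of the residual mean
#' square. The reference is normalised to unit power internally so the
#' step size is scale-free; reported weights are rescaled back to the
#' original reference units.
#'
#' The identity `z = desired - y` holds sample-exactly regardless of
#' convergence; `glance()` reports whether the stopping rule triggered.
#'
#' @param desired Data frame (`t`, `x`) or numeric vector: the demodulated
#'   displacement \eqn{\hat x}.
#' @param reference Same shape: the constructed body-motion reference
#'   \eqn{x_f}, typically a [fit_polynomial()] fitted trace.
#' @param config An [anc_config()].
#'
#' @return An object of class `anc_fit`: `signals` (tibble `t`,
#'   `desired`, `reference`, `y`, `z`, all mm), `weights`, `mu`, `taps`,
#'   `passes` (sweeps actually run), `mse_trajectory` (per-sweep mean
#'   \eqn{z^2}), `converged`. Supports [tidy()], [glance()], [augment()].
#' @export
lms_anc <- function(desired, reference, config = anc_config()) {
  stopifnot(inherits(config, "anc_config"))
  # bare vectors carry no time base; index time (fs = 1) is fine for the
  # adaptation itself and keeps the returned signal table well-formed
  if (is.numeric(desired) && is.null(attr(desired, "fs")))
    attr(desired, "fs") <- 1
  d <- as_signal(desired, col = if (is.data.frame(desired) && "x" %in% names(desired)) "x" else NULL)
  r <- as_signal(reference,
                 fs = d$fs,
                 col = if (is.data.frame(reference) && ".fitted" %in% names(reference)) ".fitted"
                       else if (is.data.frame(reference) && "x" %in% names(reference)) "x"
                       else NULL)
  if (length(d$x) != length(r$x))
    abort("`desired` and `reference` must have equal length.")
  check_finite(d$x, "Desired signal")
  check_finite(r$x, "Reference signal")
  rms <- sqrt(mean(r$x^2))
  scale <- if (rms > 0) rms else 1
  rn <- r$x / scale
  if (config$mu * config$taps * mean(rn^2) >= 1)
    warn(sprintf(
      "mu * taps * reference power = %.3g >= 1: LMS may be unstable.",
      config$mu * config$taps * mean(rn^2)))
  w0 <- config$w_init %||% numeric(config$taps)
  res <- .lms_sweeps(d$x, rn, as.numeric(w0), config$mu, config$taps,
                     config$passes, config$tol)
  if (res$diverged)
    abort(sprintf(
      "LMS weights diverged (non-finite) at mu = %.3g; reduce the step size.",
      config$mu))
  structure(
    list(
      signals = signal_tibble(d$t, d$fs, desired = d$x, reference = r$x,
                              y = res$y, z = res$z),
      weights = res$w / scale,
      mu = config$mu,
      taps = config$taps,
      passes = length(res$mse_trajectory),
      mse_trajectory = res$mse_trajectory,
      converged = res$converged,
      config = config
    ),
    class = "anc_fit"
  )
}

#' Cancel random body movement from a displacement record
#'
#' The composed canceller: [fit_polynomial()] builds the body-motion
#' reference from the record itself, then [lms_anc()] removes it
#' adaptively. The residual `z` is the vital-sign estimate
#' \eqn{x_r + x_h}.
#'
#' @param trace Data frame with columns `t`, `x`: demodulated
#'   displacement.
#' @param order Polynomial order of the reference fit (3 is the
#'   validated default).
#' @param config An [anc_config()].
#'
#' @return An `anc_fit` (see [lms_anc()]) with the `poly_fit` attached as
#'   element `poly_fit` and the reference column named after the fit.
#' @examples
#' res <- synth_motion() |> synth_baseband() |> demodulate() |> cancel_rbm()
#' glance(res)
#' @export
cancel_rbm <- function(trace, order = 3, config = anc_config()) {
  pf <- fit_polynomial(trace, order = order)
  out <- lms_anc(trace, pf$fitted, config = config)
  out$poly_fit <- pf
  out
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("<poly_fit> order %d, n = %d, mse = %.4g mm^2\n",
              x$order, x$n, x$mse))
  invisible(x)
}

#' @export
print.anc_fit <- function(x, ...) {
  cat(sprintf(
    "<anc_fit> %d taps, mu = %.3g, %d sweep(s)%s, final mean z^2 = %.4g mm^2\n",
    x$taps, x$mu, x$passes,
    if (x$converged) " (converged)" else "",
    utils::tail(x$mse_trajectory, 1)))
  invisible(x)
}

#' Tidiers for RBM-cancellation fits
#'
#' `tidy()` returns per-term (polynomial coefficients) or per-tap (LMS
#' weights) tibbles; `glance()` one-row fit summaries; `augment()` the
#' per-sample signal table.
#'
#' @param x A `poly_fit` or `anc_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @name rbm_tidiers
NULL

#' @rdname rbm_tidiers
#' @method tidy poly_fit
#' @export
tidy.poly_fit <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 degree = 0:x$order,
                 estimate = unname(x$coefficients))
}

#' @rdname rbm_tidiers
#' @method glance poly_fit
#' @export
glance.poly_fit <- function(x, ...) {
  tibble::tibble(order = x$order, mse = x$mse, n = x$n)
}

#' @rdname rbm_tidiers
#' @method augment poly_fit
#' @export
augment.poly_fit <- function(x, ...) x$fitted

#' @rdname rbm_tidiers
#' @method tidy anc_fit
#' @export
tidy.anc_fit <- function(x, ...) {
  tibble::tibble(tap = seq_along(x$weights) - 1, weight = x$weights)
}

#' @rdname rbm_tidiers
#' @method glance anc_fit
#' @export
glance.anc_fit <- function(x, ...) {
  tibble::tibble(
    taps = x$taps, mu = x$mu, passes = x$passes,
    converged = x$converged,
    mse_final = utils::tail(x$mse_trajectory, 1),
    fit_order = if (!is.null(x$poly_fit)) x$poly_fit$order else NA_integer_
  )
}

#' @rdname rbm_tidiers
#' @method augment anc_fit
#' @export
augment.anc_fit <- function(x, ...) x$signals
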