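#' Extended DACM phase extraction
#'
#' Accumulates the Doppler phase from a quadrature pair by the extended
#' differentiate-and-cross-multiply rule
#' \deqn{\varphi(n) = \sum_{m=2}^{n}
#'   \frac{I(m)[Q(m)-Q(m-1)] - [I(m)-I(m-1)]\,Q(m)}{I(m)^2 + Q(m)^2},}
#' with \eqn{\varphi(1) = 0}. Each increment equals \eqn{\sin\Delta\theta}
#' for a unit-amplitude pair, so no explicit unwrapping is needed as long
#' as the per-sample phase step stays well below \eqn{\pi}. The output is
#' the phase *relative* to the first sample; the constant
#' \eqn{4\pi d_0/\lambda + \phi} is unobservable.
#'
#' @param iq Data frame with columns `t`, `I`, `Q` (see
#'   [synth_baseband()] / [read_iq_csv()]).
#' @param floor Samples with \eqn{I^2 + Q^2} below this value are treated
#'   as numerically dead and raise an error naming the sample index.
#'
#' @return A tibble with columns `t` and `phi` (rad), `fs` attribute
#'   preserved.
#' @export
dacm_phase <- function(iq, floor = 1e-12) {
  stopifnot(all(c("I", "Q") %in% names(iq)))
  fs <- sampling_rate(iq)
  i <- iq$I
  q <- iq$Q
  n <- length(i)
  if (n < 2) abort("Need at least 2 samples to accumulate phase.")
  if (length(q) != n) abort("`I` and `Q` must have equal length.")
  p <- i^2 + q^2
  dead <- which(p < floor)
  if (length(dead))
    abort(sprintf(
      "Degenerate baseband sample at index %d: I^2 + Q^2 = %.3g below floor %.3g.",
      dead[1], p[dead[1]], floor))
  inc <- (i[-1] * diff(q) - diff(i) * q[-1]) / p[-1]
  tt <- if ("t" %in% names(iq)) iq$t else (seq_len(n) - 1) / fs
  signal_tibble(tt, fs, phi = c(0, cumsum(inc)))
}

#' Convert accumulated phase to displacement
#'
#' Scales a DACM phase trace by \eqn{\lambda / 4\pi} to millimetres:
#' \eqn{\hat x(n) = \varphi(n)\,\lambda/4\pi + \mathrm{offset}}. Because
#' the DACM phase is relative, the result is displacement relative to the
#' first sample (\eqn{\hat x(1) = 0}); `offset` merely re-bases the
#' reported values (e.g. `-d0` to quote range decrease) and is not an
#' estimate of absolute range.
#'
#' @param phase Data frame with columns `t`, `phi` from [dacm_phase()].
#' @param radar A [radar_config()] supplying the wavelength.
#' @param offset Additive reporting offset in mm.
#'
#' @return A tibble with columns `t` and `x` (mm).
#' @export
phase_to_displacement <- function(phase, radar = radar_config(), offset = 0) {
  stopifnot(inherits(radar, "radar_config"), "phi" %in% names(phase))
  fs <- sampling_rate(phase)
  signal_tibble(phase$t, fs,
                x = phase$phi * radar$wavelength / (4 * pi) + offset)
}

#' Demodulate a quadrature frame to displacement
#'
#' Convenience composition of [dacm_phase()] and
#' [phase_to_displacement()].
#'
#' @inheritParams dacm_phase
#' @inheritParams phase_to_displacement
#' @return A tibble with columns `t` and `x` (mm, relative to the first
#'   sample).
#' @examples
#' motion <- synth_motion()
#' rec <- motion |> synth_baseband() |> demodulate()
#' max(abs((rec$x - mean(rec$x)) - (motion$x - mean(motion$x)))) # small
#' @export
demodulate <- function(iq, radar = radar_config(), offset = 0, floor = 1e-12) {
  phase_to_displacement(dacm_phase(iq, floor = floor), radar, offset = offset)
}
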