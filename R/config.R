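#' Radar front-end description
#'
#' Collects the constants of the CW Doppler link: carrier frequency (the
#' wavelength is derived as \eqn{\lambda = c/f}), nominal subject distance,
#' the residual phase left after range correlation, and the baseband
#' sampling rate. Displacements and the wavelength are carried in
#' millimetres throughout the package.
#'
#' @param carrier_freq Transmit frequency in Hz. Default 10 GHz, the
#'   highest-sensitivity operating point of the reference instrument.
#' @param d0 Nominal initial distance radar-to-subject in mm. Only enters
#'   the absolute baseband phase; DACM demodulation cannot recover it.
#' @param residual_phase Constant residual phase in rad (treated as
#'   ignorable by range-correlation at short range).
#' @param fs Baseband sampling rate in Hz.
#'
#' @return An object of class `radar_config`: a list with fields
#'   `carrier_freq`, `wavelength` (mm), `d0`, `residual_phase`, `fs`.
#' @examples
#' radar_config()$wavelength # ~29.98 mm at 10 GHz
#' @export
radar_config <- function(carrier_freq = 10e9, d0 = 0, residual_phase = 0,
                         fs = 100) {
  if (!is.numeric(carrier_freq) || carrier_freq <= 0)
    abort("`carrier_freq` must be a positive frequency in Hz.")
  if (!is.numeric(fs) || fs <= 0)
    abort("`fs` must be a positive sampling rate in Hz.")
  if (!is.numeric(d0) || d0 < 0)
    abort("`d0` must be a non-negative distance in mm.")
  structure(
    list(
      carrier_freq   = carrier_freq,
      wavelength     = speed_of_light_mm() / carrier_freq,
      d0             = d0,
      residual_phase = residual_phase,
      fs             = fs
    ),
    class = "radar_config"
  )
}

# speed of light in mm/s; single source of truth for the lambda = c/f link
speed_of_light_mm <- function() 299792458 * 1e3

#' Chest-motion model parameters
#'
#' Parameters of the standard simulation model
#' \eqn{x(t) = m_r \sin(2\pi f_r t + \phi_0) + m_h \sin(2\pi f_h t + \phi_0)
#' \pm v t}: sinusoidal respiration and heartbeat riding on a
#' constant-velocity body translation whose sign encodes the motion
#' direction (positive when moving away from the radar).
#'
#' Defaults are the simulation conditions used to validate the method:
#' 3 mm respiration at 0.4 Hz, 1 mm heartbeat at 1.3 Hz, 30 mm/s body
#' velocity. `phase` is the initial phase of both vital components; the
#' default `pi/2` starts each component at an extremum of its cycle, the
#' convention under which the cosine-projection spectrum (see [ndct()])
#' attains its nominal peak accuracy (see the package vignette for why a
#' quarter-cycle offset degrades any cosine-kernel estimator).
#'
#' @param m_r,f_r Respiration amplitude (mm) and frequency (Hz).
#' @param m_h,f_h Heartbeat amplitude (mm) and frequency (Hz).
#' @param v Body-motion speed in mm/s (magnitude).
#' @param direction `+1` when the subject moves away from the radar,
#'   `-1` towards it.
#' @param phase Initial phase of the vital components in rad.
#'
#' @return An object of class `motion_params`.
#' @export
motion_params <- function(m_r = 3, f_r = 0.4, m_h = 1, f_h = 1.3,
                          v = 30, direction = 1, phase = pi / 2) {
  if (m_r < 0 || m_h < 0)
    abort("Amplitudes `m_r` and `m_h` must be non-negative (mm).")
  if (f_r <= 0 || f_h <= 0)
    abort("Frequencies `f_r` and `f_h` must be positive (Hz).")
  if (!direction %in% c(-1, 1))
    abort("`direction` must be +1 (away from radar) or -1 (towards).")
  structure(
    list(m_r = m_r, f_r = f_r, m_h = m_h, f_h = f_h,
         v = v, direction = direction, phase = phase),
    class = "motion_params"
  )
}

#' Adaptive-noise-cancellation settings
#'
#' Settings of the LMS adaptive filter used by [lms_anc()]. The reference
#' input is normalised to unit power internally, so one step size works
#' across displacement scales; `mu` is quoted in that normalised unit.
#'
#' The default step size keeps the weight adaptation quasi-static over a
#' record: the adaptation time constant \eqn{1/(2\mu\,\mathrm{taps})}
#' (about 1250 samples at the defaults) is several respiration periods, so
#' the filter converges across sweeps to the static minimum-mean-square
#' (Wiener) solution instead of tracking — and thereby cancelling — the
#' vital-sign oscillation within a sweep. Sweeps stop early once the
#' sweep-level mean of \eqn{z^2} stops improving by more than `tol`
#' (relative), i.e. once the mean square of the residual has reached its
#' minimum.
#'
#' @param mu LMS step size (dimensionless, for a unit-power reference).
#' @param taps Filter length in samples.
#' @param passes Maximum number of sweeps over the record.
#' @param tol Relative improvement of sweep-level mean squared residual
#'   below which adaptation stops.
#' @param w_init Initial tap weights; default all zero.
#'
#' @return An object of class `anc_config`.
#' @export
anc_config <- function(mu = 5e-5, taps = 8, passes = 500, tol = 1e-6,
                       w_init = NULL) {
  if (mu <= 0) abort("`mu` must be positive.")
  if (taps < 1 || taps != round(taps)) abort("`taps` must be an integer >= 1.")
  if (passes < 1) abort("`passes` must be >= 1.")
  if (!is.null(w_init) && length(w_init) != taps)
    abort("`w_init` must have length `taps`.")
  structure(
    list(mu = mu, taps = as.integer(taps), passes = as.integer(passes),
         tol = tol, w_init = w_init),
    class = "anc_config"
  )
}

#' Frequency bands and heartbeat pre-filter
#'
#' Band limits for peak picking and the specification of the zero-phase
#' high-pass applied before heartbeat estimation. Respiration typically
#' lies below 0.6 Hz and the heartbeat within 0.8–3 Hz; the high-pass
#' edges (stop 0.7 Hz, pass 0.9 Hz) remove the respiration fundamental
#' from the heartbeat band. The lower respiration edge is kept slightly
#' above DC (0.05 Hz) so residual drift does not masquerade as a
#' breathing peak.
#'
#' Attenuation/ripple are requirements on the *zero-phase* (forward and
#' backward filtered) magnitude response.
#'
#' @param resp_band,heart_band Two-element Hz intervals.
#' @param hp_fstop,hp_fpass High-pass stopband and passband edges in Hz.
#' @param hp_stop_atten Minimum stopband attenuation in dB.
#' @param hp_pass_ripple Maximum passband deviation in dB.
#'
#' @return An object of class `band_config`.
#' @export
band_config <- function(resp_band = c(0.05, 0.6), heart_band = c(0.8, 3.0),
                        hp_fstop = 0.7, hp_fpass = 0.9,
                        hp_stop_atten = 40, hp_pass_ripple = 1) {
  for (b in list(resp_band, heart_band)) {
    if (length(b) != 2 || b[1] < 0 || b[1] >= b[2])
      abort("Bands must be increasing two-element Hz intervals.")
  }
  if (hp_fstop >= hp_fpass)
    abort("`hp_fstop` must lie below `hp_fpass`.")
  structure(
    list(resp_band = resp_band, heart_band = heart_band,
         hp_fstop = hp_fstop, hp_fpass = hp_fpass,
         hp_stop_atten = hp_stop_atten, hp_pass_ripple = hp_pass_ripple),
    class = "band_config"
  )
}

#' Direction-segmentation settings
#'
#' Controls for [segment_by_direction()]. The smoothing window suppresses
#' the mm-scale vital ripple when the derivative sign is taken;
#' `min_duration` merges spuriously short runs (hysteresis) and
#' `max_duration` caps segment length so each part stays inside the
#' short-time window over which body velocity can be treated as constant
#' (3–5 s). Defaults target roughly 3-s parts.
#'
#' @param smooth_window Moving-average width for the derivative, seconds.
#' @param min_duration Minimum accepted segment length, seconds.
#' @param max_duration Maximum segment length before splitting, seconds.
#'
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(smooth_window = 1, min_duration = 2,
                                max_duration = 3.5) {
  if (min_duration <= 0 || min_duration > max_duration)
    abort("Need 0 < `min_duration` <= `max_duration`.")
  if (smooth_window <= 0)
    abort("`smooth_window` must be positive (seconds).")
  structure(
    list(smooth_window = smooth_window, min_duration = min_duration,
         max_duration = max_duration),
    class = "segmentation_config"
  )
}

#' Whole-pipeline configuration
#'
#' Bundles every stage's settings for [run_simulation_demo()] and
#' [run_record_pipeline()]. Polynomial orders 3–4 are the validated
#' choices for the reference fit; other orders are accepted with a
#' warning.
#'
#' @param radar A [radar_config()].
#' @param bands A [band_config()].
#' @param anc An [anc_config()].
#' @param fit_order Polynomial order of the body-motion reference fit.
#' @param seg A [segmentation_config()].
#' @param method Spectrum estimator for rate extraction, `"ndct"` or
#'   `"fft"`.
#' @param M Transform length (power of two) for the zero-padded spectra.
#' @param window Analysis window length in seconds.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(radar = radar_config(), bands = band_config(),
                            anc = anc_config(), fit_order = 3,
                            seg = segmentation_config(),
                            method = c("ndct", "fft"),
                            M = 2^17, window = 5) {
  method <- match.arg(method)
  if (fit_order < 1 || fit_order > 5)
    abort("`fit_order` must lie in 1..5.")
  if (!fit_order %in% c(3, 4))
    warn(sprintf(
      "fit_order = %d is outside the validated orders {3, 4}.", fit_order))
  check_transform_length(M)
  structure(
    list(radar = radar, bands = bands, anc = anc,
         fit_order = as.integer(fit_order), seg = seg,
         method = method, M = M, window = window),
    class = "pipeline_config"
  )
}

check_transform_length <- function(M) {
  if (length(M) != 1 || !is.numeric(M) || M < 2 ||
      abs(log2(M) - round(log2(M))) > 1e-9)
    abort("`M` must be a single power of two (the fast transform path requires it).")
  invisible(M)
}

#' @export
print.radar_config <- function(x, ...) {
  cat(sprintf(
    "<radar_config> %.3g GHz carrier (lambda %.4f mm), d0 %.4g mm, fs %g Hz\n",
    x$carrier_freq / 1e9, x$wavelength, x$d0, x$fs))
  invisible(x)
}

#' @export
print.motion_params <- function(x, ...) {
  cat(sprintf(
    "<motion_params> resp %.3g mm @ %.3g Hz, heart %.3g mm @ %.3g Hz, body %+.3g mm/s\n",
    x$m_r, x$f_r, x$m_h, x$f_h, x$direction * x$v))
  invisible(x)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf(
    "<pipeline_config> %s spectrum, M = 2^%d, order-%d reference fit, %g s window\n",
    toupper(x$method), round(log2(x$M)), x$fit_order, x$window))
  invisible(x)
}

# Flatten any of the config objects above to a named list of scalars for
# report echoing (keys are <block>.<field>).
flatten_config <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  blocks <- list(radar = cfg$radar, bands = cfg$bands, anc = cfg$anc,
                 seg = cfg$seg)
  out <- list(method = cfg$method, M = cfg$M,
              fit_order = cfg$fit_order, window = cfg$window)
  for (bn in names(blocks)) {
    b <- unclass(blocks[[bn]])
    b <- b[!vapply(b, is.null, logical(1))]
    names(b) <- paste(bn, names(b), sep = ".")
    out <- c(out, b)
  }
  out
}
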