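#' Cosine-projection (N-DCT) spectrum
#'
#' Computes the M-point cosine-projection spectrum of an L-sample signal,
#' \deqn{X[k] = 2 \sum_{n=0}^{L-1} z(n) \cos(2\pi k n / M),}
#' reported as magnitudes \eqn{|X[k]|} on the grid \eqn{f_k = k f_s / M},
#' \eqn{k = 0..M/2}. The sum is evaluated fast as twice the real part of
#' the M-point zero-padded discrete Fourier transform, which is
#' algebraically identical to the direct summation. Zero padding
#' (\eqn{M \gg L}) refines the frequency grid without adding resolution.
#'
#' Relative to the plain FFT magnitude, the cosine projection behaves as
#' the spectrum of the even extension of the record about its first
#' sample: a component at an extremum of its cycle at \eqn{n = 0} is
#' extended coherently over \eqn{2L} samples and shows a main lobe about
#' half as wide. The price is phase sensitivity — see the vignette.
#' Magnitudes are reported (rather than the signed projection) so peak
#' locations do not depend on component sign.
#'
#' @param signal Data frame (`t` plus one value column) or numeric
#'   vector.
#' @param fs Sampling rate in Hz (required for bare vectors).
#' @param M Transform length, a power of two with `M >= L`.
#'
#' @return A `vital_spectrum` tibble with columns `freq_hz`, `magnitude`
#'   (length `M/2 + 1`) and attributes `method`, `M`, `L`, `fs`.
#' @examples
#' sp <- ndct(synth_motion(motion_params(v = 0)), M = 2^14)
#' sp$freq_hz[which.max(sp$magnitude)] # respiration at 0.4 Hz
#' @export
ndct <- function(signal, fs = NULL, M = 2^17) {
  spectrum_core(signal, fs, M, method = "ndct")
}

#' Zero-padded FFT magnitude spectrum
#'
#' The conventional baseline: magnitude of the M-point zero-padded DFT on
#' the same frequency grid as [ndct()].
#'
#' @inheritParams ndct
#' @return A `vital_spectrum` tibble (see [ndct()]).
#' @export
fft_spectrum <- function(signal, fs = NULL, M = 2^17) {
  spectrum_core(signal, fs, M, method = "fft")
}

spectrum_core <- function(signal, fs, M, method) {
  sig <- as_signal(signal, fs = fs)
  check_transform_length(M)
  L <- length(sig$x)
  if (L > M)
    abort(sprintf("Sample length L = %d exceeds transform length M = %d.", L, M))
  check_finite(sig$x, "Signal")
  zp <- c(sig$x, rep(0, M - L))
  X <- stats::fft(zp)[seq_len(M / 2 + 1)]
  mag <- switch(method,
    ndct = abs(2 * Re(X)),
    fft  = Mod(X)
  )
  out <- tibble::tibble(
    freq_hz = (0:(M / 2)) * sig$fs / M,
    magnitude = mag
  )
  class(out) <- c("vital_spectrum", class(out))
  attr(out, "method") <- method
  attr(out, "M") <- M
  attr(out, "L") <- L
  attr(out, "fs") <- sig$fs
  out
}

#' Zero-phase high-pass for the heartbeat band
#'
#' Removes the respiration fundamental before heartbeat peak picking. The
#' filter is a Chebyshev type-II high-pass applied forward and backward
#' (zero phase); the order is chosen as the smallest (4..8) whose
#' zero-phase magnitude response attains at least `hp_stop_atten` dB at
#' `hp_fstop` and at most `hp_pass_ripple` dB deviation at `hp_fpass`.
#' Edge transients are controlled by odd-reflection padding of one record
#' length at both ends; output length equals input length.
#'
#' @param signal Data frame (`t` + value column) or numeric vector.
#' @param bands A [band_config()] holding the edge frequencies and
#'   tolerances.
#' @param fs Sampling rate in Hz (for bare vectors).
#'
#' @return The filtered signal in the same shape as the input (tibble in,
#'   tibble out with the value column replaced; vector in, vector out).
#' @export
highpass_heartbeat <- function(signal, bands = band_config(), fs = NULL) {
  stopifnot(inherits(bands, "band_config"))
  sig <- as_signal(signal, fs = fs)
  if (sig$fs <= 2 * bands$hp_fpass)
    abort(sprintf(
      "fs = %.3g Hz cannot support a high-pass with passband edge %.3g Hz.",
      sig$fs, bands$hp_fpass))
  flt <- design_highpass(bands, sig$fs)
  x <- sig$x
  L <- length(x)
  # odd (point-symmetric) reflection about both endpoints avoids the step
  # transient a zero-padded IIR start-up would inject at these low edges
  pad <- L - 1
  left <- 2 * x[1] - x[seq(pad + 1, 2)]
  right <- 2 * x[L] - x[seq(L - 1, L - pad)]
  yf <- signal::filtfilt(flt, c(left, x, right))
  y <- yf[seq(pad + 1, pad + L)]
  if (is.numeric(signal) && !is.data.frame(signal)) return(y)
  out <- signal
  out[[sig$col]] <- y
  attr(out, "fs") <- sig$fs
  out
}

# Smallest Chebyshev-II high-pass meeting the zero-phase spec at this fs.
design_highpass <- function(bands, fs) {
  w_stop <- bands$hp_fstop / (fs / 2)
  grid <- seq(0, fs / 2, length.out = 4097)
  for (ord in 4:8) {
    # design stopband depth: half the overall requirement plus margin,
    # since forward-backward filtering doubles attenuation in dB
    for (rs in c(bands$hp_stop_atten / 2 + 3, bands$hp_stop_atten / 2 + 6)) {
      flt <- signal::cheby2(ord, Rp = rs, W = w_stop, type = "high")
      h2 <- freq_response_db(flt, grid, fs) * 2
      stop_ok <- all(h2[grid <= bands$hp_fstop] <= -bands$hp_stop_atten)
      pass_ok <- all(abs(h2[grid >= bands$hp_fpass]) <= bands$hp_pass_ripple)
      stable <- max(Mod(polyroot(rev(flt$a)))) < 1
      if (stop_ok && pass_ok && stable) return(flt)
    }
  }
  abort(sprintf(
    "No realisable high-pass meets %g dB / %g dB at edges %g-%g Hz for fs = %g Hz.",
    bands$hp_stop_atten, bands$hp_pass_ripple, bands$hp_fstop,
    bands$hp_fpass, fs))
}

freq_response_db <- function(flt, f_hz, fs) {
  w <- 2 * pi * f_hz / fs
  ew <- exp(-1i * outer(w, seq_along(flt$b) - 1))
  num <- drop(ew %*% flt$b)
  ew <- exp(-1i * outer(w, seq_along(flt$a) - 1))
  den <- drop(ew %*% flt$a)
  20 * log10(pmax(Mod(num / den), 1e-12))
}

#' Estimate respiration and heartbeat rates
#'
#' Band-limited peak picking on the RBM-cancelled residual: the
#' respiration rate is the argmax frequency of the chosen spectrum within
#' `resp_band` on the raw residual; the heartbeat rate is the argmax
#' within `heart_band` after [highpass_heartbeat()]. Grid ties break
#' toward the lower frequency. Each peak also gets a prominence value
#' (peak over in-band median magnitude) so callers can flag records with
#' no credible component (see [run_record_pipeline()]).
#'
#' @param z Data frame (`t` + value column) or numeric vector: the
#'   vital-sign residual. At least 3 s of samples are required.
#' @param bands A [band_config()].
#' @param method `"ndct"` (default) or `"fft"`.
#' @param M Transform length (power of two).
#' @param fs Sampling rate in Hz (for bare vectors).
#'
#' @return A one-row `rate_estimate` tibble with columns `rr`, `hr` (Hz),
#'   `rr_peak`, `hr_peak` (spectrum units), `rr_prominence`,
#'   `hr_prominence`, `rr_amplitude`, `hr_amplitude` (implied component
#'   amplitude, mm), `method`, `window` (s). The respiration and
#'   heartbeat spectra are attached as attribute `spectra`.
#' @examples
#' synth_motion(motion_params(v = 0)) |> estimate_rates(M = 2^14)
#' @export
estimate_rates <- function(z, bands = band_config(),
                           method = c("ndct", "fft"), M = 2^17, fs = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(bands, "band_config"))
  sig <- as_signal(z, fs = fs)
  window_s <- length(sig$x) / sig$fs
  if (window_s < 3)
    abort(sprintf(
      "Window of %.2f s is too short for rate estimation (need >= 3 s).",
      window_s))
  spec_fun <- if (method == "ndct") ndct else fft_spectrum
  resp_spec <- spec_fun(sig$x, fs = sig$fs, M = M)
  heart_sig <- highpass_heartbeat(sig$x, bands = bands, fs = sig$fs)
  heart_spec <- spec_fun(heart_sig, fs = sig$fs, M = M)
  rp <- band_peak(resp_spec, bands$resp_band)
  hp <- band_peak(heart_spec, bands$heart_band)
  # implied component amplitude in mm: a cosine-phased tone of amplitude a
  # peaks at ~a*L in the cosine projection and ~a*L/2 in the FFT magnitude
  amp_scale <- if (method == "ndct") 1 else 2
  L <- length(sig$x)
  out <- tibble::tibble(
    rr = rp$freq, hr = hp$freq,
    rr_peak = rp$value, hr_peak = hp$value,
    rr_prominence = rp$prominence, hr_prominence = hp$prominence,
    rr_amplitude = amp_scale * rp$value / L,
    hr_amplitude = amp_scale * hp$value / L,
    method = method, window = window_s
  )
  class(out) <- c("rate_estimate", class(out))
  attr(out, "spectra") <- list(resp = resp_spec, heart = heart_spec)
  attr(out, "bands") <- bands
  out
}

band_peak <- function(spec, band) {
  in_band <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  if (!any(in_band))
    abort(sprintf(
      "Band [%.3g, %.3g] Hz contains no grid frequency.", band[1], band[2]))
  f <- spec$freq_hz[in_band]
  v <- spec$magnitude[in_band]
  k <- which.max(v) # first maximum: ties resolve to the lower frequency
  med <- stats::median(v)
  list(freq = f[k], value = v[k],
       prominence = if (med > 0) v[k] / med else Inf)
}

#' Rate measurement error
#'
#' Signed relative error of a measured rate against its reference,
#' \eqn{(R_{measure} - R_{ref})/R_{ref} \times 100\%}, and the average of
#' absolute per-part errors used to summarise multi-part experiments
#' (with four parts this is the printed "Average error" convention).
#'
#' @param measured,reference Rates in Hz (vectorised; `reference` must be
#'   positive).
#' @return `rate_error()`: signed percentages. `average_abs_error()`: the
#'   mean of absolute errors, in percent.
#' @examples
#' rate_error(0.393, 0.4)
#' average_abs_error(c(61.50, 10.17, 13.71, -16.75))
#' @export
rate_error <- function(measured, reference) {
  if (any(reference <= 0))
    abort("`reference` rates must be positive.")
  (measured - reference) / reference * 100
}

#' @rdname rate_error
#' @param errors Signed per-part errors in percent.
#' @export
average_abs_error <- function(errors) {
  if (length(errors) == 0) abort("`errors` must be non-empty.")
  mean(abs(errors))
}

#' Tabulate per-part rate errors
#'
#' Builds a long-format error table from per-part measured and reference
#' rates — the layout used to compare estimators across experiment parts
#' — appending one `Average` row per method/band group with the mean
#' absolute error.
#'
#' @param data Data frame with columns `part`, `band` (e.g. `"RR"`,
#'   `"HR"`), `method`, `measured`, `reference` (Hz).
#' @return A tibble with the same grouping columns plus `error_pct`;
#'   average rows carry `part = "Average"` and `NA` rates.
#' @export
rate_error_report <- function(data) {
  need <- c("part", "band", "method", "measured", "reference")
  if (!all(need %in% names(data)))
    abort(sprintf("`data` needs columns: %s.", paste(need, collapse = ", ")))
  per <- data |>
    dplyr::mutate(part = as.character(.data$part),
                  error_pct = rate_error(.data$measured, .data$reference))
  avg <- per |>
    dplyr::group_by(.data$band, .data$method) |>
    dplyr::summarise(error_pct = average_abs_error(.data$error_pct),
                     .groups = "drop") |>
    dplyr::mutate(part = "Average", measured = NA_real_,
                  reference = NA_real_)
  dplyr::bind_rows(per, avg) |>
    dplyr::arrange(.data$band, .data$method) |>
    dplyr::select(dplyr::all_of(c("part", "band", "method", "measured",
                                  "reference", "error_pct")))
}
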