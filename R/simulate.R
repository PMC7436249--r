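#' Synthesize ground-truth chest motion
#'
#' Evaluates the chest-motion model
#' \eqn{x(t) = m_r \sin(2\pi f_r t + \phi_0) +
#' m_h \sin(2\pi f_h t + \phi_0) \pm v t}
#' on a uniform time base starting at \eqn{t_1 = 0}. The linear term is the
#' body translation; its sign is the motion direction relative to the
#' radar.
#'
#' @param params A [motion_params()].
#' @param duration Record length in seconds.
#' @param fs Sampling rate in Hz. Both vital frequencies must lie below
#'   `fs / 2`; synthesis refuses aliased parameter sets.
#'
#' @return A tibble with columns `t` (s) and `x` (mm), carrying `fs` as an
#'   attribute. At the defaults (5 s at 100 Hz) the record has 500 samples.
#' @examples
#' motion <- synth_motion(motion_params(), duration = 5, fs = 100)
#' range(motion$x)
#' @export
synth_motion <- function(params = motion_params(), duration = 5, fs = 100) {
  stopifnot(inherits(params, "motion_params"))
  if (fs <= 0) abort("`fs` must be a positive sampling rate in Hz.")
  if (duration <= 0) abort("`duration` must be positive (seconds).")
  if (params$f_r >= fs / 2 || params$f_h >= fs / 2)
    abort(sprintf(
      "Vital frequencies (%.3g, %.3g Hz) must lie below fs/2 = %.3g Hz.",
      params$f_r, params$f_h, fs / 2))
  n <- round(duration * fs)
  if (n < 2) abort("Record must contain at least 2 samples.")
  t <- (seq_len(n) - 1) / fs
  x <- params$m_r * sin(2 * pi * params$f_r * t + params$phase) +
    params$m_h * sin(2 * pi * params$f_h * t + params$phase) +
    params$direction * params$v * t
  signal_tibble(t, fs, x = x)
}

#' Synthesize quadrature baseband from a displacement trace
#'
#' Maps a displacement record through the Doppler phase model
#' \eqn{\theta(n) = 4\pi d_0/\lambda + 4\pi x(n)/\lambda + \phi} and emits
#' the unit-amplitude quadrature pair \eqn{I = \cos\theta},
#' \eqn{Q = \sin\theta}. Optional additive white Gaussian noise on each
#' channel supports robustness experiments; the physical model itself is
#' noiseless at baseband (`noise_sd = 0`, the default), in which case
#' \eqn{I^2 + Q^2 = 1} at every sample.
#'
#' @param motion Data frame with columns `t` (s) and `x` (mm), e.g. from
#'   [synth_motion()] or [demodulate()].
#' @param radar A [radar_config()]; its `fs` must match the motion time
#'   base.
#' @param noise_sd Standard deviation of the per-channel additive noise
#'   (dimensionless, relative to the unit carrier amplitude).
#' @param seed Optional integer seed making the noise reproducible.
#'
#' @return A tibble with columns `t`, `I`, `Q` and an `fs` attribute.
#' @examples
#' iq <- synth_motion() |> synth_baseband()
#' max(abs(iq$I^2 + iq$Q^2 - 1)) # unit amplitude when noiseless
#' @export
synth_baseband <- function(motion, radar = radar_config(), noise_sd = 0,
                           seed = NULL) {
  stopifnot(inherits(radar, "radar_config"))
  sig <- as_signal(motion, col = "x")
  if (abs(sig$fs - radar$fs) > 1e-6 * radar$fs)
    abort(sprintf(
      "Motion sampling rate (%.6g Hz) does not match radar fs (%.6g Hz).",
      sig$fs, radar$fs))
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  check_finite(sig$x, "Displacement")
  theta <- 4 * pi * radar$d0 / radar$wavelength +
    4 * pi * sig$x / radar$wavelength + radar$residual_phase
  i <- cos(theta)
  q <- sin(theta)
  if (noise_sd > 0) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    i <- i + stats::rnorm(length(i), sd = noise_sd)
    q <- q + stats::rnorm(length(q), sd = noise_sd)
  }
  signal_tibble(sig$t, sig$fs, I = i, Q = q)
}

#' Read and write quadrature baseband CSV
#'
#' The interchange format for recorded or synthetic frames: a CSV with
#' header `t,I,Q` (seconds, dimensionless, dimensionless) plus a YAML
#' sidecar `<path>.yml` holding the acquisition keys (`fs`, and when
#' known `carrier_freq` and `d0`). Reading validates that every cell is
#' numeric and reports the offending line otherwise.
#'
#' @param iq A data frame with columns `t`, `I`, `Q`.
#' @param path CSV file path; the sidecar is written next to it.
#' @param radar Optional [radar_config()] recorded in the sidecar.
#' @return `write_iq_csv()` returns `path` invisibly; `read_iq_csv()`
#'   returns a `t,I,Q` tibble with `fs` (and any sidecar keys) attached
#'   as attributes.
#' @export
write_iq_csv <- function(iq, path, radar = NULL) {
  stopifnot(all(c("t", "I", "Q") %in% names(iq)))
  fs <- sampling_rate(iq)
  readr::write_csv(iq[c("t", "I", "Q")], path)
  meta <- list(fs = fs)
  if (!is.null(radar)) {
    meta$carrier_freq <- radar$carrier_freq
    meta$d0 <- radar$d0
  }
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' @rdname write_iq_csv
#' @export
read_iq_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!all(c("t", "I", "Q") %in% names(raw)))
    abort(sprintf("`%s` must have columns t,I,Q (found: %s).",
                  path, paste(names(raw), collapse = ",")))
  if (length(unique(lengths(raw))) > 1)
    abort("Ragged CSV: unequal column lengths.")
  num <- lapply(raw[c("t", "I", "Q")], function(col) suppressWarnings(as.numeric(col)))
  for (nm in names(num)) {
    bad <- which(is.na(num[[nm]]) & !is.na(raw[[nm]]))
    if (length(bad))
      abort(sprintf("Non-numeric value in column `%s` at data line %d of %s.",
                    nm, bad[1], path))
    if (anyNA(num[[nm]]))
      abort(sprintf("Missing value in column `%s` at data line %d of %s.",
                    nm, which(is.na(num[[nm]]))[1], path))
  }
  out <- tibble::as_tibble(num)
  meta <- if (file.exists(sidecar_path(path))) yaml::read_yaml(sidecar_path(path)) else list()
  attr(out, "fs") <- meta$fs %||% sampling_rate(out)
  for (k in setdiff(names(meta), "fs")) attr(out, k) <- meta[[k]]
  out
}

sidecar_path <- function(path) paste0(path, ".yml")
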