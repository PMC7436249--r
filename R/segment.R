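#' Split a displacement record into direction-consistent parts
#'
#' Back-and-forth body motion violates the constant-velocity assumption
#' behind the polynomial reference, so long records are cut wherever the
#' motion direction flips. The rule: smooth the first difference
#' \eqn{d(n) = (\hat x(n) - \hat x(n-1)) / \Delta t} with a moving
#' average of width `smooth_window` (so the mm-scale vital ripple cannot
#' flip the sign of the cm/s-scale trend), take the derivative sign,
#' merge runs shorter than `min_duration` into their preceding run
#' (hysteresis), and split runs longer than `max_duration` into
#' near-equal contiguous pieces. Each returned segment is labelled with
#' the majority sign of its smoothed derivative.
#'
#' Segments tile the record exactly: contiguous, non-overlapping,
#' covering every sample.
#'
#' @param trace Data frame with columns `t` and `x` (mm).
#' @param config A [segmentation_config()].
#'
#' @return A tibble with one row per segment: `segment`, `start_index`,
#'   `end_index` (1-based, inclusive), `start_s`, `end_s`, `duration`
#'   (s), `direction` (+1 / -1).
#' @examples
#' # 12 s of back-and-forth motion: four ~3 s parts, alternating signs
#' tr <- back_and_forth_record(part_s = 3, n_parts = 4)
#' segment_by_direction(tr)
#' @export
segment_by_direction <- function(trace, config = segmentation_config()) {
  stopifnot(inherits(config, "segmentation_config"))
  sig <- as_signal(trace, col = if ("x" %in% names(trace)) "x" else NULL)
  fs <- sig$fs
  n <- length(sig$x)
  min_len <- max(1L, round(config$min_duration * fs))
  max_len <- max(min_len, round(config$max_duration * fs))
  if (n < min_len)
    abort(sprintf(
      "Record of %.2f s is shorter than min_duration = %g s.",
      n / fs, config$min_duration))
  if (config$smooth_window < 1 / fs)
    abort("`smooth_window` must be at least one sample period.")

  d <- smoothed_derivative(sig$x, fs, config$smooth_window)
  sgn <- sign(d)
  # zero-derivative samples inherit the previous direction (leading zeros
  # inherit the first nonzero one)
  nz <- which(sgn != 0)
  if (length(nz) == 0) sgn[] <- 1 else {
    first <- nz[1]
    if (first > 1) sgn[seq_len(first - 1)] <- sgn[first]
    for (k in which(sgn == 0)) sgn[k] <- sgn[k - 1]
  }

  runs <- rle(as.vector(sgn))
  # hysteresis: absorb short runs into the run before them, then re-merge
  repeat {
    short <- which(runs$lengths < min_len)
    short <- short[!(short == 1 & length(runs$lengths) == 1)]
    if (length(short) == 0) break
    k <- short[1]
    if (k == 1) {
      runs$values[1] <- runs$values[2]
    } else {
      runs$values[k] <- runs$values[k - 1]
    }
    runs <- rle(inverse.rle(runs))
  }

  ends <- cumsum(runs$lengths)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  seg_start <- integer(0)
  seg_end <- integer(0)
  for (j in seq_along(starts)) {
    len <- runs$lengths[j]
    pieces <- ceiling(len / max_len)
    cuts <- round(seq(starts[j] - 1L, ends[j], length.out = pieces + 1))
    seg_start <- c(seg_start, cuts[-length(cuts)] + 1L)
    seg_end <- c(seg_end, cuts[-1])
  }

  direction <- vapply(seq_along(seg_start), function(j) {
    s <- sum(sgn[seg_start[j]:seg_end[j]])
    if (s >= 0) 1 else -1
  }, numeric(1))

  tibble::tibble(
    segment = seq_along(seg_start),
    start_index = as.integer(seg_start),
    end_index = as.integer(seg_end),
    start_s = sig$t[seg_start],
    end_s = sig$t[seg_end],
    duration = (seg_end - seg_start) / fs,
    direction = direction
  )
}

smoothed_derivative <- function(x, fs, window_s) {
  d <- c(NA, diff(x)) * fs
  d[1] <- d[2]
  w <- max(1L, round(window_s * fs))
  if (w %% 2 == 0) w <- w + 1L
  half <- (w - 1L) / 2L
  # centred moving average with edge replication
  xp <- c(rep(d[1], half), d, rep(d[length(d)], half))
  sm <- stats::filter(xp, rep(1 / w, w), sides = 2)
  as.numeric(sm[(half + 1):(half + length(d))])
}

#' Synthetic back-and-forth displacement record
#'
#' Builds a record in which the body sways alternately away from and
#' towards the radar in equal-duration constant-speed parts while the
#' vital-sign ripple continues underneath — the scenario the
#' segmentation stage exists for. Parts alternate direction starting
#' away from the radar (+1).
#'
#' @param params A [motion_params()]; `v` sets the sway speed and the
#'   vital components continue coherently across parts.
#' @param part_s Duration of each constant-direction part, seconds.
#' @param n_parts Number of parts.
#' @param fs Sampling rate in Hz.
#' @return A tibble `t`, `x` (mm) with attribute `truth`: a tibble of
#'   per-part start/end times and directions.
#' @export
back_and_forth_record <- function(params = motion_params(), part_s = 5,
                                  n_parts = 4, fs = 100) {
  n_per <- round(part_s * fs)
  n <- n_per * n_parts
  t <- (seq_len(n) - 1) / fs
  dirs <- rep(c(1, -1), length.out = n_parts)
  slope <- rep(dirs, each = n_per) * params$v
  body <- cumsum(c(0, slope[-1])) / fs
  x <- params$m_r * sin(2 * pi * params$f_r * t + params$phase) +
    params$m_h * sin(2 * pi * params$f_h * t + params$phase) + body
  out <- signal_tibble(t, fs, x = x)
  attr(out, "truth") <- tibble::tibble(
    part = seq_len(n_parts),
    start_s = (seq_len(n_parts) - 1) * part_s,
    end_s = seq_len(n_parts) * part_s - 1 / fs,
    direction = dirs
  )
  out
}
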