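# Shared fixtures and independent oracles.
#
# std_trace(): the standard simulation record (3 mm @ 0.4 Hz respiration,
# 1 mm @ 1.3 Hz heartbeat, 30 mm/s body motion, fs = 100 Hz, 5 s = 500
# samples) pushed through baseband synthesis and DACM demodulation.
# Memoised: every test sees the identical record.

std_fs <- 100
std_bin <- function(M = 2^17) std_fs / M

std_trace <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- synth_motion() |> synth_baseband() |> demodulate()
    cache
  }
})

std_anc <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- cancel_rbm(std_trace())
    cache
  }
})

std_residual <- function() {
  anc <- std_anc()
  z <- anc$signals[c("t", "z")]
  attr(z, "fs") <- attr(anc$signals, "fs")
  z
}

# Direct evaluation of the cosine projection, O(L*M): the independent
# oracle for the fast transform path.
ndct_direct <- function(z, M) {
  L <- length(z)
  n <- 0:(L - 1)
  vapply(0:(M / 2),
         function(k) abs(2 * sum(z * cos(2 * pi * k * n / M))),
         numeric(1))
}

# Four-quadrant arctangent with explicit unwrapping, relative to the
# first sample: the independent oracle for DACM phase accumulation.
unwrap_phase <- function(I, Q) {
  th <- atan2(Q, I)
  d <- diff(th)
  d <- d - 2 * pi * round(d / (2 * pi))
  c(0, cumsum(d))
}

peak_freq <- function(spec, band) {
  b <- spec$freq_hz >= band[1] & spec$freq_hz <= band[2]
  spec$freq_hz[b][which.max(spec$magnitude[b])]
}

halfmax_width <- function(spec, band) {
  idx <- which(spec$freq_hz >= band[1] & spec$freq_hz <= band[2])
  i <- idx[which.max(spec$magnitude[idx])]
  half <- spec$magnitude[i] / 2
  lo <- i
  while (lo > 1 && spec$magnitude[lo] > half) lo <- lo - 1
  hi <- i
  while (hi < nrow(spec) && spec$magnitude[hi] > half) hi <- hi + 1
  (hi - lo) * (spec$freq_hz[2] - spec$freq_hz[1])
}
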