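# Internal helpers for the tabular signal representation.
#
# Sampled series travel as tibbles with a `t` column (seconds, t[1] = 0 for
# synthetic records) plus one or more value columns. The sampling rate is
# carried as an `fs` attribute when known and re-derived from `t` otherwise.

sampling_rate <- function(data, fs = NULL) {
  if (!is.null(fs)) return(fs)
  a <- attr(data, "fs")
  if (!is.null(a)) return(a)
  if (is.data.frame(data) && "t" %in% names(data) && nrow(data) >= 2) {
    dt <- diff(data$t)
    if (any(dt <= 0)) abort("`t` must be strictly increasing.")
    if (diff(range(dt)) > 1e-6 * stats::median(dt))
      abort("`t` must be uniformly sampled to infer a sampling rate.")
    return(1 / stats::median(dt))
  }
  abort("Supply `fs` (Hz): it is not recoverable from the input.")
}

# Accept a data frame with a time column and a single value column (or a
# named one), or a bare numeric vector with `fs`; return list(x, t, fs, col).
as_signal <- function(data, fs = NULL, col = NULL) {
  if (is.numeric(data)) {
    fs <- sampling_rate(NULL, fs %||% attr(data, "fs"))
    x <- as.numeric(data)
    return(list(x = x, t = (seq_along(x) - 1) / fs, fs = fs, col = "x"))
  }
  if (!is.data.frame(data))
    abort("Expected a data frame with a `t` column or a numeric vector.")
  fs <- sampling_rate(data, fs)
  vcols <- setdiff(names(data), "t")
  if (!is.null(col)) {
    if (!col %in% names(data)) abort(sprintf("Column `%s` not found.", col))
  } else {
    if (length(vcols) != 1)
      abort(sprintf(
        "Need exactly one value column beside `t`; found: %s.",
        paste(vcols, collapse = ", ")))
    col <- vcols
  }
  x <- data[[col]]
  if (!is.numeric(x)) abort(sprintf("Column `%s` must be numeric.", col))
  tt <- if ("t" %in% names(data)) data$t else (seq_along(x) - 1) / fs
  list(x = as.numeric(x), t = tt, fs = fs, col = col)
}

signal_tibble <- function(t, fs, ...) {
  out <- tibble::tibble(t = t, ...)
  attr(out, "fs") <- fs
  out
}

check_finite <- function(x, what) {
  if (!all(is.finite(x)))
    abort(sprintf("%s contains non-finite values.", what))
  invisible(x)
}
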