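#' Plot a spectrum
#'
#' Line plot of a [ndct()] / [fft_spectrum()] result, optionally
#' restricted to a frequency range.
#'
#' @param object A `vital_spectrum`.
#' @param xlim Optional two-element Hz range to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vital_spectrum
#' @export
autoplot.vital_spectrum <- function(object, xlim = c(0, 3.5), ...) {
  df <- object[object$freq_hz >= xlim[1] & object$freq_hz <= xlim[2], ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_hz, y = .data$magnitude)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(
      x = "Frequency (Hz)", y = "Magnitude",
      title = sprintf("%s spectrum (L = %d, M = 2^%d)",
                      toupper(attr(object, "method")), attr(object, "L"),
                      round(log2(attr(object, "M"))))
    ) +
    ggplot2::theme_minimal()
}

#' Plot an ANC fit
#'
#' Shows the demodulated input and filtered reference output on the left
#' axis scale and the vital-sign residual as its own panel (the residual
#' is orders of magnitude smaller than the body motion).
#'
#' @param object An `anc_fit` from [lms_anc()] / [cancel_rbm()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot anc_fit
#' @export
autoplot.anc_fit <- function(object, ...) {
  long <- object$signals |>
    tidyr::pivot_longer(dplyr::all_of(c("desired", "y", "z")),
                        names_to = "series", values_to = "mm") |>
    dplyr::mutate(panel = ifelse(.data$series == "z",
                                 "residual z (vital signs)",
                                 "body motion scale"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t, y = .data$mm,
                                     colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Time (s)", y = "Displacement (mm)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot segmentation over a displacement trace
#'
#' @param trace Data frame `t`, `x` that was segmented.
#' @param segments Output of [segment_by_direction()].
#' @return A ggplot object with direction-coloured segment bands.
#' @export
plot_segments <- function(trace, segments) {
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = dplyr::mutate(segments,
                           direction = factor(.data$direction,
                                              c(-1, 1), c("towards", "away"))),
      ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                   ymin = -Inf, ymax = Inf, fill = .data$direction),
      alpha = 0.15) +
    ggplot2::geom_line(data = trace,
                       ggplot2::aes(x = .data$t, y = .data$x),
                       linewidth = 0.4) +
    ggplot2::labs(x = "Time (s)", y = "Displacement (mm)",
                  fill = "Direction") +
    ggplot2::theme_minimal()
}
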