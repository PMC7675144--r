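#' Spectrogram container
#'
#' A spectrogram is the common input to every encoding model in the package:
#' a channels x time matrix of log-compressed level in dB-like units, sampled
#' on a regular time grid (10-ms bins by default) with log-spaced channel
#' center frequencies.
#'
#' @param levels numeric matrix, channels x time bins, log-compressed level.
#'   Must be finite everywhere (the frontend applies a compression floor).
#' @param channel_centers_hz optional numeric vector of strictly increasing
#'   center frequencies, one per row. Defaults to a log-spaced grid from
#'   200 Hz to 20 kHz.
#' @param bin_s time bin width in seconds (default 0.01).
#'
#' @return An object of class `"spectrogram"`: a list with elements `levels`,
#'   `channel_centers_hz` and `bin_s`.
#' @examples
#' sp <- spectrogram(matrix(abs(rnorm(18 * 50)), 18, 50))
#' dim(sp$levels)
#' @export
spectrogram <- function(levels, channel_centers_hz = NULL, bin_s = 0.01) {
  levels <- as.matrix(levels)
  if (!all(is.finite(levels))) {
    stop_audenc("spectrogram levels must be finite (apply a compression floor first)",
                "audenc_value_error")
  }
  if (is.null(channel_centers_hz)) {
    channel_centers_hz <- log_spaced_centers(nrow(levels))
  }
  if (length(channel_centers_hz) != nrow(levels)) {
    stop_audenc("length(channel_centers_hz) must equal nrow(levels)",
                "audenc_shape_error")
  }
  if (any(diff(channel_centers_hz) <= 0)) {
    stop_audenc("channel_centers_hz must be strictly increasing",
                "audenc_value_error")
  }
  assert_scalar_number(bin_s, "bin_s", lower = 1e-6)
  structure(
    list(levels = levels, channel_centers_hz = channel_centers_hz, bin_s = bin_s),
    class = "spectrogram"
  )
}

#' Log-spaced gammatone channel center frequencies
#'
#' @param n_channels number of channels.
#' @param f_low,f_high lowest and highest center frequency in Hz.
#' @return numeric vector of length `n_channels`.
#' @export
log_spaced_centers <- function(n_channels = 18, f_low = 200, f_high = 20000) {
  exp(seq(log(f_low), log(f_high), length.out = n_channels))
}

# coerce a spectrogram or bare matrix to the levels matrix
spec_levels <- function(x) {
  if (inherits(x, "spectrogram")) x$levels else as.matrix(x)
}

spec_bin_s <- function(x, default = 0.01) {
  if (inherits(x, "spectrogram")) x$bin_s else default
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf(
    "<spectrogram> %d channels x %d bins (%.0f ms bins, %.0f-%.0f Hz)\n",
    nrow(x$levels), ncol(x$levels), x$bin_s * 1000,
    min(x$channel_centers_hz), max(x$channel_centers_hz)
  ))
  invisible(x)
}

#' @export
dim.spectrogram <- function(x) dim(x$levels)

#' Heatmap of a spectrogram
#'
#' @param object a [spectrogram()].
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot spectrogram
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(
    channel = seq_len(nrow(object$levels)),
    bin = seq_len(ncol(object$levels))
  )
  df$level <- as.vector(t(object$levels))[
    (df$channel - 1) * ncol(object$levels) + df$bin]
  df$time_s <- (df$bin - 1) * object$bin_s
  df$freq_hz <- object$channel_centers_hz[df$channel]
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, factor(round(.data$freq_hz)),
                                   fill = .data$level)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "level") +
    ggplot2::labs(x = "time (s)", y = "center frequency (Hz)")
}
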