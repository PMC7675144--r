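# Forward-model operations. The hot paths dispatch to the C++ core so that
# the same arithmetic is used during fitting and prediction (this is what
# makes the architecture-nesting identities exact to the bit).

#' Linear STRF drive
#'
#' Applies the factored spectro-temporal filter to a spectrogram: spectral
#' weighting (F x R) followed by causal convolution with the temporal filters
#' (R x U). Output length equals input length; lags run from 0 to U-1 bins.
#'
#' @param spec a [spectrogram()] or a channels x time matrix.
#' @param strf an [strf_params()] object with matching channel count.
#' @return numeric vector of the linear drive, one value per time bin.
#' @export
linear_drive <- function(spec, strf) {
  S <- spec_levels(spec)
  if (nrow(S) != nrow(strf$spectral_weights)) {
    stop_audenc(sprintf("spectrogram has %d channels but STRF expects %d",
                        nrow(S), nrow(strf$spectral_weights)),
                "audenc_shape_error")
  }
  as.numeric(forward_predict_cpp(
    S, strf$spectral_weights, strf$temporal_filters,
    nl = rep(0, 4), stp_u = rep(0, ncol(strf$spectral_weights)),
    stp_tau = rep(0.1, ncol(strf$spectral_weights)),
    theta1 = rep(0, 4), K = numeric(0),
    use_stp = FALSE, use_gc = FALSE, bin_s = spec_bin_s(spec),
    linear_only = TRUE
  ))
}

#' Double-exponential output nonlinearity
#'
#' `y = b + a * exp(-exp(-k * (x - s)))`: an increasing sigmoid for `k > 0`,
#' bounded in `[b, b + a]` for `a >= 0`. At `x = s` the output is
#' `b + a * exp(-1)`.
#'
#' @param x numeric input series (linear drive).
#' @param p an [nl_params()] object.
#' @return numeric rate series, same length as `x`.
#' @export
double_exponential <- function(x, p) {
  stopifnot(inherits(p, "nl_params"))
  p$b + p$a * exp(-exp(-p$k * (x - p$s)))
}

#' Short-term plasticity transform
#'
#' Scales each spectrally weighted channel by its synapse's vesicle
#' availability d(t). Availability starts at 1 and is updated per bin:
#' depression (`u > 0`) consumes `u * s * d`, facilitation (`u < 0`) adds
#' `-u * s * (2 - d)`, and both recover toward 1 with time constant `tau`.
#' The release drive uses the rectified input (depletion is defined for
#' non-negative stimulation), while the output scales the raw signal, so
#' `u = 0` returns the input unchanged. `d` is clamped to `[0, 2]`.
#'
#' @param channel_signals rank x time matrix of spectrally weighted channels.
#' @param p an [stp_params()] object with one synapse per row.
#' @param bin_s time bin width in seconds (default 0.01).
#' @return the scaled rank x time matrix, with the availability matrix
#'   attached as attribute `"availability"`.
#' @export
stp_transform <- function(channel_signals, p, bin_s = 0.01) {
  stopifnot(inherits(p, "stp_params"))
  X <- as.matrix(channel_signals)
  if (nrow(X) != length(p$u)) {
    stop_audenc("channel_signals must have one row per synapse",
                "audenc_shape_error")
  }
  d <- stp_availability_cpp(X, p$u, p$tau, bin_s)
  out <- d * X
  attr(out, "availability") <- d
  out
}

#' Rolling spectrogram contrast
#'
#' Per-channel coefficient of variation (sd / mean) of the log-level within
#' a rolling window that precedes the current bin: with the defaults the
#' window covers 20-90 ms before each bin (70-ms window, offset 20 ms).
#' Contrast is 0 for bins whose window is incomplete or whose mean level is
#' at the floor.
#'
#' @param spec a [spectrogram()] or a channels x time matrix of log-levels.
#' @param window_ms window length in ms; must be a multiple of the bin width
#'   and at least 2 bins.
#' @param offset_ms window offset in ms; positive multiple of the bin width.
#' @param floor_guard mean levels at or below this value give contrast 0.
#' @return channels x time contrast matrix `C_f(t)`.
#' @export
compute_contrast <- function(spec, window_ms = 70, offset_ms = 20,
                             floor_guard = 1e-6) {
  S <- spec_levels(spec)
  bin_ms <- spec_bin_s(spec) * 1000
  win <- window_ms / bin_ms
  off <- offset_ms / bin_ms
  if (abs(win - round(win)) > 1e-8 || abs(off - round(off)) > 1e-8 ||
      round(off) < 1) {
    stop_audenc("window_ms and offset_ms must be positive multiples of the bin width",
                "audenc_config_error")
  }
  win <- as.integer(round(win))
  off <- as.integer(round(off))
  if (win < 2) {
    stop_audenc("contrast window must span at least 2 bins",
                "audenc_config_error")
  }
  contrast_cpp(S, win, off, floor_guard)
}

#' Frequency-summed contrast index
#'
#' Sums the per-channel contrast across frequencies,
#' `K(t) = sum_f C_f(t)`, optionally rescaled by a stored normalizer so
#' that K is of order 1 (see [calibrate_contrast_norm()]).
#'
#' @param C channels x time contrast matrix from [compute_contrast()].
#' @param normalizer optional positive scalar divisor.
#' @return numeric vector `K(t)`.
#' @export
contrast_index <- function(C, normalizer = NULL) {
  K <- colSums(as.matrix(C))
  if (!is.null(normalizer)) {
    assert_scalar_number(normalizer, "normalizer", lower = 1e-12)
    K <- K / normalizer
  }
  K
}

#' Contrast-modulated output nonlinearity
#'
#' Replaces each parameter of the double-exponential nonlinearity by its
#' contrast-dependent value `theta_i(t) = theta_i0 + (theta_i1 - theta_i0) *
#' K(t)` and applies the nonlinearity bin-wise. With `theta1` equal to the
#' base parameters the result is identical to [double_exponential()]. The
#' modulated amplitude is clamped at zero where the linear extrapolation
#' would make it negative (only reachable for K outside the calibrated
#' \[0, 1\] range).
#'
#' @param x numeric input series (linear drive).
#' @param K normalized contrast index, same length as `x`.
#' @param base an [nl_params()] object of base values (theta at K = 0).
#' @param gc a [gc_params()] object holding the endpoints `theta1`.
#' @return numeric rate series.
#' @export
modulated_nonlinearity <- function(x, K, base, gc) {
  stopifnot(inherits(base, "nl_params"), inherits(gc, "gc_params"))
  if (length(x) != length(K)) {
    stop_audenc("x and K must be aligned in time", "audenc_shape_error")
  }
  t1 <- gc$theta1
  b <- base$b + (t1[["b"]] - base$b) * K
  a <- pmax(base$a + (t1[["a"]] - base$a) * K, 0)
  s <- base$s + (t1[["s"]] - base$s) * K
  k <- base$k + (t1[["k"]] - base$k) * K
  b + a * exp(-exp(-k * (x - s)))
}

#' Calibrate the contrast normalizer of a GC model
#'
#' Computes the raw frequency-summed contrast over every stimulus in a bank
#' and stores its 95th percentile in the model's GC parameters, so that the
#' normalized K(t) used by [predict.fitted_model()] has unit 95th percentile
#' over the calibration set. This keeps `theta1` interpretable as "parameter
#' value at high contrast".
#'
#' @param model a [fitted_model()] with a GC stage.
#' @param bank a [generate_stimulus_bank()] bank or list of spectrograms.
#' @return the model with `gc$k_norm` set.
#' @export
calibrate_contrast_norm <- function(model, bank) {
  stopifnot(inherits(model, "fitted_model"))
  if (!arch_uses_gc(model$architecture)) return(model)
  stimuli <- if (inherits(bank, "stimulus_bank")) bank$stimuli else bank
  k_all <- unlist(lapply(stimuli, function(sp) {
    contrast_index(compute_contrast(sp, model$gc$window_ms, model$gc$offset_ms))
  }))
  k_norm <- as.numeric(quantile(k_all, 0.95, names = FALSE))
  if (!is.finite(k_norm) || k_norm <= 0) k_norm <- 1
  model$gc$k_norm <- k_norm
  model
}

# normalized contrast series for a GC model on one stimulus
gc_contrast_series <- function(model, spec) {
  if (is.na(model$gc$k_norm)) {
    stop_audenc("GC model has no stored contrast normalizer; run calibrate_contrast_norm() first",
                "audenc_structure_error")
  }
  contrast_index(compute_contrast(spec, model$gc$window_ms, model$gc$offset_ms),
                 normalizer = model$gc$k_norm)
}

#' Predict the PSTH response of an encoding model
#'
#' Runs the forward pass of the model's architecture: spectral weighting,
#' optional STP scaling of the weighted channels, temporal convolution, and
#' the (optionally contrast-modulated) output nonlinearity, with the final
#' rate rectified at 0 spikes/s. Restricting the extra mechanisms (`u = 0`,
#' `theta1 = theta0`) reproduces the LN prediction exactly.
#'
#' @param object a [fitted_model()].
#' @param spec a [spectrogram()] or channels x time matrix.
#' @param ... ignored.
#' @return numeric vector of predicted firing rate, one value per bin.
#' @export
predict.fitted_model <- function(object, spec, ...) {
  S <- spec_levels(spec)
  if (nrow(S) != nrow(object$strf$spectral_weights)) {
    stop_audenc(sprintf("spectrogram has %d channels but model expects %d",
                        nrow(S), nrow(object$strf$spectral_weights)),
                "audenc_shape_error")
  }
  use_stp <- arch_uses_stp(object$architecture)
  use_gc <- arch_uses_gc(object$architecture)
  rank <- ncol(object$strf$spectral_weights)
  K <- if (use_gc) gc_contrast_series(object, spec) else numeric(0)
  theta1 <- if (use_gc) as.numeric(object$gc$theta1[c("b", "a", "s", "k")]) else rep(0, 4)
  u <- if (use_stp) object$stp$u else rep(0, rank)
  tau <- if (use_stp) object$stp$tau else rep(0.1, rank)
  as.numeric(forward_predict_cpp(
    S, object$strf$spectral_weights, object$strf$temporal_filters,
    nl = nl_vec(object$nl), stp_u = u, stp_tau = tau, theta1 = theta1, K = K,
    use_stp = use_stp, use_gc = use_gc, bin_s = spec_bin_s(spec),
    linear_only = FALSE
  ))
}
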