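ARCHITECTURES <- c("LN", "STP", "GC", "GC+STP")

arch_uses_stp <- function(architecture) architecture %in% c("STP", "GC+STP")
arch_uses_gc <- function(architecture) architecture %in% c("GC", "GC+STP")

#' Rank-constrained STRF parameters
#'
#' The spectro-temporal receptive field is stored in factored form: an
#' F x R spectral weighting matrix and an R x U matrix of temporal filters
#' (R = 3 synaptic channels, U = 15 lags of 10 ms by default). The effective
#' full filter is the product `spectral_weights %*% temporal_filters`.
#'
#' @param spectral_weights numeric matrix, channels x rank.
#' @param temporal_filters numeric matrix, rank x lags.
#' @return an object of class `"strf_params"`.
#' @export
strf_params <- function(spectral_weights, temporal_filters) {
  spectral_weights <- as.matrix(spectral_weights)
  temporal_filters <- as.matrix(temporal_filters)
  if (!all(is.finite(spectral_weights)) || !all(is.finite(temporal_filters))) {
    stop_audenc("STRF parameters must be finite", "audenc_value_error")
  }
  if (ncol(spectral_weights) != nrow(temporal_filters)) {
    stop_audenc("spectral_weights rank must match temporal_filters rank",
                "audenc_shape_error")
  }
  structure(list(spectral_weights = spectral_weights,
                 temporal_filters = temporal_filters),
            class = "strf_params")
}

#' Effective full STRF filter
#'
#' @param strf an [strf_params()] object.
#' @return channels x lags matrix `spectral_weights %*% temporal_filters`.
#' @export
effective_filter <- function(strf) {
  strf$spectral_weights %*% strf$temporal_filters
}

#' Double-exponential output nonlinearity parameters
#'
#' Parameters of `y = b + a * exp(-exp(-k * (x - s)))`: baseline rate `b`,
#' response amplitude `a` (both spikes/s), input offset `s` and gain `k`
#' (per input unit).
#'
#' @param b baseline spike rate.
#' @param a amplitude; must be non-negative.
#' @param s input offset (firing threshold).
#' @param k gain.
#' @return an object of class `"nl_params"`.
#' @export
nl_params <- function(b, a, s, k) {
  for (v in list(b, a, s, k)) assert_scalar_number(v, "nl parameter")
  if (a < 0) stop_audenc("nonlinearity amplitude `a` must be >= 0",
                         "audenc_value_error")
  structure(list(b = b, a = a, s = s, k = k), class = "nl_params")
}

nl_vec <- function(p) c(p$b, p$a, p$s, p$k)

#' Short-term plasticity parameters
#'
#' One virtual synapse per spectral channel of the rank-3 STRF. `u[i]` is the
#' fraction of available vesicles released per unit input (positive values
#' give depression, negative facilitation); `tau[i]` is the recovery time
#' constant in seconds.
#'
#' @param u numeric vector of release fractions, `|u| <= u_max`.
#' @param tau numeric vector of recovery time constants (s), strictly
#'   positive.
#' @param u_max bound on `|u|` (default 1).
#' @return an object of class `"stp_params"`.
#' @export
stp_params <- function(u, tau, u_max = 1) {
  if (length(u) != length(tau)) {
    stop_audenc("u and tau must have the same length", "audenc_shape_error")
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop_audenc("recovery time constants tau must be > 0", "audenc_param_error")
  }
  if (any(!is.finite(u)) || any(abs(u) > u_max)) {
    stop_audenc(sprintf("|u| must be <= %g", u_max), "audenc_param_error")
  }
  structure(list(u = as.numeric(u), tau = as.numeric(tau), u_max = u_max),
            class = "stp_params")
}

#' Contrast gain control parameters
#'
#' Linear modulation of the output nonlinearity by the frequency-summed
#' stimulus contrast K(t): each nonlinearity parameter moves from its base
#' value (at K = 0) to the endpoint in `theta1` (at K = 1),
#' `theta_i(t) = theta_i0 + (theta_i1 - theta_i0) * K(t)`.
#'
#' @param theta1 named numeric vector `c(b=, a=, s=, k=)` of endpoint
#'   parameter values at unit contrast; `a` endpoint must be non-negative.
#' @param window_ms rolling contrast window length in ms (default 70).
#' @param offset_ms window offset before the current bin in ms (default 20).
#' @param k_norm stored contrast normalizer: raw frequency-summed contrast is
#'   divided by this value so K has unit 95th percentile over the calibration
#'   stimulus set. `NA` until calibrated (see [calibrate_contrast_norm()]).
#' @return an object of class `"gc_params"`.
#' @export
gc_params <- function(theta1, window_ms = 70, offset_ms = 20, k_norm = NA_real_) {
  theta1 <- theta1[c("b", "a", "s", "k")]
  if (any(is.na(names(theta1))) || any(!is.finite(theta1))) {
    stop_audenc("theta1 must be a finite named vector with names b, a, s, k",
                "audenc_param_error")
  }
  if (theta1[["a"]] < 0) {
    stop_audenc("theta1['a'] must be >= 0", "audenc_value_error")
  }
  assert_scalar_number(window_ms, "window_ms", lower = 1e-9)
  assert_scalar_number(offset_ms, "offset_ms", lower = 1e-9)
  structure(list(theta1 = theta1, window_ms = window_ms, offset_ms = offset_ms,
                 k_norm = as.numeric(k_norm)),
            class = "gc_params")
}

#' Encoding model container
#'
#' Bundles the parameter groups of one of the four architectures. Parameter
#' groups must be present exactly when the architecture requires them: STP
#' parameters for `"STP"` and `"GC+STP"`, gain-control parameters for `"GC"`
#' and `"GC+STP"`.
#'
#' @param architecture one of `"LN"`, `"STP"`, `"GC"`, `"GC+STP"`.
#' @param strf an [strf_params()] object.
#' @param nl an [nl_params()] object (base values of the output
#'   nonlinearity).
#' @param stp an [stp_params()] object or `NULL`.
#' @param gc a [gc_params()] object or `NULL`.
#' @param meta list of fit metadata (stage losses, seed, ...).
#' @return an object of class `"fitted_model"`.
#' @export
fitted_model <- function(architecture, strf, nl, stp = NULL, gc = NULL,
                         meta = list()) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  stopifnot(inherits(strf, "strf_params"), inherits(nl, "nl_params"))
  if (arch_uses_stp(architecture) != !is.null(stp)) {
    stop_audenc(sprintf("architecture %s requires STP parameters %s",
                        architecture,
                        if (arch_uses_stp(architecture)) "present" else "absent"),
                "audenc_structure_error")
  }
  if (arch_uses_gc(architecture) != !is.null(gc)) {
    stop_audenc(sprintf("architecture %s requires GC parameters %s",
                        architecture,
                        if (arch_uses_gc(architecture)) "present" else "absent"),
                "audenc_structure_error")
  }
  if (!is.null(stp) && length(stp$u) != ncol(strf$spectral_weights)) {
    stop_audenc("one STP synapse is required per STRF rank channel",
                "audenc_shape_error")
  }
  structure(list(architecture = architecture, strf = strf, nl = nl, stp = stp,
                 gc = gc, meta = meta),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s: %d channels, rank %d, %d lags\n",
              x$architecture, nrow(x$strf$spectral_weights),
              ncol(x$strf$spectral_weights), ncol(x$strf$temporal_filters)))
  if (!is.null(x$meta$stage_loss)) {
    cat("  stage losses:",
        paste(signif(x$meta$stage_loss, 4), collapse = " -> "), "\n")
  }
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model a [fitted_model()].
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(
    architecture = model$architecture,
    strf = list(spectral_weights = model$strf$spectral_weights,
                temporal_filters = model$strf$temporal_filters),
    nl = model$nl[c("b", "a", "s", "k")],
    stp = if (!is.null(model$stp)) model$stp[c("u", "tau", "u_max")],
    gc = if (!is.null(model$gc)) {
      list(theta1 = as.list(model$gc$theta1), window_ms = model$gc$window_ms,
           offset_ms = model$gc$offset_ms, k_norm = model$gc$k_norm)
    },
    meta = model$meta
  )
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Deserialize a fitted model from JSON
#'
#' @param x JSON string, or path to a JSON file written by [model_to_json()].
#' @return a [fitted_model()].
#' @export
model_from_json <- function(x) {
  if (length(x) == 1 && file.exists(x)) x <- paste(readLines(x), collapse = "\n")
  doc <- jsonlite::fromJSON(x, simplifyVector = TRUE)
  stp <- NULL
  if (!is.null(doc$stp)) {
    stp <- stp_params(doc$stp$u, doc$stp$tau, u_max = doc$stp$u_max)
  }
  gc <- NULL
  if (!is.null(doc$gc)) {
    gc <- gc_params(unlist(doc$gc$theta1), window_ms = doc$gc$window_ms,
                    offset_ms = doc$gc$offset_ms,
                    k_norm = doc$gc$k_norm %||% NA_real_)
  }
  fitted_model(doc$architecture,
               strf_params(as.matrix(doc$strf$spectral_weights),
                           as.matrix(doc$strf$temporal_filters)),
               nl_params(doc$nl$b, doc$nl$a, doc$nl$s, doc$nl$k),
               stp = stp, gc = gc,
               meta = as.list(doc$meta))
}
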