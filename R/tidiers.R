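# broom-style tidiers for fitted models and reports.

#' Tidy a fitted encoding model
#'
#' One row per scalar parameter, with the parameter group (`spectral`,
#' `temporal`, `nonlinearity`, `stp`, `gc`) and indices where applicable.
#'
#' @param x a [fitted_model()].
#' @param ... ignored.
#' @return a tibble with columns `group`, `term`, `channel`, `lag`,
#'   `estimate`.
#' @method tidy fitted_model
#' @export
tidy.fitted_model <- function(x, ...) {
  W <- x$strf$spectral_weights
  H <- x$strf$temporal_filters
  rows <- list(
    tibble(group = "spectral",
           term = sprintf("w[%d,%d]", row(W), col(W)),
           channel = as.integer(row(W)), lag = NA_integer_,
           estimate = as.vector(W)),
    tibble(group = "temporal",
           term = sprintf("h[%d,%d]", row(H), col(H)),
           channel = as.integer(row(H)), lag = as.integer(col(H)) - 1L,
           estimate = as.vector(H)),
    tibble(group = "nonlinearity", term = c("b", "a", "s", "k"),
           channel = NA_integer_, lag = NA_integer_,
           estimate = unlist(x$nl[c("b", "a", "s", "k")], use.names = FALSE))
  )
  if (!is.null(x$stp)) {
    rows <- c(rows, list(tibble(
      group = "stp",
      term = c(sprintf("u[%d]", seq_along(x$stp$u)),
               sprintf("tau[%d]", seq_along(x$stp$tau))),
      channel = rep(seq_along(x$stp$u), 2), lag = NA_integer_,
      estimate = c(x$stp$u, x$stp$tau))))
  }
  if (!is.null(x$gc)) {
    rows <- c(rows, list(tibble(
      group = "gc", term = sprintf("theta1[%s]", names(x$gc$theta1)),
      channel = NA_integer_, lag = NA_integer_,
      estimate = as.numeric(x$gc$theta1))))
  }
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted encoding model
#'
#' @param x a [fitted_model()].
#' @param ... ignored.
#' @return a tibble with the architecture, parameter counts, per-synapse
#'   mean STP parameters where present, and the final stage loss.
#' @method glance fitted_model
#' @export
glance.fitted_model <- function(x, ...) {
  tibble(
    architecture = x$architecture,
    n_channels = nrow(x$strf$spectral_weights),
    rank = ncol(x$strf$spectral_weights),
    n_lags = ncol(x$strf$temporal_filters),
    mean_u = if (!is.null(x$stp)) mean(x$stp$u) else NA_real_,
    mean_tau = if (!is.null(x$stp)) mean(x$stp$tau) else NA_real_,
    k_norm = if (!is.null(x$gc)) x$gc$k_norm else NA_real_,
    final_loss = if (length(x$meta$stage_loss)) {
      unname(x$meta$stage_loss[length(x$meta$stage_loss)])
    } else NA_real_
  )
}

#' Per-neuron table of a population report
#'
#' @param x a [run_experiment()] report.
#' @param ... ignored.
#' @return the per-neuron tibble.
#' @method tidy population_report
#' @export
tidy.population_report <- function(x, ...) x$neurons

#' One-row population summary
#'
#' @param x a [run_experiment()] report.
#' @param ... ignored.
#' @return a one-row tibble of population medians and counts.
#' @method glance population_report
#' @export
glance.population_report <- function(x, ...) {
  s <- x$summary
  tibble(
    regime = s$regime, n_neurons = s$n_neurons,
    n_responsive = s$n_responsive, n_improved = s$n_improved,
    median_r_ln = s$median_r$ln, median_r_stp = s$median_r$stp,
    median_r_gc = s$median_r$gc, median_r_both = s$median_r$both,
    median_equivalence = s$median_equivalence,
    median_effect_size = s$median_effect_size,
    median_reliability = s$median_reliability,
    median_w_plus_stp = s$median_w_plus$stp,
    median_w_plus_gc = s$median_w_plus$gc
  )
}
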