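# Significance testing, model-equivalence analysis and response reliability.

#' Permutation test for prediction accuracy
#'
#' Tests whether a prediction correlates with the response better than
#' expected for a random prediction with the same autocorrelation. The null
#' distribution is built by circularly shifting the prediction by random
#' offsets of at least `min_shift_s`; the p-value is
#' `(1 + #\{null r >= observed r\}) / (n_perm + 1)`.
#'
#' @param pred predicted PSTH.
#' @param resp_mean repetition-averaged response, same length.
#' @param n_perm number of permutations (default 500).
#' @param seed integer seed.
#' @param min_shift_s minimum circular shift in seconds (default 0.5).
#' @param bin_s bin width in seconds.
#' @return p-value with attribute `observed` (the observed correlation). A
#'   constant prediction or response returns 1 with attribute
#'   `degenerate = TRUE`.
#' @export
permutation_significance <- function(pred, resp_mean, n_perm = 500, seed = 1,
                                     min_shift_s = 0.5, bin_s = 0.01) {
  if (length(pred) != length(resp_mean)) {
    stop_audenc("pred and resp_mean must have equal length",
                "audenc_shape_error")
  }
  n <- length(pred)
  min_shift <- round(min_shift_s / bin_s)
  if (n < 2 * min_shift) {
    stop_audenc(sprintf(
      "series of %d bins is too short for a %d-bin minimum circular shift",
      n, min_shift), "audenc_config_error")
  }
  if (sd(pred) == 0 || sd(resp_mean) == 0) {
    return(structure(1, degenerate = TRUE, observed = 0))
  }
  r_obs <- cor(pred, resp_mean)
  null_r <- with_local_seed(derive_seed(seed, 61), {
    shifts <- sample(seq(min_shift, n - min_shift), n_perm, replace = TRUE)
    vapply(shifts, function(sft) {
      cor(pred[c((sft + 1):n, 1:sft)], resp_mean)
    }, numeric(1))
  })
  structure((1 + sum(null_r >= r_obs)) / (n_perm + 1), observed = r_obs)
}

#' Jackknife t test for improvement in prediction correlation
#'
#' Tests whether model B predicts the validation response better than model
#' A using a delete-one-block jackknife over contiguous segments of the
#' validation series: pseudo-values of the difference in prediction
#' correlation (R_B - R_A) are compared against zero with a one-sided
#' paired t statistic.
#'
#' @param predA,predB predictions of the two models over the validation
#'   bins.
#' @param resp_reps repetitions x bins response matrix (or list of
#'   matrices).
#' @param n_jack number of contiguous blocks (default 20, at least 2).
#' @return one-sided p-value (small when B improves over A) with attributes
#'   `statistic` (the t statistic, antisymmetric in A and B) and `df`.
#' @export
jackknife_improvement <- function(predA, predB, resp_reps, n_jack = 20) {
  if (n_jack < 2) {
    stop_audenc("n_jack must be at least 2", "audenc_config_error")
  }
  if (is.list(resp_reps)) resp_reps <- do.call(cbind, resp_reps)
  resp_mean <- colMeans(as.matrix(resp_reps))
  n <- length(resp_mean)
  if (length(predA) != n || length(predB) != n) {
    stop_audenc("predictions must match the response length",
                "audenc_shape_error")
  }
  if (n < n_jack) {
    stop_audenc("validation series shorter than the number of jackknife blocks",
                "audenc_config_error")
  }
  block <- as.integer(cut(seq_len(n), n_jack))
  d_hat <- safe_cor(predB, resp_mean) - safe_cor(predA, resp_mean)
  d_loo <- vapply(seq_len(n_jack), function(i) {
    keep <- block != i
    safe_cor(predB[keep], resp_mean[keep]) -
      safe_cor(predA[keep], resp_mean[keep])
  }, numeric(1))
  pseudo <- n_jack * d_hat - (n_jack - 1) * d_loo
  se <- sd(pseudo) / sqrt(n_jack)
  if (!is.finite(se) || se == 0) {
    if (abs(mean(pseudo)) < 1e-12) {
      return(structure(1, statistic = 0, df = n_jack - 1, degenerate = TRUE))
    }
    return(structure(as.numeric(mean(pseudo) < 0),
                     statistic = sign(mean(pseudo)) * Inf, df = n_jack - 1,
                     degenerate = TRUE))
  }
  tstat <- mean(pseudo) / se
  structure(pt(tstat, df = n_jack - 1, lower.tail = FALSE),
            statistic = tstat, df = n_jack - 1)
}

#' Equivalence of two model predictions relative to a reference
#'
#' First-order partial correlation between two model prediction series,
#' controlling for the reference (LN) prediction:
#' `(r_sg - r_sl * r_gl) / sqrt((1 - r_sl^2) (1 - r_gl^2))`. A score of 1
#' means both models deviate from the reference in exactly the same way; 0
#' means their deviations are unrelated. Symmetric in the two model
#' predictions.
#'
#' @param pred_stp,pred_gc predictions of the two models being compared.
#' @param pred_ln the reference (LN) prediction.
#' @return partial correlation in \[-1, 1\]; `NA` with attribute
#'   `degenerate = TRUE` when either prediction is numerically identical to
#'   the reference.
#' @export
equivalence_partial_correlation <- function(pred_stp, pred_gc, pred_ln) {
  if (length(pred_stp) != length(pred_ln) || length(pred_gc) != length(pred_ln)) {
    stop_audenc("prediction series must have equal length",
                "audenc_shape_error")
  }
  r_sl <- safe_cor(pred_stp, pred_ln)
  r_gl <- safe_cor(pred_gc, pred_ln)
  if ((1 - r_sl^2) < 1e-12 || (1 - r_gl^2) < 1e-12) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  den <- sqrt((1 - r_sl^2) * (1 - r_gl^2))
  clip1((safe_cor(pred_stp, pred_gc) - r_sl * r_gl) / den)
}

#' Correct a within-model equivalence ceiling for split-half fitting
#'
#' Fitting on half the estimation data gives noisier parameter estimates
#' and therefore a lower within-model equivalence than the full dataset
#' would. The ratio of between-model equivalence measured on the full
#' versus opposite-half data estimates that loss, giving the corrected
#' ceiling `W_plus = (B_full / B_half) * W_half`.
#'
#' @param W_half within-model equivalence from two split-half fits.
#' @param B_full between-model equivalence using full-data fits.
#' @param B_half between-model equivalence using opposite-half fits.
#' @return corrected within-model equivalence; `NA` with attribute
#'   `degenerate = TRUE` when `B_half` is 0.
#' @export
corrected_within_equivalence <- function(W_half, B_full, B_half) {
  if (!is.finite(B_half) || B_half == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  (B_full / B_half) * W_half
}

#' Mean effect size of the nonlinear mechanisms
#'
#' Average change in prediction correlation of the STP and GC models
#' relative to the LN model:
#' `((r_stp - r_ln) + (r_gc - r_ln)) / 2`.
#'
#' @param r_stp,r_gc,r_ln prediction correlations of the three models.
#' @return scalar effect size.
#' @export
effect_size <- function(r_stp, r_gc, r_ln) {
  ((r_stp - r_ln) + (r_gc - r_ln)) / 2
}

#' Signal-power reliability of repeated responses
#'
#' For each stimulus with repetitions `y_j`, total power is the dot product
#' `<y_j, y_j>` and signal power is the mean cross-repetition dot product
#' `<y_j, y_k>` over `k != j`; the per-stimulus reliability averages the
#' signal/total ratio over repetitions, and the overall reliability averages
#' over stimuli. A value of 1 indicates a noise-free response; 0.5 a
#' response that is half signal, half noise; 0 pure noise. All-zero
#' repetitions are skipped (division guard) and counted in `n_skipped`.
#'
#' @param resp_reps a repetitions x bins matrix, or a list of such matrices
#'   (one per stimulus).
#' @return an object of class `"reliability_result"`: list with
#'   `per_stimulus`, `overall`, `n_stimuli`, `n_reps` and `n_skipped`.
#' @export
reliability <- function(resp_reps) {
  if (!is.list(resp_reps)) resp_reps <- list(resp_reps)
  skipped <- 0
  per_stimulus <- vapply(resp_reps, function(Y) {
    Y <- as.matrix(Y)
    m <- nrow(Y)
    if (m < 2) {
      stop_audenc("reliability requires at least 2 repetitions per stimulus",
                  "audenc_config_error")
    }
    G <- Y %*% t(Y)        # Gram matrix of dot products
    ratios <- vapply(seq_len(m), function(j) {
      tp <- G[j, j]
      if (tp == 0) return(NA_real_)
      sp <- mean(G[j, -j])
      sp / tp
    }, numeric(1))
    skipped <<- skipped + sum(is.na(ratios))
    mean(ratios, na.rm = TRUE)
  }, numeric(1))
  structure(list(per_stimulus = per_stimulus,
                 overall = mean(per_stimulus),
                 n_stimuli = length(per_stimulus),
                 n_reps = vapply(resp_reps, nrow, integer(1)),
                 n_skipped = skipped),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability> overall %.3f over %d stimuli (reps: %s)\n",
              x$overall, x$n_stimuli,
              paste(unique(x$n_reps), collapse = "/")))
  invisible(x)
}

#' Within-model equivalence ceiling from split-half fits
#'
#' Upper bound on the between-model equivalence score: the estimation set is
#' split into two stimulus-balanced halves (alternating assignment after a
#' seeded shuffle), the same architecture is fitted independently to each
#' half, and the partial correlation between the two fits' validation
#' predictions is computed relative to the LN prediction. Combine with
#' between-model terms via [corrected_within_equivalence()].
#'
#' @param architecture model architecture to split-fit.
#' @param est_data estimation [fit_data()].
#' @param val_data validation [fit_data()].
#' @param ln_model the reference LN model fitted on the full estimation set.
#' @param config a [fit_config()].
#' @param seed seed for the half assignment.
#' @return list with `w_half`, the two half-fit models (`fit1`, `fit2`) and
#'   their validation predictions (`pred1`, `pred2`).
#' @export
within_model_ceiling <- function(architecture, est_data, val_data, ln_model,
                                 config = fit_config(), seed = 1) {
  n <- length(est_data$stims)
  if (n < 2) {
    stop_audenc("estimation data must be splittable into two non-empty halves",
                "audenc_config_error")
  }
  ord <- with_local_seed(derive_seed(seed, 71), sample(n))
  half1 <- sort(ord[seq(1, n, by = 2)])
  half2 <- sort(ord[seq(2, n, by = 2)])
  fit1 <- fit_model(architecture, fit_data_subset(est_data, half1), config)
  fit2 <- fit_model(architecture, fit_data_subset(est_data, half2), config)
  predict_concat <- function(model) {
    unlist(lapply(val_data$stims, function(s) {
      predict(model, spectrogram(s, bin_s = val_data$bin_s))
    }))
  }
  pred1 <- predict_concat(fit1)
  pred2 <- predict_concat(fit2)
  pred_ln <- predict_concat(ln_model)
  list(w_half = equivalence_partial_correlation(pred1, pred2, pred_ln),
       fit1 = fit1, fit2 = fit2, pred1 = pred1, pred2 = pred2,
       half1 = half1, half2 = half2, pred_ln = pred_ln)
}
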