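# Staged model estimation. All parameter groups live in one flat vector
# (spectral weights | temporal filters | nonlinearity | STP u | STP tau |
# GC theta1); each stage frees a subset and runs bounded L-BFGS-B on the
# MSE between prediction and the repetition-averaged response.

#' Fitting configuration
#'
#' @param rank STRF rank (number of spectral channels / virtual synapses).
#' @param n_lags temporal filter length in 10-ms bins.
#' @param tol_coarse,tol_fine relative loss-change stopping tolerances for
#'   the coarse and fine stages.
#' @param maxit maximum optimizer iterations per stage (0 returns the
#'   initialization unchanged).
#' @param n_restarts number of seeded initializations of the full staged
#'   schedule; the restart with the lowest final estimation loss wins
#'   (default 1).
#' @param u_max bound on the magnitude of STP release fractions.
#' @param tau_min,tau_max bounds on STP recovery time constants (seconds).
#' @param gc_window_ms,gc_offset_ms contrast window used by GC stages.
#' @param init_jitter SD of the seeded jitter added to the spectral-weight
#'   initialization (breaks rank symmetry).
#' @param seed integer seed for the initialization.
#' @param bin_s time bin width in seconds.
#' @param log_file optional path; per-stage records (stage, evaluations,
#'   loss) are appended as lines.
#' @return an object of class `"fit_config"`.
#' @export
fit_config <- function(rank = 3, n_lags = 15, tol_coarse = 1e-4,
                       tol_fine = 1e-7, maxit = 1000, n_restarts = 1,
                       u_max = 1, tau_min = 1e-3, tau_max = 1,
                       gc_window_ms = 70, gc_offset_ms = 20,
                       init_jitter = 0.15, seed = 1, bin_s = 0.01,
                       log_file = NULL) {
  assert_scalar_number(tol_coarse, "tol_coarse", lower = 1e-15)
  assert_scalar_number(tol_fine, "tol_fine", lower = 1e-16)
  assert_scalar_number(maxit, "maxit", lower = 0)
  assert_scalar_number(n_restarts, "n_restarts", lower = 1)
  structure(list(rank = rank, n_lags = n_lags, tol_coarse = tol_coarse,
                 tol_fine = tol_fine, maxit = maxit,
                 n_restarts = n_restarts, u_max = u_max,
                 tau_min = tau_min, tau_max = tau_max,
                 gc_window_ms = gc_window_ms, gc_offset_ms = gc_offset_ms,
                 init_jitter = init_jitter, seed = seed, bin_s = bin_s,
                 log_file = log_file),
            class = "fit_config")
}

#' Read a fitting configuration from a JSON file
#'
#' @param path path to a JSON document of `fit_config()` arguments.
#' @return a [fit_config()].
#' @export
fit_config_read <- function(path) {
  args <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(fit_config, args)
}

#' Assemble estimation or validation data for fitting
#'
#' Pairs each selected stimulus with the repetition-averaged response of a
#' simulated (or recorded) neuron.
#'
#' @param bank a [generate_stimulus_bank()] bank.
#' @param response a [simulate_neuron()] result (or compatible list with
#'   `resp` matrices and `est_idx`/`val_idx`).
#' @param subset `"est"` or `"val"`.
#' @return an object of class `"fit_data"`: list with `stims` (level
#'   matrices), `resp_mean` (vectors), `resp_reps` (repetition matrices),
#'   `idx` and `bin_s`.
#' @export
fit_data <- function(bank, response, subset = c("est", "val")) {
  subset <- match.arg(subset)
  idx <- if (subset == "est") response$est_idx else response$val_idx
  if (length(idx) < 1) {
    stop_audenc("data subset must contain at least one stimulus",
                "audenc_config_error")
  }
  structure(list(
    stims = lapply(bank$stimuli[idx], spec_levels),
    resp_mean = lapply(response$resp[idx], colMeans),
    resp_reps = response$resp[idx],
    idx = idx,
    bin_s = bank$stimuli[[1]]$bin_s
  ), class = "fit_data")
}

# subset an existing fit_data by position (used for split-half fits)
fit_data_subset <- function(data, pos) {
  structure(list(
    stims = data$stims[pos], resp_mean = data$resp_mean[pos],
    resp_reps = data$resp_reps[pos], idx = data$idx[pos], bin_s = data$bin_s
  ), class = "fit_data")
}

#' Mean-squared error between prediction and mean response
#'
#' @param pred predicted PSTH (numeric vector).
#' @param resp_mean repetition-averaged response of equal length.
#' @return scalar mean of squared bin-wise differences.
#' @export
mse <- function(pred, resp_mean) {
  if (length(pred) != length(resp_mean)) {
    stop_audenc("pred and resp_mean must have equal length",
                "audenc_shape_error")
  }
  mean((pred - resp_mean)^2)
}

# ---- parameter vector layout -------------------------------------------

par_layout <- function(Fch, rank, n_lags) {
  nW <- Fch * rank
  nH <- rank * n_lags
  iW <- seq_len(nW)
  iH <- nW + seq_len(nH)
  iNL <- nW + nH + 1:4
  iU <- nW + nH + 4 + 1:rank
  iTau <- nW + nH + 4 + rank + seq_len(rank)
  iTheta1 <- nW + nH + 4 + 2 * rank + 1:4
  list(iW = iW, iH = iH, iNL = iNL, iU = iU, iTau = iTau, iTheta1 = iTheta1,
       n = nW + nH + 4 + 2 * rank + 4, Fch = Fch, rank = rank,
       n_lags = n_lags)
}

pack_par <- function(layout, W, H, nl, u, tau, theta1) {
  par <- numeric(layout$n)
  par[layout$iW] <- as.vector(W)
  par[layout$iH] <- as.vector(H)
  par[layout$iNL] <- nl
  par[layout$iU] <- u
  par[layout$iTau] <- tau
  par[layout$iTheta1] <- theta1
  par
}

par_bounds <- function(layout, config) {
  lower <- rep(-Inf, layout$n)
  upper <- rep(Inf, layout$n)
  lower[layout$iNL[2]] <- 0                       # amplitude a >= 0
  lower[layout$iU] <- -config$u_max
  upper[layout$iU] <- config$u_max
  lower[layout$iTau] <- config$tau_min
  upper[layout$iTau] <- config$tau_max
  lower[layout$iTheta1[2]] <- 0                   # a endpoint >= 0
  list(lower = lower, upper = upper)
}

# exact model-preserving renormalization: unit-norm spectral columns with
# compensation of the temporal filters and (for STP) the release fractions
normalize_columns <- function(par, layout, use_stp, u_max) {
  W <- matrix(par[layout$iW], layout$Fch, layout$rank)
  H <- matrix(par[layout$iH], layout$rank, layout$n_lags)
  u <- par[layout$iU]
  for (j in seq_len(layout$rank)) {
    cn <- sqrt(sum(W[, j]^2))
    if (cn < 1e-12) next
    if (use_stp && abs(u[j] * cn) > u_max) next   # would leave the feasible box
    W[, j] <- W[, j] / cn
    H[j, ] <- H[j, ] * cn
    if (use_stp) u[j] <- u[j] * cn
  }
  par[layout$iW] <- as.vector(W)
  par[layout$iH] <- as.vector(H)
  par[layout$iU] <- u
  par
}

# Staged schedule. Every architecture starts from a coarse linear STRF fit
# and a full LN polish. STP architectures then re-factorize the LN
# effective filter by seeded non-negative matrix factorization before the
# plasticity stages: the rank-3 factorization is only defined up to an
# invertible mixing of its factors, and the non-negative "parts" convention
# pins the virtual synapses to non-negative spectral bumps, which is the
# regime in which vesicle depletion is defined. Each stage's `use_stp`
# records whether the synapses are engaged during that stage.
stage_schedule <- function(architecture) {
  stp <- arch_uses_stp(architecture)
  s <- list(
    list(name = "strf_coarse", groups = c("W", "H"), tol = "coarse",
         linear_only = TRUE, use_stp = FALSE, use_gc = FALSE),
    list(name = "nl_coarse", groups = "NL", tol = "coarse",
         linear_only = FALSE, use_stp = FALSE, use_gc = FALSE),
    list(name = "joint_ln_fine", groups = c("W", "H", "NL"), tol = "fine",
         linear_only = FALSE, use_stp = FALSE, use_gc = FALSE)
  )
  if (stp) {
    s <- c(s, list(
      list(name = "nmf_refactor", groups = character(0), tol = "coarse",
           linear_only = FALSE, use_stp = FALSE, use_gc = FALSE),
      list(name = "nl_stp_coarse", groups = c("NL", "U", "Tau"),
           tol = "coarse", linear_only = FALSE, use_stp = TRUE,
           use_gc = FALSE),
      list(name = "joint_stp_fine", groups = c("W", "H", "NL", "U", "Tau"),
           tol = "fine", linear_only = FALSE, use_stp = TRUE,
           use_gc = FALSE)
    ))
  }
  if (arch_uses_gc(architecture)) {
    s <- c(s, list(
      list(name = "gc_coarse", groups = c("Theta1", if (stp) c("U", "Tau")),
           tol = "coarse", linear_only = FALSE, use_stp = stp,
           use_gc = TRUE),
      list(name = "all_fine",
           groups = c("W", "H", "NL", "Theta1", if (stp) c("U", "Tau")),
           tol = "fine", linear_only = FALSE, use_stp = stp, use_gc = TRUE)
    ))
  }
  s
}

# rank-R non-negative factorization by multiplicative updates (seeded)
nmf_refactor <- function(W, H, rank, seed, iters = 400) {
  A <- pmax(W %*% H, 0) + 1e-9
  with_local_seed(seed, {
    Wn <- matrix(runif(nrow(A) * rank, 0.1, 1), nrow(A), rank)
    Hn <- matrix(runif(rank * ncol(A), 0.1, 1), rank, ncol(A))
    for (it in seq_len(iters)) {
      Hn <- Hn * (crossprod(Wn, A)) / (crossprod(Wn) %*% Hn + 1e-12)
      Wn <- Wn * (A %*% t(Hn)) / (Wn %*% tcrossprod(Hn) + 1e-12)
    }
    for (j in seq_len(rank)) {
      cn <- sqrt(sum(Wn[, j]^2))
      if (cn > 1e-12) {
        Wn[, j] <- Wn[, j] / cn
        Hn[j, ] <- Hn[j, ] * cn
      }
    }
    list(W = Wn, H = Hn)
  })
}

group_idx <- function(layout, groups) {
  sort(unique(unlist(lapply(groups, function(g) {
    switch(g, W = layout$iW, H = layout$iH, NL = layout$iNL, U = layout$iU,
           Tau = layout$iTau, Theta1 = layout$iTheta1)
  }))))
}

#' Fit an encoding model by staged bounded gradient descent
#'
#' Estimates a model of the requested architecture on estimation data by
#' minimizing the MSE between the prediction and the repetition-averaged
#' response, following the staged warm-start schedule: (1) the linear STRF
#' alone against the response, with coarse stopping; (2) the output
#' nonlinearity (plus STP where present) with the STRF fixed; (3) all LN
#' (+STP) parameters jointly with fine stopping; for GC architectures, (4)
#' the contrast-modulation (plus STP) parameters with the LN stage fixed
#' and (5) all parameters jointly. Stages not applicable to the
#' architecture are skipped, each stage starts from the previous solution,
#' and a stage is never allowed to end with a higher loss than it started.
#'
#' @param architecture one of `"LN"`, `"STP"`, `"GC"`, `"GC+STP"`.
#' @param est_data a [fit_data()] object (estimation set).
#' @param config a [fit_config()].
#' @return a [fitted_model()] with per-stage losses in `meta$stage_loss`.
#' @export
fit_model <- function(architecture, est_data, config = fit_config()) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  stopifnot(inherits(est_data, "fit_data"))
  if (length(est_data$stims) < 1) {
    stop_audenc("estimation data must contain at least one stimulus",
                "audenc_config_error")
  }
  Fch <- nrow(est_data$stims[[1]])
  layout <- par_layout(Fch, config$rank, config$n_lags)
  use_stp <- arch_uses_stp(architecture)
  use_gc <- arch_uses_gc(architecture)
  bin_s <- est_data$bin_s

  # contrast series (fixed during optimization); normalizer from the
  # estimation set
  k_norm <- NA_real_
  Ks <- lapply(est_data$stims, function(s) numeric(0))
  if (use_gc) {
    K_raw <- lapply(est_data$stims, function(s) {
      contrast_index(compute_contrast(
        spectrogram(s, bin_s = bin_s), config$gc_window_ms, config$gc_offset_ms))
    })
    k_norm <- as.numeric(quantile(unlist(K_raw), 0.95, names = FALSE))
    if (!is.finite(k_norm) || k_norm <= 0) k_norm <- 1
    Ks <- lapply(K_raw, function(k) k / k_norm)
  }

  concat_resp <- unlist(est_data$resp_mean)
  bounds <- par_bounds(layout, config)
  stages <- stage_schedule(architecture)
  log_con <- config$log_file

  obj_call <- function(par, linear_only, stage_stp, stage_gc = use_gc) {
    fit_objective_cpp(par, est_data$stims, est_data$resp_mean, Ks,
                      Fch, config$rank, config$n_lags, stage_stp, stage_gc,
                      linear_only, bin_s)
  }

  run_schedule <- function(restart_seed) {
  # ---- initialization ---------------------------------------------------
  init <- with_local_seed(derive_seed(restart_seed, 55), {
    r_f <- vapply(seq_len(Fch), function(f) {
      safe_cor(unlist(lapply(est_data$stims, function(s) s[f, ])), concat_resp)
    }, numeric(1))
    if (all(abs(r_f) < 1e-12)) r_f <- rep(1 / sqrt(Fch), Fch)
    W <- vapply(seq_len(config$rank), function(j) {
      v <- r_f + rnorm(Fch, sd = max(sd(r_f), 0.05) * config$init_jitter)
      v / sqrt(sum(v^2))
    }, numeric(Fch))
    H <- matrix(0, config$rank, config$n_lags)
    sd_resp <- max(sd(concat_resp), 1e-6)
    for (j in seq_len(config$rank)) {
      xj <- unlist(lapply(est_data$stims, function(s) colSums(s * W[, j])))
      H[j, 2] <- sd_resp / (config$rank * max(sd(xj), 1e-9))
    }
    list(W = W, H = H)
  })
  par <- pack_par(layout, init$W, init$H, nl = c(0, 1, 0, 1),
                  u = rep(0.05, config$rank), tau = rep(0.1, config$rank),
                  theta1 = c(0, 1, 0, 1))
  stage_loss <- numeric(0)

  for (si in seq_along(stages)) {
    st <- stages[[si]]

    if (st$name == "nmf_refactor") {
      # re-factorize the LN effective filter with non-negative parts so the
      # virtual synapses start from non-negative spectral bumps
      if (config$maxit > 0) {
        W <- matrix(par[layout$iW], Fch, config$rank)
        H <- matrix(par[layout$iH], config$rank, config$n_lags)
        nm <- nmf_refactor(W, H, config$rank, derive_seed(restart_seed, 56))
        par[layout$iW] <- as.vector(nm$W)
        par[layout$iH] <- as.vector(nm$H)
      }
      f_end <- obj_call(par, FALSE, st$use_stp, st$use_gc)
      stage_loss <- c(stage_loss, setNames(f_end, st$name))
      next
    }

    # heuristic warm starts between stages
    if (st$name == "nl_coarse") {
      ylin <- unlist(lapply(est_data$stims, function(s) {
        forward_predict_cpp(s, matrix(par[layout$iW], Fch, config$rank),
                            matrix(par[layout$iH], config$rank, config$n_lags),
                            rep(0, 4), rep(0, config$rank),
                            rep(0.1, config$rank), rep(0, 4), numeric(0),
                            FALSE, FALSE, bin_s, TRUE)
      }))
      q <- quantile(concat_resp, c(0.1, 0.9), names = FALSE)
      par[layout$iNL] <- c(q[1], max(q[2] - q[1], 1e-2), median(ylin),
                           1 / max(sd(ylin), 1e-6))
    }
    if (st$name == "gc_coarse") {
      par[layout$iTheta1] <- par[layout$iNL]
    }

    free <- group_idx(layout, st$groups)
    tol <- if (st$tol == "coarse") config$tol_coarse else config$tol_fine
    f0 <- obj_call(par, st$linear_only, st$use_stp, st$use_gc)
    if (!is.finite(f0)) {
      stop_audenc(sprintf("non-finite loss at start of stage %s", st$name),
                  "audenc_fit_error")
    }
    if (config$maxit > 0 && length(free) > 0) {
      par_stage <- par
      fn <- function(p) {
        par_stage[free] <- p
        v <- obj_call(par_stage, st$linear_only, st$use_stp, st$use_gc)
        if (!is.finite(v)) {
          stop_audenc(sprintf("non-finite loss in stage %s", st$name),
                      "audenc_fit_error")
        }
        v
      }
      gr <- function(p) {
        par_stage[free] <- p
        g <- model_gradient_cpp(par_stage, est_data$stims, est_data$resp_mean,
                                Ks, Fch, config$rank, config$n_lags,
                                st$use_stp, st$use_gc, st$linear_only, bin_s)
        as.numeric(g)[free]
      }
      opt <- optim(par[free], fn, gr, method = "L-BFGS-B",
                   lower = bounds$lower[free], upper = bounds$upper[free],
                   control = list(maxit = config$maxit,
                                  factr = tol / .Machine$double.eps))
      f_end <- opt$value
      if (is.finite(f_end) && f_end <= f0) {
        par[free] <- opt$par
      } else {
        f_end <- f0   # never end a stage worse than it started
      }
      evals <- opt$counts[["function"]]
    } else {
      f_end <- f0
      evals <- 0
    }
    par <- normalize_columns(par, layout, st$use_stp, config$u_max)
    stage_loss <- c(stage_loss, setNames(f_end, st$name))
    if (st$name == "joint_ln_fine") par_ln <- par
    if (!is.null(log_con)) {
      cat(sprintf("stage=%s evals=%d loss=%.8g\n", st$name, evals, f_end),
          file = log_con, append = TRUE)
    }
  }

  # The NMF re-factorization may move the STP path off the LN optimum; the
  # nested architecture can always represent that optimum exactly (u = 0,
  # theta1 = theta0), so fall back to it when the staged path ends worse.
  fallback_ln <- FALSE
  if ((use_stp || use_gc) && config$maxit > 0) {
    par_embed <- par_ln
    par_embed[layout$iU] <- 0
    if (use_gc) par_embed[layout$iTheta1] <- par_embed[layout$iNL]
    f_final <- obj_call(par, FALSE, use_stp, use_gc)
    f_embed <- obj_call(par_embed, FALSE, use_stp, use_gc)
    if (is.finite(f_embed) && f_embed < f_final) {
      par <- par_embed
      fallback_ln <- TRUE
      stage_loss <- c(stage_loss, setNames(f_embed, "ln_fallback"))
    }
  }

  list(par = par, stage_loss = stage_loss, fallback_ln = fallback_ln,
       final_loss = obj_call(par, FALSE, use_stp, use_gc))
  }

  # seeded restarts of the whole schedule; lowest final estimation loss wins
  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    res <- run_schedule(derive_seed(config$seed, c(58, r)))
    if (is.null(best) || res$final_loss < best$final_loss) best <- res
  }
  par <- best$par
  stage_loss <- best$stage_loss
  fallback_ln <- best$fallback_ln

  W <- matrix(par[layout$iW], Fch, config$rank)
  H <- matrix(par[layout$iH], config$rank, config$n_lags)
  nl <- par[layout$iNL]
  fitted_model(
    architecture,
    strf_params(W, H),
    nl_params(nl[1], max(nl[2], 0), nl[3], nl[4]),
    stp = if (use_stp) stp_params(par[layout$iU], par[layout$iTau],
                                  u_max = config$u_max),
    gc = if (use_gc) gc_params(
      setNames(par[layout$iTheta1], c("b", "a", "s", "k")),
      window_ms = config$gc_window_ms, offset_ms = config$gc_offset_ms,
      k_norm = k_norm),
    meta = list(stage_loss = stage_loss, seed = config$seed,
                fallback_ln = fallback_ln,
                n_est_stimuli = length(est_data$stims))
  )
}

#' Noise-adjusted prediction correlation
#'
#' Pearson correlation between a prediction and the repetition-averaged
#' response, divided by an estimate of the best attainable correlation
#' given finite repetitions: the square root of the split-half reliability
#' of the mean response stepped up by the Spearman-Brown relation. Clipped
#' to \[-1, 1\]. With a single repetition the raw correlation is returned
#' with a warning; a zero-variance prediction returns 0 with attribute
#' `degenerate = TRUE`; when the split-half ceiling is non-positive the raw
#' correlation is returned with attribute `ceiling_undefined = TRUE`.
#'
#' @param pred predicted PSTH (numeric vector over the validation bins).
#' @param resp_reps repetitions x bins matrix (or list of such matrices,
#'   concatenated along time).
#' @return scalar adjusted correlation with attribute `raw` (the unadjusted
#'   Pearson correlation) and `ceiling` (the estimated full-set
#'   reliability).
#' @export
noise_adjusted_correlation <- function(pred, resp_reps) {
  if (is.list(resp_reps)) resp_reps <- do.call(cbind, resp_reps)
  resp_reps <- as.matrix(resp_reps)
  if (ncol(resp_reps) != length(pred)) {
    stop_audenc("pred length must match the number of response bins",
                "audenc_shape_error")
  }
  m <- nrow(resp_reps)
  resp_mean <- colMeans(resp_reps)
  if (sd(pred) == 0) {
    return(structure(0, degenerate = TRUE, raw = 0, ceiling = NA_real_))
  }
  r_raw <- safe_cor(pred, resp_mean)
  if (m < 2) {
    warn("only one repetition available; returning the raw correlation")
    return(structure(clip1(r_raw), raw = r_raw, ceiling = NA_real_))
  }
  odd <- seq(1, m, by = 2)
  even <- seq(2, m, by = 2)
  r_sh <- safe_cor(colMeans(resp_reps[odd, , drop = FALSE]),
                   colMeans(resp_reps[even, , drop = FALSE]))
  ceiling_full <- 2 * r_sh / (1 + r_sh)
  if (!is.finite(ceiling_full) || ceiling_full <= 0) {
    return(structure(clip1(r_raw), ceiling_undefined = TRUE, raw = r_raw,
                     ceiling = ceiling_full))
  }
  structure(clip1(r_raw / sqrt(ceiling_full)), raw = r_raw,
            ceiling = ceiling_full)
}

#' Score a fitted model on validation data
#'
#' Convenience wrapper: predicts the concatenated validation PSTH and
#' returns raw and noise-adjusted prediction correlations.
#'
#' @param model a [fitted_model()].
#' @param bank the stimulus bank.
#' @param response the [simulate_neuron()] result.
#' @return list with `pred` (concatenated validation prediction),
#'   `resp_mean`, `resp_reps`, `r_raw` and `r_adj`.
#' @export
score_model <- function(model, bank, response) {
  val <- fit_data(bank, response, "val")
  pred <- unlist(lapply(val$stims, function(s) {
    predict(model, spectrogram(s, bin_s = val$bin_s))
  }))
  reps <- do.call(cbind, val$resp_reps)
  r_adj <- noise_adjusted_correlation(pred, reps)
  list(pred = pred, resp_mean = unlist(val$resp_mean), resp_reps = reps,
       r_raw = attr(r_adj, "raw"), r_adj = as.numeric(r_adj))
}
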