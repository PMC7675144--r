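# Ground-truth model neurons and response simulation.

#' Draw a random ground-truth encoding model
#'
#' Samples a plausible model of the requested architecture for use as a
#' simulation ground truth: smooth unit-norm spectral weight columns,
#' gamma-shaped temporal filters with mixed excitation and delayed
#' inhibition, an output nonlinearity calibrated to the drive distribution
#' over `bank` (so the sigmoid operates in its dynamic range), strongly
#' adapting STP synapses (release fractions and recovery time constants in
#' the range reported for adapting cortical cells), and a GC stage whose
#' gain drops substantially from low to high contrast.
#'
#' @param architecture one of `"LN"`, `"STP"`, `"GC"`, `"GC+STP"`.
#' @param bank stimulus bank used to calibrate the nonlinearity offset/gain
#'   and (for GC architectures) the contrast normalizer.
#' @param seed integer seed.
#' @param rank STRF rank (default 3).
#' @param n_lags temporal filter length in bins (default 15).
#' @return a [fitted_model()] usable as a simulation ground truth.
#' @export
random_model <- function(architecture, bank, seed = 1, rank = 3, n_lags = 15) {
  architecture <- match.arg(architecture, ARCHITECTURES)
  stopifnot(inherits(bank, "stimulus_bank"))
  Fch <- nrow(bank$stimuli[[1]]$levels)
  with_local_seed(derive_seed(seed, 7), {
    # spectral weights: non-negative unit-norm bumps (one excitatory input
    # band per virtual synapse; suppression is carried by the temporal
    # filters)
    W <- matrix(0, Fch, rank)
    main_fc <- runif(1, Fch * 0.25, Fch * 0.75)
    for (j in seq_len(rank)) {
      fc <- main_fc + (j - 1) * runif(1, -3, 3)
      bw <- runif(1, 0.9, 2.2)
      w <- exp(-0.5 * ((seq_len(Fch) - fc) / bw)^2)
      W[, j] <- w / sqrt(sum(w^2))
    }
    # temporal filters: gamma-shaped with column-specific latency; later
    # columns may be suppressive (negative amplitude)
    u_grid <- 0:(n_lags - 1)
    H <- matrix(0, rank, n_lags)
    for (j in seq_len(rank)) {
      peak <- sample(1:4, 1)
      shape <- (u_grid / max(peak, 1))^2 * exp(-u_grid / max(peak, 1))
      amp <- runif(1, 0.5, 1) *
        (if (j == 1) 1 else sample(c(1, -1), 1, prob = c(0.7, 0.3)) *
           runif(1, 0.3, 0.8))
      H[j, ] <- amp * shape / max(shape)
    }
    strf <- strf_params(W, H)
    stp <- NULL
    if (arch_uses_stp(architecture)) {
      # strongly adapting synapses, the regime in which plasticity shapes
      # the response well beyond what a linear filter can mimic
      stp <- stp_params(u = runif(rank, 0.35, 0.55),
                        tau = runif(rank, 0.08, 0.15))
    }
    # calibrate the drive scale and the nonlinearity operating point on the
    # bank, using the post-adaptation drive so the sigmoid sees the
    # dynamics the synapses actually transmit
    drive_fun <- function(strf_) {
      unlist(lapply(bank$stimuli, function(sp) {
        forward_predict_cpp(
          spec_levels(sp), strf_$spectral_weights, strf_$temporal_filters,
          rep(0, 4), if (is.null(stp)) rep(0, rank) else stp$u,
          if (is.null(stp)) rep(0.1, rank) else stp$tau, rep(0, 4),
          numeric(0), !is.null(stp), FALSE, sp$bin_s, TRUE)
      }))
    }
    drive <- drive_fun(strf)
    target_sd <- 8
    H <- H * target_sd / max(sd(drive), 1e-9)
    strf <- strf_params(W, H)
    drive <- drive * target_sd / max(sd(drive), 1e-9)
    nl <- nl_params(
      b = runif(1, 0.5, 2),
      a = runif(1, 25, 45),
      s = as.numeric(quantile(drive, 0.6)),
      k = runif(1, 1.2, 1.8) / target_sd
    )
    gc <- NULL
    if (arch_uses_gc(architecture)) {
      # strong contrast modulation: gain and amplitude drop markedly from
      # low- to high-contrast epochs, baseline rises
      gc <- gc_params(theta1 = c(
        b = nl$b + runif(1, 0.15, 0.3) * nl$a,
        a = runif(1, 0.1, 0.25) * nl$a,
        s = nl$s,
        k = runif(1, 0.1, 0.2) * nl$k
      ))
    }
    model <- fitted_model(architecture, strf, nl, stp = stp, gc = gc,
                          meta = list(seed = seed, ground_truth = TRUE))
    calibrate_contrast_norm(model, bank)
  })
}

#' Ground-truth neuron specification
#'
#' Couples a ground-truth model with a trial-noise model. With
#' `noise = "none"` repeated simulations are bit-identical; `"gaussian"`
#' adds independent zero-mean noise of the given SD to every bin;
#' `"poisson"` draws spike counts per bin from the predicted rate.
#'
#' @param model a [fitted_model()] ground truth.
#' @param noise `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_sd Gaussian noise SD in spikes/s (ignored otherwise).
#' @param seed integer seed for the trial noise.
#' @return an object of class `"ground_truth_neuron"`.
#' @export
ground_truth_neuron <- function(model, noise = c("none", "gaussian", "poisson"),
                                noise_sd = 0, seed = 1) {
  noise <- match.arg(noise)
  stopifnot(inherits(model, "fitted_model"))
  assert_scalar_number(noise_sd, "noise_sd", lower = 0)
  structure(list(model = model, architecture = model$architecture,
                 noise = noise, noise_sd = noise_sd, seed = seed),
            class = "ground_truth_neuron")
}

#' Simulate trial-by-trial responses of a ground-truth neuron
#'
#' Predicts the noiseless PSTH for every stimulus in the bank and draws
#' repeated trials around it. A minority of stimuli (about `val_frac`) is
#' held out as the high-repetition validation set; the rest form the
#' low-repetition estimation set, emulating the estimation/validation design
#' of chronic natural-sound recordings.
#'
#' @param neuron a [ground_truth_neuron()].
#' @param bank a [generate_stimulus_bank()] bank.
#' @param n_reps_est repetitions per estimation stimulus (default 3).
#' @param n_reps_val repetitions per validation stimulus (default 24).
#' @param val_frac fraction of stimuli held out for validation (default
#'   0.1, at least one stimulus). In labeled clean/noisy banks the
#'   validation set is drawn from both labels when possible.
#' @return an object of class `"neuron_response"`: list with `resp` (per
#'   stimulus repetition x time matrices), `pred` (noiseless predictions),
#'   `est_idx`, `val_idx`, the ground-truth `neuron` and `bin_s`.
#' @export
simulate_neuron <- function(neuron, bank, n_reps_est = 3, n_reps_val = 24,
                            val_frac = 0.1) {
  stopifnot(inherits(neuron, "ground_truth_neuron"),
            inherits(bank, "stimulus_bank"))
  n <- length(bank$stimuli)
  pred <- lapply(bank$stimuli, function(sp) predict(neuron$model, sp))

  n_val <- max(1, round(val_frac * n))
  val_idx <- with_local_seed(derive_seed(neuron$seed, 101), {
    if (all(c("clean", "noisy") %in% bank$labels) && n_val >= 2) {
      cl <- which(bank$labels == "clean")
      no <- which(bank$labels == "noisy")
      k1 <- ceiling(n_val / 2)
      sort(c(sample(cl, min(k1, length(cl))),
             sample(no, min(n_val - k1, length(no)))))
    } else {
      sort(sample(n, n_val))
    }
  })
  est_idx <- setdiff(seq_len(n), val_idx)

  resp <- with_local_seed(derive_seed(neuron$seed, 202), {
    lapply(seq_len(n), function(j) {
      m <- if (j %in% val_idx) n_reps_val else n_reps_est
      mu <- pred[[j]]
      if (neuron$noise == "none") {
        matrix(rep(mu, each = m), nrow = m)
      } else if (neuron$noise == "gaussian") {
        matrix(rep(mu, each = m), nrow = m) +
          matrix(rnorm(m * length(mu), sd = neuron$noise_sd), nrow = m)
      } else {
        lam <- mu
        if (any(lam < 0)) {
          warn("negative rates clamped to zero for Poisson sampling")
          lam <- pmax(lam, 0)
        }
        bin_s <- bank$stimuli[[j]]$bin_s
        matrix(rpois(m * length(lam), lambda = rep(lam * bin_s, each = m)),
               nrow = m) / bin_s
      }
    })
  })

  structure(list(neuron = neuron, resp = resp, pred = pred,
                 est_idx = est_idx, val_idx = val_idx,
                 n_reps_est = n_reps_est, n_reps_val = n_reps_val,
                 bin_s = bank$stimuli[[1]]$bin_s),
            class = "neuron_response")
}

#' @export
print.neuron_response <- function(x, ...) {
  cat(sprintf(
    "<neuron_response> %s ground truth (%s noise): %d est stimuli x %d reps, %d val stimuli x %d reps\n",
    x$neuron$architecture, x$neuron$noise, length(x$est_idx), x$n_reps_est,
    length(x$val_idx), x$n_reps_val))
  invisible(x)
}

#' Generate a synthetic population of model neurons
#'
#' Draws `n_neurons` ground-truth neurons with architectures in the given
#' mixture, simulates their responses to the bank with Gaussian trial noise,
#' and returns neuron/response pairs with known class labels for recovery
#' scoring. Noise levels are expressed relative to the SD of each neuron's
#' noiseless prediction and cycled across neurons.
#'
#' @param n_neurons number of neurons (0 gives an empty population).
#' @param class_mixture named vector of mixture fractions over
#'   architectures; must sum to 1.
#' @param bank a [generate_stimulus_bank()] bank.
#' @param noise_levels relative Gaussian noise SDs (default `c(0.5, 1)`).
#' @param seed integer master seed.
#' @param n_reps_est,n_reps_val repetitions for the estimation/validation
#'   stimuli.
#' @param val_frac fraction of stimuli held out for validation.
#' @return a list of `list(neuron =, response =)` pairs with class
#'   `"population"`.
#' @export
generate_population <- function(n_neurons, class_mixture, bank,
                                noise_levels = c(0.5, 1), seed = 1,
                                n_reps_est = 3, n_reps_val = 24,
                                val_frac = 0.1) {
  if (length(class_mixture) == 0) {
    stop_audenc("class_mixture must not be empty", "audenc_config_error")
  }
  if (!all(names(class_mixture) %in% ARCHITECTURES)) {
    stop_audenc("class_mixture names must be model architectures",
                "audenc_config_error")
  }
  if (abs(sum(class_mixture) - 1) > 1e-8) {
    stop_audenc("class_mixture fractions must sum to 1", "audenc_config_error")
  }
  if (n_neurons == 0) return(structure(list(), class = "population"))

  # largest-remainder apportionment of classes
  exact <- class_mixture * n_neurons
  counts <- floor(exact)
  rem <- n_neurons - sum(counts)
  if (rem > 0) {
    order_rem <- order(exact - counts, decreasing = TRUE)
    counts[order_rem[seq_len(rem)]] <- counts[order_rem[seq_len(rem)]] + 1
  }
  classes <- rep(names(counts), times = counts)

  pop <- lapply(seq_len(n_neurons), function(i) {
    model <- random_model(classes[i], bank, seed = derive_seed(seed, c(31, i)))
    pred_sd <- sd(unlist(lapply(bank$stimuli, function(sp) predict(model, sp))))
    level <- noise_levels[((i - 1) %% length(noise_levels)) + 1]
    neuron <- ground_truth_neuron(model, noise = "gaussian",
                                  noise_sd = level * pred_sd,
                                  seed = derive_seed(seed, c(32, i)))
    list(neuron = neuron,
         response = simulate_neuron(neuron, bank, n_reps_est, n_reps_val,
                                    val_frac = val_frac))
  })
  structure(pop, class = "population")
}
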