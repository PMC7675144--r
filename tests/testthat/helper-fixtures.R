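# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# small smooth-contrast bank used by most fitting tests
small_bank <- function() {
  if (is.null(.fixture_env$small_bank)) {
    .fixture_env$small_bank <- generate_stimulus_bank(
      "smooth_contrast", n_stimuli = 10, duration_s = 1.5, n_channels = 10,
      seed = 42)
  }
  .fixture_env$small_bank
}

# causal convolution oracle used both here and in the linear-drive tests
conv_causal <- function(x, h) {
  out <- numeric(length(x))
  for (u in seq_along(h)) {
    idx <- seq_along(x) - (u - 1)
    ok <- idx >= 1
    out[ok] <- out[ok] + h[u] * x[idx[ok]]
  }
  out
}

# a hand-built, identifiable STP ground truth on a given bank: spectrally
# separated non-negative synapses with distinct latencies, nonlinearity
# calibrated to the adapted drive
separated_stp_truth <- function(bank, u = c(0.45, 0.40, 0.35),
                                tau = c(0.10, 0.12, 0.08)) {
  Fch <- nrow(bank$stimuli[[1]]$levels)
  centers <- Fch * c(0.22, 0.5, 0.78)
  W <- vapply(centers, function(fc) {
    w <- exp(-0.5 * ((seq_len(Fch) - fc) / (Fch / 12))^2)
    w / sqrt(sum(w^2))
  }, numeric(Fch))
  ug <- 0:14
  H <- t(vapply(1:3, function(j) {
    s <- (ug / j)^2 * exp(-ug / j)
    0.9 * s / max(s)
  }, numeric(15)))
  stp <- stp_params(u, tau)
  adapted_drive <- function(H) {
    unlist(lapply(bank$stimuli, function(sp) {
      xs <- stp_transform(t(W) %*% sp$levels, stp, sp$bin_s)
      drv <- numeric(ncol(xs))
      for (i in 1:3) drv <- drv + conv_causal(xs[i, ], H[i, ])
      drv
    }))
  }
  adapted <- adapted_drive(H)
  H <- H * 8 / sd(adapted)
  adapted <- adapted * 8 / sd(adapted)
  nl <- nl_params(b = 1, a = 30, s = as.numeric(quantile(adapted, 0.6)),
                  k = 1.5 / 8)
  fitted_model("STP", strf_params(W, H), nl, stp = stp)
}

# simple random LN model for forward-path tests (no bank calibration)
toy_ln_model <- function(Fch = 10, seed = 7) {
  withr::with_seed(seed, {
    W <- matrix(rnorm(Fch * 3), Fch, 3)
    W <- apply(W, 2, function(w) w / sqrt(sum(w^2)))
    H <- matrix(rnorm(3 * 15, sd = 0.3), 3, 15)
    fitted_model("LN", strf_params(W, H), nl_params(1, 20, 2, 0.3))
  })
}
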