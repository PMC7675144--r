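# Synthetic stimulus banks. Spectrograms are built directly in log-level
# space as sums of sparse spectro-temporal ridges over a slowly
# amplitude-modulated noise floor, which gives naturalistic contrast
# dynamics without any audio source material. Noisy variants mix the clean
# linear-power spectrogram with a flat broadband floor whose power equals
# the clean stimulus's mean power (a 0 dB SNR equivalent in spectrogram
# space).

REGIMES <- c("smooth_contrast", "bimodal_clean_noisy")

# one synthetic "natural" log-spectrogram; depth scales ridge amplitudes and
# modulation, i.e. the overall contrast of the sample
gen_synth_levels <- function(n_channels, n_bins, depth) {
  Fch <- n_channels
  Tb <- n_bins
  # smoothed noise background with slow (1/f-like) amplitude modulation
  E <- matrix(rnorm(Fch * Tb), Fch, Tb)
  E <- t(apply(E, 1, smooth_ma, 5))
  if (Fch >= 3) E <- apply(E, 2, smooth_ma, 3)
  env <- abs(smooth_ma(rnorm(Tb), 25)) + abs(smooth_ma(rnorm(Tb), 80))
  env <- 0.25 + 0.75 * env / max(env, 1e-9)
  bg <- 0.35 * sweep(abs(E), 2, env, `*`)
  # sparse spectro-temporal ridges with sharp onsets and slower decays,
  # the temporal asymmetry characteristic of natural sound events
  n_ridges <- 3 + rpois(1, round(Tb / 40))
  L <- matrix(0, Fch, Tb)
  fgrid <- seq_len(Fch)
  tgrid <- seq_len(Tb)
  for (r in seq_len(n_ridges)) {
    fc <- runif(1, 1, Fch)
    bw <- runif(1, 0.8, 2.5)
    t0 <- runif(1, 1, Tb - 5)
    attack <- runif(1, 1, 3)          # bins (10-30 ms)
    decay <- runif(1, 8, 35)          # bins (80-350 ms)
    amp <- runif(1, 1.0, 2.5) * depth
    dt <- tgrid - t0
    env_t <- ifelse(dt >= 0, (1 - exp(-dt / attack)) * exp(-dt / decay), 0)
    L <- L + amp * outer(exp(-0.5 * ((fgrid - fc) / bw)^2), env_t)
  }
  # quiet gaps between sound events, long enough (200-450 ms) to let
  # adaptation and gain state recover between epochs
  gate <- rep(1, Tb)
  n_gaps <- 1 + rpois(1, Tb / 120)
  for (g in seq_len(n_gaps)) {
    g0 <- sample.int(Tb, 1)
    glen <- sample(20:45, 1)
    gate[g0:min(Tb, g0 + glen)] <- 0.05
  }
  L <- sweep(pmax(L + bg, 0), 2, gate, `*`)
  # texture segments: some epochs are replaced by dense flat noise at a
  # comparable mean level, so contrast varies at roughly fixed level (the
  # acoustic-texture dimension that dissociates gain state from drive)
  t0 <- 1
  while (t0 < Tb) {
    t1 <- min(Tb, t0 + sample(50:120, 1) - 1)
    if (runif(1) < 0.4) {
      seg <- t0:t1
      m <- max(mean(L[, seg]), 0.4 * depth)
      tex <- matrix(rnorm(Fch * length(seg)), Fch, length(seg))
      if (Fch >= 3) tex <- apply(tex, 2, smooth_ma, 3)
      L[, seg] <- pmax(m * (1 + 0.1 * tex), 0)
    }
    t0 <- t1 + 1
  }
  L
}

# additive broadband floor at the clean stimulus's mean power (0 dB SNR
# equivalent), applied in the linear-power domain
add_noise_floor <- function(levels) {
  p <- 10^levels
  log10(p + mean(p))
}

#' Generate a synthetic stimulus bank
#'
#' Builds a bank of synthetic natural-sound-like log-spectrograms in one of
#' two contrast regimes: `"smooth_contrast"` draws per-stimulus contrast from
#' a continuous range (the statistics of a diverse natural-sound library),
#' while `"bimodal_clean_noisy"` pairs clean samples with noisy variants
#' whose linear power is mixed with a flat broadband floor, producing two
#' labeled clusters of high-contrast (clean) and low-contrast (noisy)
#' stimuli.
#'
#' @param regime `"smooth_contrast"` or `"bimodal_clean_noisy"`.
#' @param n_stimuli number of stimuli (at least 2). In the bimodal regime
#'   the bank holds `ceiling(n/2)` clean stimuli followed by their noisy
#'   counterparts.
#' @param duration_s duration of each stimulus in seconds (default 3).
#' @param n_channels number of spectrogram channels (default 18).
#' @param seed integer master seed; the same arguments and seed always
#'   reproduce the same bank.
#' @param bin_s time bin width in seconds.
#' @return an object of class `"stimulus_bank"`: list with `stimuli` (list of
#'   [spectrogram()]), `regime`, `labels` (`"clean"`, `"noisy"` or `"n/a"`),
#'   `sample_rate_hz` (100) and `seed`.
#' @examples
#' bank <- generate_stimulus_bank("smooth_contrast", n_stimuli = 4,
#'                                duration_s = 1, n_channels = 8, seed = 1)
#' bank
#' @export
generate_stimulus_bank <- function(regime, n_stimuli, duration_s = 3,
                                   n_channels = 18, seed = 1, bin_s = 0.01) {
  if (length(regime) != 1 || !regime %in% REGIMES) {
    stop_audenc(sprintf("unknown regime '%s'; use one of: %s",
                        paste(regime, collapse = ","),
                        paste(REGIMES, collapse = ", ")),
                "audenc_config_error")
  }
  if (n_stimuli < 2) stop_audenc("n_stimuli must be >= 2", "audenc_config_error")
  if (n_channels < 1) stop_audenc("n_channels must be >= 1", "audenc_config_error")
  n_bins <- round(duration_s / bin_s)
  centers <- log_spaced_centers(n_channels)

  if (regime == "smooth_contrast") {
    stimuli <- lapply(seq_len(n_stimuli), function(j) {
      with_local_seed(derive_seed(seed, c(11, j)), {
        depth <- runif(1, 0.5, 1.7)
        spectrogram(gen_synth_levels(n_channels, n_bins, depth), centers, bin_s)
      })
    })
    labels <- rep("n/a", n_stimuli)
  } else {
    n_clean <- ceiling(n_stimuli / 2)
    n_noisy <- n_stimuli - n_clean
    clean <- lapply(seq_len(n_clean), function(j) {
      with_local_seed(derive_seed(seed, c(11, j)), {
        depth <- runif(1, 1.1, 1.7)
        spectrogram(gen_synth_levels(n_channels, n_bins, depth), centers, bin_s)
      })
    })
    noisy <- lapply(seq_len(n_noisy), function(j) {
      spectrogram(add_noise_floor(clean[[j]]$levels), centers, bin_s)
    })
    stimuli <- c(clean, noisy)
    labels <- c(rep("clean", n_clean), rep("noisy", n_noisy))
  }

  structure(
    list(stimuli = stimuli, regime = regime, labels = labels,
         sample_rate_hz = 1 / bin_s, seed = seed, duration_s = duration_s),
    class = "stimulus_bank"
  )
}

#' @export
print.stimulus_bank <- function(x, ...) {
  cat(sprintf("<stimulus_bank> %s: %d stimuli, %d channels x %d bins each\n",
              x$regime, length(x$stimuli), nrow(x$stimuli[[1]]$levels),
              ncol(x$stimuli[[1]]$levels)))
  if (x$regime == "bimodal_clean_noisy") {
    cat(sprintf("  %d clean / %d noisy\n", sum(x$labels == "clean"),
                sum(x$labels == "noisy")))
  }
  invisible(x)
}

#' @export
length.stimulus_bank <- function(x) length(x$stimuli)

#' Per-stimulus level and contrast summary of a bank
#'
#' One row per stimulus with its label, mean and SD of the log-level, and
#' the time-averaged frequency-summed contrast. The (mean, SD) scatter is
#' unimodal for smooth-contrast banks and splits into two labeled clusters
#' for clean/noisy banks.
#'
#' @param bank a [generate_stimulus_bank()] bank.
#' @param window_ms,offset_ms contrast window passed to
#'   [compute_contrast()].
#' @return a tibble with columns `stimulus`, `label`, `mean_level`,
#'   `sd_level`, `mean_contrast`.
#' @export
bank_contrast_summary <- function(bank, window_ms = 70, offset_ms = 20) {
  purrr::map_dfr(seq_along(bank$stimuli), function(j) {
    sp <- bank$stimuli[[j]]
    K <- contrast_index(compute_contrast(sp, window_ms, offset_ms))
    valid <- K[K > 0]
    tibble(
      stimulus = j,
      label = bank$labels[j],
      mean_level = mean(sp$levels),
      sd_level = sd(as.vector(sp$levels)),
      mean_contrast = mean(if (length(valid)) valid else K)
    )
  })
}

#' Contrast scatter of a stimulus bank
#'
#' Scatter of per-stimulus SD versus mean log-level, colored by clean/noisy
#' label where available.
#'
#' @param object a [generate_stimulus_bank()] bank.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot stimulus_bank
#' @export
autoplot.stimulus_bank <- function(object, ...) {
  df <- bank_contrast_summary(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_level, .data$sd_level,
                                   colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean level", y = "SD of level", colour = NULL)
}

#' Write a stimulus bank to disk
#'
#' Stores the bank as a columnar long table (`stimuli.csv`: stimulus,
#' channel, bin, level) plus a JSON sidecar of metadata (regime, labels,
#' seed, channel centers).
#'
#' @param bank a [generate_stimulus_bank()] bank.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_stimulus_bank <- function(bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- purrr::map_dfr(seq_along(bank$stimuli), function(j) {
    lv <- bank$stimuli[[j]]$levels
    tibble(
      stimulus = j,
      channel = rep(seq_len(nrow(lv)), times = ncol(lv)),
      bin = rep(seq_len(ncol(lv)), each = nrow(lv)),
      level = as.vector(lv)
    )
  })
  utils::write.csv(long, file.path(dir, "stimuli.csv"), row.names = FALSE)
  meta <- list(regime = bank$regime, labels = bank$labels, seed = bank$seed,
               duration_s = bank$duration_s,
               sample_rate_hz = bank$sample_rate_hz,
               bin_s = bank$stimuli[[1]]$bin_s,
               channel_centers_hz = bank$stimuli[[1]]$channel_centers_hz)
  jsonlite::write_json(meta, file.path(dir, "bank.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a stimulus bank written by [write_stimulus_bank()]
#'
#' @param dir directory containing `stimuli.csv` and `bank.json`.
#' @return a `"stimulus_bank"` object.
#' @export
read_stimulus_bank <- function(dir) {
  meta <- jsonlite::fromJSON(file.path(dir, "bank.json"))
  long <- utils::read.csv(file.path(dir, "stimuli.csv"))
  stimuli <- lapply(sort(unique(long$stimulus)), function(j) {
    sub <- long[long$stimulus == j, ]
    lv <- matrix(0, max(sub$channel), max(sub$bin))
    lv[cbind(sub$channel, sub$bin)] <- sub$level
    spectrogram(lv, meta$channel_centers_hz, meta$bin_s)
  })
  structure(
    list(stimuli = stimuli, regime = meta$regime, labels = meta$labels,
         sample_rate_hz = meta$sample_rate_hz, seed = meta$seed,
         duration_s = meta$duration_s),
    class = "stimulus_bank"
  )
}
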