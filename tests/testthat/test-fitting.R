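# Staged estimation, objective, gradients and the noise-adjusted score.

test_that("mse matches a naive two-pass computation", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, 2, 3) + 0.5, c(1, 2, 3)), 0.25)
  withr::with_seed(31, {
    a <- rnorm(200); b <- rnorm(200)
  })
  naive <- 0
  for (i in seq_along(a)) naive <- naive + (a[i] - b[i])^2
  expect_equal(mse(a, b), naive / 200, tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), class = "audenc_shape_error")
})

test_that("the analytic gradient matches central finite differences", {
  bank <- generate_stimulus_bank("smooth_contrast", 3, 0.8, 8, seed = 33)
  stims <- lapply(bank$stimuli, function(s) s$levels)
  withr::with_seed(34, {
    resps <- lapply(stims, function(s) abs(rnorm(ncol(s), 5, 3)))
    par <- c(rnorm(8 * 3, 0, 0.3), rnorm(3 * 15, 0, 0.3), c(1, 20, 2, 0.3),
             runif(3, -0.3, 0.5), runif(3, 0.02, 0.5), c(2, 15, 2.5, 0.2))
  })
  Ks <- lapply(stims, function(s) {
    contrast_index(compute_contrast(spectrogram(s))) / 3
  })
  n <- length(par)
  combos <- list(c(FALSE, FALSE, TRUE), c(FALSE, FALSE, FALSE),
                 c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                 c(TRUE, TRUE, FALSE))
  for (cf in combos) {
    ga <- audenc:::model_gradient_cpp(par, stims, resps, Ks, 8L, 3L, 15L,
                                      cf[1], cf[2], cf[3], 0.01)
    gn <- audenc:::fit_gradient_cpp(par, seq_len(n) - 1L, stims, resps, Ks,
                                    8L, 3L, 15L, cf[1], cf[2], cf[3], 0.01)
    expect_lt(max(abs(ga - gn)), 1e-6)
  }
})

test_that("zero-iteration fits return the initialization with its loss", {
  bank <- small_bank()
  truth <- random_model("LN", bank, seed = 35)
  resp <- simulate_neuron(ground_truth_neuron(truth, "none", seed = 1), bank,
                          n_reps_est = 1, n_reps_val = 2)
  est <- fit_data(bank, resp, "est")
  f0 <- fit_model("LN", est, fit_config(maxit = 0, seed = 5))
  expect_s3_class(f0, "fitted_model")
  expect_true(all(c("strf_coarse", "nl_coarse", "joint_ln_fine") %in%
                    names(f0$meta$stage_loss)))
  # spectral columns are the unit-norm initialization, untouched by descent
  expect_equal(colSums(f0$strf$spectral_weights^2), rep(1, 3),
               tolerance = 1e-10)
})

test_that("fits are deterministic given data and seed", {
  bank <- small_bank()
  truth <- random_model("STP", bank, seed = 36)
  resp <- simulate_neuron(ground_truth_neuron(truth, "gaussian", 3, seed = 2),
                          bank, n_reps_est = 2, n_reps_val = 4)
  est <- fit_data(bank, resp, "est")
  cfg <- fit_config(maxit = 120, seed = 11)
  f1 <- fit_model("STP", est, cfg)
  f2 <- fit_model("STP", est, cfg)
  expect_identical(f1$strf, f2$strf)
  expect_identical(f1$stp, f2$stp)
  expect_identical(f1$meta$stage_loss, f2$meta$stage_loss)
})

test_that("staged fitting recovers a noise-free LN simulation", {
  bank <- small_bank()
  truth <- random_model("LN", bank, seed = 37)
  resp <- simulate_neuron(ground_truth_neuron(truth, "none", seed = 3), bank,
                          n_reps_est = 1, n_reps_val = 2, val_frac = 0.2)
  est <- fit_data(bank, resp, "est")
  fit <- fit_model("LN", est, fit_config(seed = 12, n_restarts = 2))
  sc <- score_model(fit, bank, resp)
  expect_gt(sc$r_raw, 0.99)
  # a stage never ends worse than the previous stage under the same
  # objective (the final joint stage refines the nonlinearity stage)
  sl <- fit$meta$stage_loss
  expect_lte(sl[["joint_ln_fine"]], sl[["nl_coarse"]] + 1e-12)
})

test_that("nested architectures never end worse than their LN stage", {
  bank <- small_bank()
  truth <- random_model("GC", bank, seed = 38)
  resp <- simulate_neuron(ground_truth_neuron(truth, "gaussian", 4, seed = 4),
                          bank, n_reps_est = 2, n_reps_val = 4)
  est <- fit_data(bank, resp, "est")
  for (arch in c("GC", "GC+STP")) {
    f <- fit_model(arch, est, fit_config(maxit = 150, seed = 13))
    sl <- f$meta$stage_loss
    expect_lte(sl[[length(sl)]], sl[["joint_ln_fine"]] + 1e-9)
  }
})

test_that("noise-adjusted correlation applies the split-half ceiling", {
  withr::with_seed(41, {
    signal <- abs(rnorm(600, 5, 3))
    reps <- matrix(rep(signal, each = 20), nrow = 20) +
      matrix(rnorm(20 * 600, sd = 3), nrow = 20)
  })
  # noise-free repetitions, perfect prediction: ceiling 1, R = 1
  clean <- matrix(rep(signal, each = 4), nrow = 4)
  expect_equal(as.numeric(noise_adjusted_correlation(signal, clean)), 1)
  # adjusted R approaches the correlation with the noiseless signal
  withr::with_seed(42, pred <- signal + rnorm(600, sd = 2))
  rho <- cor(pred, signal)
  r_adj <- noise_adjusted_correlation(pred, reps)
  expect_equal(as.numeric(r_adj), rho, tolerance = 0.05)
  # adjustment only raises a positive raw correlation
  expect_gte(as.numeric(r_adj), attr(r_adj, "raw"))
  # uncorrelated prediction scores near zero
  withr::with_seed(43, junk <- rnorm(600))
  expect_lt(abs(as.numeric(noise_adjusted_correlation(junk, reps))), 0.15)
  # degenerate cases
  expect_warning(r1 <- noise_adjusted_correlation(pred, reps[1, , drop = FALSE]))
  expect_equal(as.numeric(r1), cor(pred, reps[1, ]), tolerance = 1e-10)
  r0 <- noise_adjusted_correlation(rep(1, 600), reps)
  expect_equal(as.numeric(r0), 0)
  expect_true(attr(r0, "degenerate"))
})

test_that("fit configurations load from JSON documents", {
  path <- withr::local_tempfile(fileext = ".json")
  writeLines('{"maxit": 77, "tol_coarse": 1e-3, "seed": 9}', path)
  cfg <- fit_config_read(path)
  expect_equal(cfg$maxit, 77)
  expect_equal(cfg$tol_coarse, 1e-3)
  expect_equal(cfg$seed, 9)
  expect_equal(cfg$n_lags, 15)
})
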