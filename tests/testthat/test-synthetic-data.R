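# Synthetic stimulus banks and ground-truth neuron simulation.

test_that("smooth-contrast banks span a continuous contrast range", {
  bank <- generate_stimulus_bank("smooth_contrast", n_stimuli = 20,
                                 duration_s = 1, n_channels = 12, seed = 1)
  expect_length(bank$stimuli, 20)
  expect_true(all(bank$labels == "n/a"))
  cs <- bank_contrast_summary(bank)
  # continuous spread: no dominant two-cluster gap in per-stimulus contrast
  v <- sort(cs$mean_contrast)
  gaps <- diff(v)
  expect_lt(max(gaps), 0.6 * (max(v) - min(v)))
})

test_that("clean/noisy banks form two labeled contrast clusters", {
  bank <- generate_stimulus_bank("bimodal_clean_noisy", n_stimuli = 20,
                                 duration_s = 3, n_channels = 12, seed = 1)
  expect_equal(sum(bank$labels == "clean"), 10)
  expect_equal(sum(bank$labels == "noisy"), 10)
  cs <- bank_contrast_summary(bank)
  expect_lt(median(cs$mean_contrast[cs$label == "noisy"]),
            median(cs$mean_contrast[cs$label == "clean"]))
  # every noisy stimulus has strictly lower contrast than its clean source
  expect_true(all(cs$mean_contrast[cs$label == "noisy"] <
                    cs$mean_contrast[cs$label == "clean"]))
  # a blind two-component split on contrast recovers the labels exactly
  km <- kmeans(log10(cs$mean_contrast), centers = 2, nstart = 5)
  split_label <- km$cluster == km$cluster[which.max(cs$mean_contrast)]
  expect_true(all(split_label == (cs$label == "clean")))
})

test_that("bank generation is deterministic in the seed and validates input", {
  b1 <- generate_stimulus_bank("smooth_contrast", 4, 1, 8, seed = 9)
  b2 <- generate_stimulus_bank("smooth_contrast", 4, 1, 8, seed = 9)
  expect_identical(b1, b2)
  expect_error(generate_stimulus_bank("chirp_train", 4, 1, 8),
               class = "audenc_config_error")
  expect_error(generate_stimulus_bank("smooth_contrast", 1, 1, 8),
               class = "audenc_config_error")
})

test_that("noise-free simulation reproduces the forward prediction exactly", {
  bank <- small_bank()
  truth <- random_model("LN", bank, seed = 3)
  neuron <- ground_truth_neuron(truth, "none", seed = 5)
  resp <- simulate_neuron(neuron, bank, n_reps_est = 2, n_reps_val = 4)
  for (j in seq_along(bank$stimuli)) {
    expect_identical(resp$resp[[j]][1, ], resp$pred[[j]])
    expect_identical(resp$resp[[j]][nrow(resp$resp[[j]]), ], resp$pred[[j]])
  }
  expect_equal(reliability(resp$resp[resp$val_idx])$overall, 1)
  # est/val split is disjoint and the validation set is the minority
  expect_length(intersect(resp$est_idx, resp$val_idx), 0)
  expect_lt(length(resp$val_idx), length(resp$est_idx))
  # bit-identical under the same seed
  resp2 <- simulate_neuron(neuron, bank, n_reps_est = 2, n_reps_val = 4)
  expect_identical(resp$resp, resp2$resp)
})

test_that("noisy simulations have the forward prediction as their mean", {
  bank <- generate_stimulus_bank("smooth_contrast", 2, 0.5, 8, seed = 11)
  truth <- random_model("LN", bank, seed = 3)
  # Gaussian: exact expectation; check with many reps
  ng <- ground_truth_neuron(truth, "gaussian", noise_sd = 4, seed = 5)
  rg <- simulate_neuron(ng, bank, n_reps_est = 1000, n_reps_val = 1000,
                        val_frac = 0.5)
  mu_hat <- colMeans(rg$resp[[1]])
  se <- 4 / sqrt(1000)
  expect_lt(max(abs(mu_hat - rg$pred[[1]])), 6 * se)
  # Poisson: per-bin mean within Monte-Carlo error of the rate
  np <- ground_truth_neuron(truth, "poisson", seed = 5)
  rp <- simulate_neuron(np, bank, n_reps_est = 1500, n_reps_val = 1500,
                        val_frac = 0.5)
  mu <- rp$pred[[1]]
  mu_hat <- colMeans(rp$resp[[1]])
  se <- sqrt(pmax(mu, 1e-3) / 0.01) / sqrt(1500)   # sd of a rate estimate
  expect_lt(max(abs(mu_hat - mu) / pmax(se, 1e-6)), 6)
})

test_that("population generation honors the class mixture", {
  bank <- small_bank()
  pop <- generate_population(5, c(LN = 1), bank, seed = 2)
  expect_length(pop, 5)
  expect_true(all(vapply(pop, function(p) p$neuron$architecture,
                         character(1)) == "LN"))
  p1 <- generate_population(6, c(STP = 0.5, GC = 0.5), bank, seed = 4)
  p2 <- generate_population(6, c(STP = 0.5, GC = 0.5), bank, seed = 4)
  expect_identical(vapply(p1, function(p) p$neuron$architecture, character(1)),
                   vapply(p2, function(p) p$neuron$architecture, character(1)))
  expect_equal(sum(vapply(p1, function(p) p$neuron$architecture,
                          character(1)) == "STP"), 3)
  expect_length(generate_population(0, c(LN = 1), bank, seed = 1), 0)
  expect_error(generate_population(3, numeric(0), bank),
               class = "audenc_config_error")
  expect_error(generate_population(3, c(LN = 0.5), bank),
               class = "audenc_config_error")
})

test_that("stimulus banks round-trip through the on-disk format", {
  bank <- generate_stimulus_bank("bimodal_clean_noisy", 4, 0.5, 6, seed = 8)
  dir <- withr::local_tempdir()
  write_stimulus_bank(bank, dir)
  back <- read_stimulus_bank(dir)
  expect_equal(back$labels, bank$labels)
  expect_equal(back$regime, bank$regime)
  expect_equal(back$stimuli[[2]]$levels, bank$stimuli[[2]]$levels,
               tolerance = 1e-12)
})
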