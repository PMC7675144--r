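# Significance tests, equivalence analysis and the reliability metric.

test_that("permutation test is exact for self-prediction and flat for noise", {
  withr::with_seed(51, resp <- abs(rnorm(800, 5, 2)))
  p_self <- permutation_significance(resp, resp, n_perm = 999, seed = 1)
  expect_equal(as.numeric(p_self), 1 / 1000)
  # constant prediction is flagged, never significant
  p_const <- permutation_significance(rep(2, 800), resp, n_perm = 99, seed = 1)
  expect_equal(as.numeric(p_const), 1)
  expect_true(attr(p_const, "degenerate"))
  expect_error(permutation_significance(resp[1:60], resp[1:60]),
               class = "audenc_config_error")
  # null calibration: p-values of unrelated predictions are near-uniform
  # (oracle: empirical CDF over simulated neurons)
  withr::with_seed(52, {
    ps <- vapply(1:200, function(i) {
      as.numeric(permutation_significance(rnorm(300), rnorm(300),
                                          n_perm = 99, seed = i))
    }, numeric(1))
  })
  cdf <- ecdf(ps)
  expect_lt(max(abs(cdf(c(0.25, 0.5, 0.75)) - c(0.25, 0.5, 0.75))), 0.12)
})

test_that("jackknife improvement test behaves at its fixed points", {
  withr::with_seed(53, {
    signal <- abs(rnorm(900, 6, 3))
    reps <- matrix(rep(signal, each = 10), 10) + matrix(rnorm(9000, sd = 2), 10)
    good <- signal + rnorm(900, sd = 1)
    junk <- rnorm(900)
  })
  p_same <- jackknife_improvement(good, good, reps)
  expect_equal(as.numeric(p_same), 1)
  p_imp <- jackknife_improvement(junk, good, reps)
  expect_lt(as.numeric(p_imp), 1e-4)
  # large-sample z oracle on the same pseudo-values agrees qualitatively
  z_p <- pnorm(attr(p_imp, "statistic"), lower.tail = FALSE)
  expect_lt(z_p, 1e-4)
  # reversing the models flips the statistic's sign
  p_rev <- jackknife_improvement(good, junk, reps)
  expect_equal(attr(p_rev, "statistic"), -attr(p_imp, "statistic"),
               tolerance = 1e-10)
  expect_error(jackknife_improvement(good, good, reps, n_jack = 1),
               class = "audenc_config_error")
})

test_that("equivalence partial correlation matches its closed forms", {
  withr::with_seed(54, {
    ln <- abs(rnorm(1000, 5, 2))
    dev <- as.numeric(arima.sim(list(ar = 0.8), 1000))
  })
  # identical deviations: perfectly equivalent
  expect_equal(as.numeric(equivalence_partial_correlation(
    ln + dev, ln + dev, ln)), 1, tolerance = 1e-12)
  # orthogonal deviations: zero equivalence (Gram-Schmidt construction)
  withr::with_seed(55, {
    e1 <- rnorm(1000); e2 <- rnorm(1000)
  })
  e1 <- resid(lm(e1 ~ ln))
  e2 <- resid(lm(e2 ~ ln + e1))
  expect_equal(as.numeric(equivalence_partial_correlation(
    ln + e1, ln + e2, ln)), 0, tolerance = 1e-10)
  # random triple: regress-out-then-correlate oracle
  withr::with_seed(56, {
    a <- ln + rnorm(1000); b <- ln + rnorm(1000)
  })
  oracle <- cor(resid(lm(a ~ ln)), resid(lm(b ~ ln)))
  got <- as.numeric(equivalence_partial_correlation(a, b, ln))
  expect_equal(got, oracle, tolerance = 1e-10)
  # symmetric in the two models; invariant to affine rescaling
  expect_equal(as.numeric(equivalence_partial_correlation(b, a, ln)), got)
  expect_equal(as.numeric(equivalence_partial_correlation(
    2 * a + 3, 0.5 * b - 1, ln)), got, tolerance = 1e-10)
  # degenerate: a model numerically identical to the reference
  degen <- equivalence_partial_correlation(ln, b, ln)
  expect_true(is.na(degen))
  expect_true(attr(degen, "degenerate"))
})

test_that("the split-half ceiling correction follows the stated ratio", {
  expect_equal(corrected_within_equivalence(0.4, 0.3, 0.2), 0.6)
  expect_equal(corrected_within_equivalence(0.5, 0.2, 0.2), 0.5)
  expect_equal(corrected_within_equivalence(0.4, 0.6, 0.4),
               corrected_within_equivalence(0.4, 0.3, 0.2))
  bad <- corrected_within_equivalence(0.4, 0.3, 0)
  expect_true(is.na(bad))
  expect_true(attr(bad, "degenerate"))
})

test_that("effect size is the mean improvement over the LN model", {
  expect_equal(effect_size(0.5, 0.5, 0.5), 0)
  expect_equal(effect_size(0.6, 0.8, 0.5), 0.2)
  expect_equal(effect_size(0.6 + 0.1, 0.8 + 0.1, 0.5 + 0.1), 0.2)
})

test_that("reliability measures the signal fraction of repeated responses", {
  withr::with_seed(61, signal <- abs(rnorm(500, 5, 3)))
  # identical repetitions are perfectly reliable
  ident <- matrix(rep(signal, each = 6), 6)
  expect_equal(reliability(ident)$overall, 1)
  # overall reliability is the mean of the per-stimulus values
  withr::with_seed(62, {
    r2 <- lapply(1:3, function(i) {
      matrix(rep(signal, each = 8), 8) + matrix(rnorm(8 * 500, sd = i), 8)
    })
  })
  rel <- reliability(r2)
  expect_equal(rel$overall, mean(rel$per_stimulus))
  # reliability decreases monotonically with noise
  expect_true(all(diff(rel$per_stimulus) < 0))
  # unbiased for S / (S + N) under additive independent noise
  S <- mean(signal^2)
  for (ratio in c(1, 3)) {
    sd_n <- sqrt(S / ratio)
    withr::with_seed(63 + ratio, {
      vals <- vapply(1:60, function(i) {
        reps <- matrix(rep(signal, each = 12), 12) +
          matrix(rnorm(12 * 500, sd = sd_n), 12)
        reliability(reps)$overall
      }, numeric(1))
    })
    expect_equal(mean(vals), S / (S + sd_n^2), tolerance = 0.01)
  }
  # pure noise: zero reliability in expectation
  withr::with_seed(66, {
    noise_vals <- vapply(1:200, function(i) {
      reliability(matrix(rnorm(6 * 100), 6))$overall
    }, numeric(1))
  })
  expect_lt(abs(mean(noise_vals)), 0.02)
  # all-zero repetition rows are skipped with a count; the surviving
  # ratios still see the zero repetition in their cross terms
  z <- matrix(rep(signal, each = 3), 3)
  z[2, ] <- 0
  rz <- reliability(z)
  expect_equal(rz$n_skipped, 1)
  expect_equal(rz$overall, 0.5)
})

test_that("within-model ceilings are deterministic and noise-sensitive", {
  bank <- small_bank()
  truth <- random_model("GC", bank, seed = 71)
  cfg <- fit_config(maxit = 400, n_restarts = 2, seed = 21)
  run_ceiling <- function(noise_sd, seed) {
    resp <- simulate_neuron(ground_truth_neuron(truth, if (noise_sd > 0)
      "gaussian" else "none", noise_sd, seed = 6), bank,
      n_reps_est = 2, n_reps_val = 6, val_frac = 0.2)
    est <- fit_data(bank, resp, "est")
    val <- fit_data(bank, resp, "val")
    ln <- fit_model("LN", est, cfg)
    within_model_ceiling("GC", est, val, ln, cfg, seed = seed)
  }
  w0a <- run_ceiling(0, seed = 31)
  w0b <- run_ceiling(0, seed = 31)
  expect_identical(w0a$w_half, w0b$w_half)
  # noise-free split halves see the same optimum: ceiling near 1
  expect_gt(as.numeric(w0a$w_half), 0.8)
  # a noise ladder lowers the ceiling monotonically at these seeds
  w_noise <- vapply(c(8, 20), function(sd_n) {
    as.numeric(run_ceiling(sd_n, seed = 31)$w_half)
  }, numeric(1))
  expect_true(all(diff(c(as.numeric(w0a$w_half), w_noise)) < 0))
})
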