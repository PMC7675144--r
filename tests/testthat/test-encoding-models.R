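# Forward-model building blocks and the four architectures.

test_that("linear drive equals the full-filter convolution", {
  # zero input, impulse response, and a random-case oracle
  strf <- toy_ln_model(Fch = 10)$strf
  expect_equal(linear_drive(matrix(0, 10, 40), strf), rep(0, 40))

  imp <- matrix(0, 10, 30)
  imp[4, 7] <- 1
  drv <- linear_drive(imp, strf)
  eff <- effective_filter(strf)
  expect_equal(drv[7:21], unname(eff[4, ]), tolerance = 1e-12)
  expect_equal(drv[1:6], rep(0, 6))

  withr::with_seed(21, {
    spec <- matrix(abs(rnorm(18 * 60)), 18, 60)
    W <- matrix(rnorm(18 * 3), 18, 3)
    H <- matrix(rnorm(3 * 15, sd = 0.5), 3, 15)
  })
  strf2 <- strf_params(W, H)
  # oracle: direct double sum over channels and lags with the expanded filter
  eff2 <- W %*% H
  oracle <- vapply(seq_len(60), function(t) {
    acc <- 0
    for (f in 1:18) for (u in 0:14) {
      if (t - u >= 1) acc <- acc + eff2[f, u + 1] * spec[f, t - u]
    }
    acc
  }, numeric(1))
  expect_equal(linear_drive(spec, strf2), oracle, tolerance = 1e-10)
  expect_error(linear_drive(matrix(0, 5, 10), strf2),
               class = "audenc_shape_error")
})

test_that("double exponential nonlinearity has the stated closed forms", {
  p <- nl_params(b = 2, a = 10, s = 1.5, k = 0.8)
  expect_equal(double_exponential(p$s, p), p$b + p$a * exp(-1))
  expect_equal(double_exponential(seq(-5, 5), nl_params(3, 0, 0, 1)),
               rep(3, 11))
  # increasing for k > 0 (dense finite-difference oracle); strictly so
  # away from the numerically saturated tails
  x <- seq(-30, 30, length.out = 2000)
  expect_true(all(diff(double_exponential(x, p)) >= 0))
  xc <- x[x > -2 & x < 8]
  expect_true(all(diff(double_exponential(xc, p)) > 0))
  # bounded in [b, b + a]
  y <- double_exponential(seq(-1e3, 1e3, length.out = 999), p)
  expect_true(all(y >= p$b & y <= p$b + p$a))
})

test_that("STP availability follows the depression/facilitation updates", {
  p <- stp_params(u = c(0.2, 0.2, 0.2), tau = c(0.1, 0.1, 0.1))
  # u = 0: transform is the identity
  x <- matrix(abs(rnorm(3 * 80)), 3)
  out0 <- stp_transform(x, stp_params(rep(0, 3), rep(0.1, 3)))
  expect_identical(unclass(out0)[, ], x)
  # zero input: availability stays at its fixed point 1
  outz <- stp_transform(matrix(0, 3, 50), p)
  expect_true(all(attr(outz, "availability") == 1))
  # constant drive converges to the algebraic fixed point of the update
  sbar <- 2.5
  out <- stp_transform(matrix(sbar, 3, 600), p, bin_s = 0.01)
  d_end <- attr(out, "availability")[, 600]
  d_star <- 1 / (1 + 0.2 * sbar * 0.1 / 0.01)
  expect_equal(unname(d_end), rep(d_star, 3), tolerance = 1e-6)
  # iterated-update oracle agrees with the C++ recursion
  d <- 1
  for (t in 2:600) d <- d - 0.2 * sbar * d + (1 - d) * 0.01 / 0.1
  expect_equal(unname(d_end[1]), d, tolerance = 1e-12)
  # availability bounds: always within [0, 2]; pure depression stays in (0, 1]
  withr::with_seed(2, xr <- matrix(abs(rnorm(3 * 300, 3, 2)), 3))
  dmat <- attr(stp_transform(xr, stp_params(rep(0.9, 3), rep(0.02, 3))),
               "availability")
  expect_true(all(dmat >= 0 & dmat <= 1))
  dfac <- attr(stp_transform(xr, stp_params(rep(-0.5, 3), rep(0.05, 3))),
               "availability")
  expect_true(all(dfac >= 1 - 1e-12 & dfac <= 2))
  expect_error(stp_params(c(0, 0, 0), c(0.1, -1, 0.1)),
               class = "audenc_param_error")
})

test_that("rolling contrast matches the windowed coefficient of variation", {
  # constant level: zero variance, zero contrast
  expect_true(all(compute_contrast(matrix(3, 4, 50)) == 0))
  # scale invariance of the CV on linear-domain levels
  withr::with_seed(6, lin <- matrix(abs(rnorm(5 * 60, 10, 3)), 5))
  expect_equal(compute_contrast(lin), compute_contrast(5 * lin),
               tolerance = 1e-12)
  # two-level square wave: enumerated-window oracle
  L1 <- 1; L2 <- 3
  sq <- matrix(rep(c(L1, L2), length.out = 100), 1, 100, byrow = TRUE)
  C <- compute_contrast(sq, window_ms = 80, offset_ms = 20)
  # an 8-bin window holds four of each level regardless of phase
  vals <- rep(c(L1, L2), each = 4)
  cv <- sd(vals) / mean(vals)
  expect_equal(unique(round(C[1, 30:90], 12)), round(cv, 12))
  expect_error(compute_contrast(sq, window_ms = 10),
               class = "audenc_config_error")
  expect_error(compute_contrast(sq, window_ms = 75),
               class = "audenc_config_error")
})

test_that("the contrast index sums channels and honors its normalizer", {
  expect_equal(contrast_index(matrix(0, 3, 10)), rep(0, 10))
  C1 <- matrix(0, 4, 6); C1[2, ] <- seq(0.1, 0.6, by = 0.1)
  expect_equal(contrast_index(C1), C1[2, ])
  withr::with_seed(8, Cr <- matrix(runif(5 * 20), 5))
  expect_equal(contrast_index(Cr), apply(Cr, 2, sum))
  expect_equal(contrast_index(Cr, normalizer = 2), colSums(Cr) / 2)
})

test_that("contrast modulation interpolates the nonlinearity parameters", {
  base <- nl_params(1, 20, 2, 0.5)
  gc <- gc_params(theta1 = c(b = 3, a = 10, s = 2, k = 0.2))
  x <- seq(-10, 10, length.out = 101)
  expect_identical(modulated_nonlinearity(x, rep(0, 101), base, gc),
                   double_exponential(x, base))
  expect_equal(modulated_nonlinearity(x, rep(1, 101), base, gc),
               double_exponential(x, nl_params(3, 10, 2, 0.2)),
               tolerance = 1e-14)
  same <- gc_params(theta1 = c(b = base$b, a = base$a, s = base$s, k = base$k))
  withr::with_seed(9, K <- runif(101))
  expect_identical(modulated_nonlinearity(x, K, base, same),
                   double_exponential(x, base))
  # bin-wise linearity in K: moving K by eps moves each theta by delta * eps
  eps <- 1e-4
  th_a <- function(K) base$a + (gc$theta1[["a"]] - base$a) * K
  expect_equal(th_a(K + eps) - th_a(K), rep((10 - 20) * eps, 101))
})

test_that("restricting the extra mechanisms reproduces the LN prediction bitwise", {
  bank <- small_bank()
  full <- random_model("GC+STP", bank, seed = 13)
  ln <- fitted_model("LN", full$strf, full$nl)
  spec <- bank$stimuli[[3]]

  stp0 <- full
  stp0$stp$u[] <- 0
  stp0$gc$theta1 <- c(b = full$nl$b, a = full$nl$a, s = full$nl$s,
                      k = full$nl$k)
  expect_identical(predict(stp0, spec), predict(ln, spec))

  stp_only <- random_model("STP", bank, seed = 13)
  stp_only$stp$u[] <- 0
  expect_identical(predict(stp_only, spec),
                   predict(fitted_model("LN", stp_only$strf, stp_only$nl),
                           spec))

  gc_only <- random_model("GC", bank, seed = 13)
  gc_only$gc$theta1 <- c(b = gc_only$nl$b, a = gc_only$nl$a, s = gc_only$nl$s,
                         k = gc_only$nl$k)
  expect_identical(predict(gc_only, spec),
                   predict(fitted_model("LN", gc_only$strf, gc_only$nl),
                           spec))

  # prediction is pure: repeated calls agree bitwise, output is non-negative
  p1 <- predict(full, spec)
  p2 <- predict(full, spec)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0))
})

test_that("architecture and parameter-group pairing is enforced", {
  m <- toy_ln_model()
  expect_error(fitted_model("STP", m$strf, m$nl),
               class = "audenc_structure_error")
  expect_error(fitted_model("LN", m$strf, m$nl,
                            stp = stp_params(rep(0.1, 3), rep(0.1, 3))),
               class = "audenc_structure_error")
  expect_error(fitted_model("GC", m$strf, m$nl),
               class = "audenc_structure_error")
  gc_model <- fitted_model("GC", m$strf, m$nl,
                           gc = gc_params(c(b = 1, a = 2, s = 0, k = 1)))
  expect_error(predict(gc_model, matrix(1, 10, 30)),
               class = "audenc_structure_error")  # uncalibrated normalizer
})

test_that("models serialize to JSON and back without loss", {
  bank <- small_bank()
  for (arch in c("LN", "STP", "GC", "GC+STP")) {
    m <- random_model(arch, bank, seed = 17)
    back <- model_from_json(model_to_json(m))
    expect_equal(back$strf$spectral_weights, m$strf$spectral_weights,
                 tolerance = 1e-12)
    expect_equal(unlist(back$nl), unlist(m$nl), tolerance = 1e-12)
    spec <- bank$stimuli[[1]]
    expect_equal(predict(back, spec), predict(m, spec), tolerance = 1e-10)
  }
  path <- withr::local_tempfile(fileext = ".json")
  m <- random_model("STP", bank, seed = 18)
  model_to_json(m, path)
  expect_equal(model_from_json(path)$stp$u, m$stp$u, tolerance = 1e-12)
})
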