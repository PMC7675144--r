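# Gammatone spectrogram frontend and WAV I/O.

fs <- 44100

test_that("digital silence maps to the compression floor", {
  sp <- gammatone_spectrogram(rep(0, fs %/% 2), fs, n_channels = 6)
  expect_true(all(sp$levels == 0))
})

test_that("output shape follows the 10-ms bin contract", {
  x <- sin(2 * pi * 500 * seq(0, 0.337, by = 1 / fs))
  sp <- gammatone_spectrogram(x, fs)
  expect_equal(nrow(sp$levels), 18)
  expect_equal(ncol(sp$levels), ceiling(length(x) / fs / 0.01))
  expect_true(all(is.finite(sp$levels)))
  expect_true(all(diff(sp$channel_centers_hz) > 0))
  expect_equal(sp$channel_centers_hz[1], 200, tolerance = 1e-6)
  expect_equal(sp$channel_centers_hz[18], 20000, tolerance = 1e-6)
})

test_that("a pure tone peaks in the channel whose filter passes it best", {
  # oracle: order-2 gammatone magnitude response evaluated analytically
  centers <- log_spaced_centers(12, 200, 20000)
  gt_mag <- function(f, fc) {
    b <- 1.019 * 24.7 * (4.37 * fc / 1000 + 1)
    (1 + ((f - fc) / b)^2)^(-1)   # order-2 resonance envelope
  }
  for (j in c(3, 7, 10)) {
    tone_f <- centers[j]
    expected <- which.max(vapply(centers, function(fc) gt_mag(tone_f, fc),
                                 numeric(1)))
    x <- sin(2 * pi * tone_f * seq(0, 0.5, by = 1 / fs))
    sp <- gammatone_spectrogram(x, fs, n_channels = 12)
    expect_equal(which.max(rowMeans(sp$levels)), expected)
    expect_equal(expected, j)
  }
})

test_that("doubling the waveform shifts above-floor levels by a constant", {
  withr::with_seed(3, {
    x <- rnorm(fs %/% 2) * 0.1
  })
  s1 <- gammatone_spectrogram(x, fs, n_channels = 8)$levels
  s2 <- gammatone_spectrogram(2 * x, fs, n_channels = 8)$levels
  strong <- s1 > 1   # well above the compression floor
  shifts <- (s2 - s1)[strong]
  expect_equal(mean(shifts), log10(2), tolerance = 0.05)
  expect_lt(sd(shifts), 0.03)
})

test_that("spectrograms concatenate away from the boundary region", {
  withr::with_seed(4, {
    a <- rnorm(fs) * 0.1
    b <- rnorm(fs) * 0.1
  })
  sa <- gammatone_spectrogram(a, fs, n_channels = 6)$levels
  sab <- gammatone_spectrogram(c(a, b), fs, n_channels = 6)$levels
  expect_equal(sab[, 1:ncol(sa)], sa, tolerance = 1e-5)
  # second half matches the isolated spectrogram once filter memory fades
  sb <- gammatone_spectrogram(b, fs, n_channels = 6)$levels
  margin <- 30   # 300 ms
  expect_equal(sab[, (ncol(sa) + margin):(2 * ncol(sa))],
               sb[, margin:ncol(sb)], tolerance = 0.02)
})

test_that("sample rates below Nyquist for the top channel are rejected", {
  expect_error(gammatone_spectrogram(rnorm(1000), 16000),
               class = "audenc_nyquist_error")
  expect_error(gammatone_spectrogram(rnorm(1000)),
               class = "audenc_config_error")
})

test_that("WAV files round-trip through the reader and writer", {
  withr::with_seed(5, x <- round(runif(2000, -0.5, 0.5) * 32767) / 32767)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, 22050, path)
  back <- read_wav(path)
  expect_equal(back$sample_rate_hz, 22050)
  expect_equal(back$samples, x, tolerance = 1e-4)
  # the reader's list output feeds straight into the frontend
  sp <- gammatone_spectrogram(read_wav(path), n_channels = 4, f_high = 10000)
  expect_equal(nrow(sp$levels), 4)
})
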