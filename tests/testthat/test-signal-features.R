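test_that("discrete TKEO matches its three-sample definition", {
  expect_equal(tkeo_discrete(c(3, 3, 3, 3))$values, rep(0, 4))
  expect_equal(tkeo_discrete(c(1, 2, 3))$values[2], 4 - 1 * 3)
  # brute-force elementwise evaluation on random signals, exact equality
  for (s in 1:20) {
    x <- withr::with_seed(s, round(rnorm(50), 3))
    got <- tkeo_discrete(x)$values
    expected <- vapply(2:49, function(n) x[n]^2 - x[n - 1] * x[n + 1],
                       numeric(1))
    expect_identical(got[2:49], expected)
    expect_identical(got[1], got[2])
    expect_identical(got[50], got[49])
  }
  expect_error(tkeo_discrete(c(1, 2)), "length >= 3")
})

test_that("TKEO of a sampled cosine is the constant A^2 sin(w)^2", {
  for (A in c(0.5, 1, 2)) {
    for (w in c(pi / 8, pi / 4, pi / 2)) {
      x <- A * cos(w * (0:63))
      vals <- tkeo_discrete(x)$values[2:63]
      expect_lt(max(abs(vals - A^2 * sin(w)^2)), 1e-9)
    }
  }
})

test_that("continuous TKEO recovers analytic energies of simple signals", {
  dt <- 1e-3
  t <- seq(0, 1, by = dt)
  ramp <- tkeo_continuous(5 * t, dt)
  i <- 2:(length(t) - 1)
  expect_lt(max(abs(ramp$values[i] - 25)), 1e-6)
  expect_equal(tkeo_continuous(rep(2, 10), dt)$values, rep(0, 10))
  Omega <- 2 * pi * 4
  cosv <- tkeo_continuous(1.5 * cos(Omega * t), dt)
  expect_lt(max(abs(cosv$values[i] - 1.5^2 * Omega^2)) / (1.5^2 * Omega^2),
            1e-3)
  expect_error(tkeo_continuous(1:4, dt), "length >= 5")
  expect_error(tkeo_continuous(1:10, 0), "dt")
})

test_that("spectrogram peak frequency matches a Fourier oracle", {
  fs <- 256
  x <- sin(2 * pi * 10 * (0:1023) / fs)
  seg <- structure(list(samples = matrix(x, 1), sampling_rate = fs,
                        label = "normal", segment_id = "tone"),
                   class = "eeg_segment")
  img <- to_spectrogram(seg, 1, apply_tkeo = FALSE)
  prof <- rowMeans(img$pixels)
  peak_freq <- img$freq[which.max(prof)]
  # oracle: location of the periodogram peak
  sp <- Mod(stats::fft(x))^2
  freq <- (seq_along(x) - 1) * fs / length(x)
  oracle_peak <- freq[which.max(sp[freq <= fs / 2])]
  bin_width <- diff(img$freq[1:2])
  expect_lte(abs(peak_freq - oracle_peak), bin_width)
})

test_that("degenerate and repeated spectrograms behave predictably", {
  cfg <- generator_config(background_amp = 0, seed = 1L)
  zero_seg <- generate_segment("normal", cfg)
  img <- to_spectrogram(zero_seg, 1)
  expect_true(all(img$pixels == img$pixels[1, 1]))
  cfg2 <- generator_config(seed = 4L)
  seg <- generate_segment("ictal", cfg2)
  expect_identical(to_spectrogram(seg, 1)$pixels, to_spectrogram(seg, 1)$pixels)
  expect_error(to_spectrogram(seg, 99L), "does not exist")
  expect_error(to_spectrogram(seg, 1, stft_params(window = 4096)),
               "longer than segment")
})

test_that("one-second segments image to a single-frame spectrogram", {
  cfg <- generator_config(segment_length_s = 1, seed = 6L)
  seg <- generate_segment("ictal", cfg)
  img <- to_spectrogram(seg, 1)
  expect_equal(ncol(img$pixels), 1L)
  expect_true(all(img$pixels >= 0 & img$pixels <= 255))
  r <- resize_image(img, 32)
  expect_equal(dim(r$pixels), c(32L, 32L))
})

test_that("resize produces the published backbone input sizes", {
  img <- random_image(33, seed = 1L)
  img$pixels <- img$pixels[, 1:13]
  for (side in c(227L, 224L)) {
    r <- resize_image(img, side)
    expect_equal(dim(r$pixels), c(side, side))
    expect_true(all(r$pixels >= 0 & r$pixels <= 255))
  }
  expect_error(resize_image(img, 4), "side")
})

test_that("resizing a square image to its own side is the identity", {
  img <- random_image(32, seed = 2L)
  r <- resize_image(img, 32)
  expect_identical(r$pixels, img$pixels)
})

test_that("PNG writer and reader round-trip pixels and metadata", {
  img <- random_image(16, seed = 3L)
  path <- withr::local_tempfile(fileext = ".png")
  write_spectrogram_png(img, path)
  back <- read_spectrogram_png(path)
  expect_identical(back$pixels, img$pixels)
  expect_identical(back$label, "synthetic")
})
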