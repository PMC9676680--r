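test_that("SPL conversion and its inverse are exact", {
  expect_equal(spl_from_pressure(2e-5), 0)
  expect_equal(spl_from_pressure(0.2), 80)
  expect_equal(spl_from_pressure(2), 100)
  expect_identical(spl_from_pressure(0), -Inf)
  expect_error(spl_from_pressure(-1), "non-negative")
  p <- 10^runif(20, -6, 2)
  expect_equal(pressure_from_spl(spl_from_pressure(p)), p, tolerance = 1e-12)
  expect_equal(pressure_from_spl(-Inf), 0)
})

test_that("A-weighting matches the standard curve", {
  expect_equal(a_weight_offset(1000), 0, tolerance = 0.01)
  expect_equal(a_weight_offset(20.2), -50.1, tolerance = 0.1)
  expect_error(a_weight_offset(0), "> 0")
  # continuous and strictly increasing across the audible band of interest
  f <- seq(20, 1000, by = 1)
  w <- a_weight_offset(f)
  expect_true(all(diff(w) > 0))
  expect_lt(max(abs(diff(w))), 1.5)   # smooth: steepest near 20 Hz (~1.3 dB/Hz)
})

test_that("relative error reproduces the printed grid-ladder arithmetic", {
  expect_equal(relative_error(1.5761e-01, 1.5800e-01), 0.2468, tolerance = 1e-3)
  expect_equal(relative_error(1.5772e-01, 1.5800e-01), 0.1772, tolerance = 1e-3)
  expect_equal(relative_error(3.3, 3.3), 0)
  expect_error(relative_error(1, 0), "non-zero")
})

test_that("band statistics follow the dB-value RMS convention", {
  # single nonzero bin: peak = rms = the bin level, at that bin's frequency
  sp1 <- pressure_spectrum(c(50, 100, 200),
                           c(0, pressure_from_spl(60) * sqrt(2), 0))
  br1 <- band_stats(sp1)
  expect_equal(br1$peak_db, 60, tolerance = 1e-9)
  expect_equal(br1$freq_at_peak_db, 100)
  expect_equal(br1$rms_db, 60, tolerance = 1e-9)
  # flat spectrum: peak = rms
  spf <- pressure_spectrum(seq(100, 500, by = 100),
                           rep(pressure_from_spl(50) * sqrt(2), 5))
  brf <- band_stats(spf)
  expect_equal(brf$peak_db, 50, tolerance = 1e-9)
  expect_equal(brf$rms_db, 50, tolerance = 1e-9)
  # two-bin mixture under the dB-value convention
  sp2 <- pressure_spectrum(c(100, 200),
                           pressure_from_spl(c(40, 60)) * sqrt(2))
  expect_equal(band_stats(sp2)$rms_db, sqrt((40^2 + 60^2) / 2), tolerance = 1e-9)
  # out-of-band bins do not leak into the report
  sp3 <- pressure_spectrum(c(10, 100, 1500),
                           pressure_from_spl(c(90, 55, 95)) * sqrt(2))
  br3 <- band_stats(sp3, band = c(20, 1000))
  expect_equal(br3$peak_db, 55, tolerance = 1e-9)
  expect_equal(br3$rms_db, 55, tolerance = 1e-9)
  expect_error(band_stats(sp3, band = c(300, 200)), "lo < hi")
})

test_that("amplitude gradients difference band RMS levels", {
  g <- amplitude_gradient(82.0, 48.6)
  expect_equal(g$db_difference, 33.4)
  expect_equal(g$percent_decrease, 40.7, tolerance = 0.05)
  same <- amplitude_gradient(64.2, 64.2)
  expect_equal(same$db_difference, 0)
  expect_equal(same$percent_decrease, 0)
  half <- amplitude_gradient(100, 50)
  expect_equal(half$db_difference, 50)
  expect_equal(half$percent_decrease, 50)
})

test_that("sonification renders cycles at the requested rate and level", {
  period <- 60 / 70
  m <- 1715
  t <- (seq_len(m) - 1) * period / m
  x <- sin(2 * pi * 200 * t) * (1 + 0.5 * cos(2 * pi * t / period))
  clip <- sonify(x, period, n_cycles = 9, sample_rate = 44100)
  expect_equal(length(clip$samples) / 44100, 9 * period,
               tolerance = 1.01 / 44100)
  expect_equal(max(abs(clip$samples)), 10^(-1 / 20), tolerance = 1e-6)
  # silence in, silence out
  z <- sonify(rep(0, 128), period, n_cycles = 2, sample_rate = 8000)
  expect_true(all(z$samples == 0))
  # a pure tone survives the round trip: the spectrogram ridge sits at 200 Hz
  tone <- sonify(sin(2 * pi * 200 * t), period, n_cycles = 6,
                 sample_rate = 8000)
  sg <- stft(tone, window_length = 0.25)
  ridge <- sg$frequencies[apply(sg$magnitude_db, 2, which.max)]
  expect_lt(max(abs(ridge - 200)), 4.1)  # within one frequency bin
  expect_error(sonify(numeric(0), period), "length >= 2")
})

test_that("audio clips survive a 16-bit WAV round trip", {
  set.seed(4)
  x <- runif(8000, -0.9, 0.9)
  clip <- audio_clip(x, 8000, "PT")
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(clip, path)
  back <- read_wav(path, label = "PT")
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$samples, clip$samples, tolerance = 1 / 32000)
})
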