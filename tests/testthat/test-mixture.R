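test_that("peak-window RMS has its closed forms and scaling", {
  rate <- 16000
  pulse <- audio_signal(c(numeric(100), rep(0.3, 160), numeric(100)), rate)
  expect_equal(peak_window_rms(pulse), 0.3, tolerance = 1e-12)
  pulse2 <- audio_signal(2 * pulse$samples, rate)
  expect_equal(peak_window_rms(pulse2), 0.6, tolerance = 1e-12)
  imp <- audio_signal(c(numeric(500), 1, numeric(500)), rate)
  expect_equal(peak_window_rms(imp), sqrt(1 / 80), tolerance = 1e-12)
  expect_error(peak_window_rms(audio_signal(rep(1, 10), rate)), "shorter")
})

test_that("STR follows its defining formula", {
  rate <- 16000
  a <- audio_signal(rep(0.01, 1600), rate)
  b <- audio_signal(rep(0.01, 1600), rate)
  expect_equal(compute_str(a, b), 0, tolerance = 1e-10)
  b2 <- audio_signal(2 * b$samples, rate)
  expect_equal(compute_str(a, b2), -20 * log10(2), tolerance = 1e-10)
  c1 <- audio_signal(rep(0.01, 1600), rate)
  c2 <- audio_signal(rep(0.0316227766, 1600), rate)
  expect_equal(compute_str(c1, c2), -10, tolerance = 1e-6)
  expect_error(compute_str(audio_signal(numeric(1600), rate), b), "silent")
})

test_that("mixing hits the requested STR and is exactly additive", {
  for (seed in 1:5) {
    sp <- synth_speech(1.5, seed = seed)
    tr <- synth_transient(transient_params(), seed = seed + 100)
    for (str in c(-5, -12.5, -20)) {
      mx <- mix_at_str(sp, tr, str, seed = seed)
      expect_equal(compute_str(mx$clean, mx$transient_placed), str,
                   tolerance = 0.01)
      expect_equal(mx$mixture$samples,
                   mx$clean$samples + mx$transient_placed$samples,
                   tolerance = 1e-14)
    }
  }
  sp <- synth_speech(1.5, seed = 1)
  tr <- synth_transient(transient_params(), seed = 101)
  m1 <- mix_at_str(sp, tr, -10, seed = 9)
  m2 <- mix_at_str(sp, tr, -10, seed = 9)
  expect_identical(m1$position, m2$position)
  long <- audio_signal(numeric(30000) + 0.1, 16000)
  expect_error(mix_at_str(sp, long, -10), "longer")
})

test_that("duration sampler matches the target moments", {
  d <- sample_duration(1000, seed = 11)
  expect_lt(abs(mean(d) - 1.98), 0.1)
  expect_lt(abs(sd(d) - 0.59), 0.1)
})

test_that("synthetic speech is reproducible and band-limited", {
  s1 <- synth_speech(1.5, seed = 12)
  s2 <- synth_speech(1.5, seed = 12)
  expect_identical(s1$samples, s2$samples)
  expect_false(identical(synth_speech(1.5, seed = 13)$samples, s1$samples))
  P <- abs(fft(s1$samples))^2
  n <- length(P); f <- (0:(n - 1)) * 16000 / n
  half <- 1:(n %/% 2)
  centroid <- sum(f[half] * P[half]) / sum(P[half])
  expect_lt(centroid, 4000)
  expect_error(synth_speech(0.3), "duration")
})

test_that("synthetic transients meet the envelope constraints", {
  for (sh in c("tonal", "noisy", "multi_peak")) {
    for (seed in 1:6) {
      tr <- synth_transient(transient_params(spectral_shape = sh), seed = seed)
      expect_lt(measured_rise_time_ms(tr), 1)
      expect_lte(duration(tr) * 1000, 500)
      s2 <- synth_transient(transient_params(spectral_shape = sh), seed = seed)
      expect_identical(tr$samples, s2$samples)
    }
  }
  tr3 <- synth_transient(transient_params(spectral_shape = "multi_peak",
                                          n_peaks = 3), seed = 4)
  expect_equal(count_envelope_peaks(tr3), 3)
  expect_error(transient_params(rise_time_ms = 1.5), "rise_time")
  expect_error(transient_params(duration_ms = 700), "duration_ms")
})

test_that("corpus manifests keep train and test disjoint and reproducible", {
  man <- build_corpus(n_train = 3, n_test = 2, seed = 5)
  tr <- man[man$split == "train", ]
  te <- man[man$split == "test", ]
  expect_length(intersect(tr$speech_seed, te$speech_seed), 0)
  expect_length(intersect(tr$transient_seed, te$transient_seed), 0)
  expect_setequal(unique(tr$str_db), c(-5, -10, -15))
  expect_setequal(unique(te$str_db), c(-5, -10, -15, -20))
  m1 <- realize_mixture(man[1, ])
  m2 <- realize_mixture(man[1, ])
  expect_identical(m1$mixture$samples, m2$mixture$samples)
  man_b <- build_corpus(n_train = 3, n_test = 2, seed = 5)
  expect_identical(man, man_b)
})

test_that("corpus WAV export round trips through the manifest", {
  man <- build_corpus(n_train = 1, n_test = 1, train_strs = -10,
                      test_strs = -15, seed = 6)
  dir <- tempfile("corpus")
  out <- write_corpus(man, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  w <- read_wav(out$path[1])
  mx <- realize_mixture(man[1, ])
  expect_lt(max(abs(w$samples - mx$mixture$samples)), 1e-6)
  unlink(dir, recursive = TRUE)
})
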