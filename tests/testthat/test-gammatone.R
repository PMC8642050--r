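test_that("bank geometry follows the ERB_N-number scale", {
  bank <- build_bank()
  expect_equal(bank$n_channels, 64)
  expect_equal(bank$center_freqs[1], 50, tolerance = 1e-6)
  expect_equal(bank$center_freqs[64], 8000, tolerance = 1e-6)
  expect_true(all(diff(bank$center_freqs) > 0))
  # centers equally spaced in Cams
  steps <- diff(erb_number(bank$center_freqs))
  expect_lt(diff(range(steps)), 1e-9)
  expect_equal(erb_number(1000), 21.4 * log10(4.37 + 1), tolerance = 1e-12)
  expect_equal(build_bank(n_channels = 1)$center_freqs, 50)
  expect_error(build_bank(f_hi = 9000, rate = 16000), "Nyquist")
  # each channel's weights peak at the FFT bin nearest its center
  peak_bins <- apply(bank$bin_weights, 1, which.max)
  nearest <- vapply(bank$center_freqs,
                    function(fc) which.min(abs(bank$bin_freqs - fc)), 0L)
  expect_equal(peak_bins, nearest)
})

test_that("feature extraction is energy-like and tone-selective", {
  bank <- build_bank()
  z <- extract_features(audio_signal(numeric(8000), 16000), bank)
  expect_true(all(z$values == 0))

  x <- tone(1000, dur_s = 0.5)
  f1 <- extract_features(x, bank)
  f2 <- extract_features(audio_signal(3 * x$samples, 16000), bank)
  expect_equal(f2$values, 9 * f1$values, tolerance = 1e-10)

  best <- bank$center_freqs[which.max(colMeans(f1$values))]
  expect_lt(abs(erb_number(best) - erb_number(1000)), 1)

  expect_error(extract_features(audio_signal(0.1 + numeric(100), 22050), bank),
               "rate")
})

test_that("spectral weighting agrees with time-domain gammatone filtering", {
  # independent oracle: literal 4th-order gammatone impulse-response
  # filtering, frame the filtered signal, sum squared windowed samples.
  # Agreement is expected where the channel bandwidth clearly exceeds the
  # 5-ms window's spectral mainlobe (~200 Hz), i.e. centers of several kHz;
  # below that the finite window widens the effective filter.
  bank <- build_bank()
  spec <- default_rnn_frame_spec(16000)
  w <- frame_window(spec)
  for (ch in c(56, 60, 63)) {
    fc <- bank$center_freqs[ch]
    x <- tone(fc, dur_s = 0.3)
    # oracle channel signal
    b <- 1.019 * erb_bandwidth(fc)
    th <- (0:1599) / 16000
    h <- th^3 * exp(-2 * pi * b * th) * cos(2 * pi * fc * th)
    H_fc <- abs(sum(h * exp(-2i * pi * fc * th)))   # peak gain to normalize
    h <- h / H_fc
    y <- stats::convolve(x$samples, rev(h), type = "open")[seq_along(x$samples)]
    # discard the filter transient, compare interior frames
    yf <- frame_signal(y, spec)
    oracle <- rowSums(yf^2)
    feats <- extract_features(x, bank, spec)$values[, ch]
    idx <- 40:80
    expect_lt(max(abs(feats[idx] - oracle[idx]) / oracle[idx]), 0.15)
  }
})

test_that("ideal ratio mask has its closed-form values and monotonicity", {
  S2 <- matrix(c(1, 1, 1, 0), 2)
  V2 <- matrix(c(1, 4, 0, 0), 2)
  m <- compute_irm(S2, V2)
  expect_equal(m$values[1, 1], 0.5)
  expect_equal(m$values[2, 1], 0.2)
  expect_equal(m$values[1, 2], 1)     # V = 0 -> all speech
  expect_equal(m$values[2, 2], 1)     # silence convention
  expect_error(compute_irm(S2, matrix(0, 3, 3)), "shapes")

  set.seed(8)
  S2 <- matrix(runif(200), 20)
  V2a <- matrix(runif(200), 20)
  V2b <- V2a + matrix(runif(200), 20)          # more transient energy
  ma <- compute_irm(S2, V2a)$values
  mb <- compute_irm(S2, V2b)$values
  expect_true(all(mb <= ma + 1e-12))
  expect_true(all(ma >= 0 & ma <= 1))
})

test_that("mask application is transparent at ones, silent at zeros", {
  bank <- build_bank()
  x <- white_noise(0.5, seed = 9)
  feats <- extract_features(x, bank)
  n_fr <- nrow(feats$values)
  y1 <- apply_mask(x, tf_mask(matrix(1, n_fr, 64)), bank)
  expect_lt(rel_err_db(x$samples, y1$samples, 200:7800), -40)
  y0 <- apply_mask(x, tf_mask(matrix(0, n_fr, 64)), bank)
  expect_lt(lin2db(audio_rms(y0) / audio_rms(x)), -60)
  expect_error(apply_mask(x, tf_mask(matrix(1, 5, 64)), bank), "frame count")
  # energy non-expansion for arbitrary masks <= 1
  set.seed(10)
  m <- tf_mask(matrix(runif(n_fr * 64), n_fr))
  ym <- apply_mask(x, m, bank)
  expect_lte(sum(ym$samples^2), sum(x$samples^2) * (1 + 1e-6))
})

test_that("true-IRM masking improves STOI on a corrupted mixture", {
  sp <- synth_speech(1.5, seed = 21)
  tr <- synth_transient(transient_params(spectral_shape = "noisy"), seed = 22)
  mx <- mix_at_str(sp, tr, -15, seed = 23)
  bank <- build_bank()
  irm <- compute_irm(extract_features(mx$clean, bank),
                     extract_features(mx$transient_placed, bank))
  cleaned <- apply_mask(mx$mixture, irm, bank)
  expect_gt(stoi(mx$clean, cleaned)$value,
            stoi(mx$clean, mx$mixture)$value)
})
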