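test_that("resampling preserves duration, identity rate, and tone frequency", {
  x <- tone(1000, dur_s = 1, rate = 16000)
  y <- resample_audio(x, 22050)
  expect_equal(length(y), 22050)
  expect_equal(y$rate, 22050)
  expect_identical(resample_audio(x, 16000), x)
  expect_lt(abs(dominant_freq(y) - 1000), 1)
  expect_error(resample_audio(x, -1), "positive")
})

test_that("resample round trip is near-transparent for band-limited input", {
  x <- tone(700, dur_s = 1)
  z <- resample_audio(resample_audio(x, 22050), 16000)
  i <- 500:15500
  expect_gt(cor(z$samples[i], x$samples[i]), 0.999)
  expect_lt(rel_err_db(x$samples, z$samples, i), -40)
})

test_that("framing obeys the frame-count formula and window choices", {
  spec <- frame_spec(80, 40, "hann")
  expect_equal(nrow(frame_signal(white_noise(1), spec)), 399)
  one <- frame_signal(audio_signal(rep(0.5, 80), 16000), spec)
  expect_equal(nrow(one), 1)
  rect <- frame_spec(8, 4, "rect")
  fr <- frame_signal(audio_signal(rep(1, 24), 16000), rect)
  expect_true(all(fr == 1))
  expect_error(frame_signal(audio_signal(rep(0, 10), 16000), spec), "shorter")
  expect_error(frame_spec(80, 0), "hop")
  expect_error(frame_spec(80, 81), "hop")
})

test_that("overlap-add round trip is transparent for both analysis grids", {
  x <- white_noise(1, seed = 3)
  spec <- frame_spec(80, 40, "hann")
  y <- overlap_add(frame_signal(x, spec), spec, 16000, length_hint = 16000)
  expect_lt(rel_err_db(x$samples, y$samples, 200:15800), -40)

  # MCTR grid: 22-sample Tukey frames, hop 10
  mspec <- frame_spec(22, 10, "tukey", 0.5)
  xi <- white_noise(1, rate = 22050, seed = 4)
  yi <- overlap_add(frame_signal(xi, mspec), mspec, 22050,
                    length_hint = length(xi))
  expect_lt(rel_err_db(xi$samples, yi$samples, 200:21800), -40)

  z <- overlap_add(frame_signal(audio_signal(numeric(800) + 0, 16000), spec),
                   spec, 16000)
  expect_true(all(z$samples == 0))

  s <- tone(500, dur_s = 0.5)
  sr <- overlap_add(frame_signal(s, spec), spec, 16000, length_hint = length(s))
  i <- 200:7800
  expect_gt(cor(sr$samples[i], s$samples[i]), 0.999)

  expect_error(overlap_add(matrix(0, 3, 10), spec, 16000), "length")
})

test_that("rms has its closed forms and homogeneity", {
  expect_equal(audio_rms(tone(440, 1)), 1 / sqrt(2), tolerance = 1e-4)
  expect_equal(audio_rms(rep(0, 100)), 0)
  x <- white_noise(0.1)
  expect_equal(audio_rms(audio_signal(2 * x$samples, 16000)),
               2 * audio_rms(x))
  expect_error(audio_rms(numeric(0)), "empty")
})

test_that("set_level follows the declared SPL convention", {
  x <- white_noise(0.2, seed = 5)
  y <- set_level(x, 60)
  expect_equal(audio_rms(y), 0.01, tolerance = 1e-12)  # 0 dBFS RMS = 100 dB SPL
  expect_equal(set_level(y, 60)$samples, y$samples, tolerance = 1e-12)
  y2 <- set_level(x, 66.02)
  expect_equal(audio_rms(y2) / audio_rms(y), 2, tolerance = 1e-3)
  expect_error(set_level(audio_signal(rep(0, 10), 16000), 60), "zero-RMS")
})

test_that("gain filtering matches the table and delays linearly", {
  x <- white_noise(0.5, seed = 6)
  flat <- gain_table(c(100, 8000), c(0, 0))
  y <- apply_gain_filter(x, flat, 513)
  d <- 256                                     # (513 - 1) / 2
  i <- 1000:6000
  expect_lt(rel_err_db(x$samples[i], y$samples[i + d]), -40)

  up <- gain_table(c(100, 8000), c(6.02, 6.02))
  y2 <- apply_gain_filter(x, up, 513)
  expect_equal(audio_rms(y2$samples[i + d]) / audio_rms(x$samples[i]), 2,
               tolerance = 0.02)

  tilt <- gain_table(c(1000, 4000), c(0, 20))
  probe <- tone(4000, dur_s = 0.5)
  yp <- apply_gain_filter(probe, tilt, 513)
  g <- lin2db(audio_rms(yp$samples[4000:7500]) /
                audio_rms(probe$samples[4000:7500]))
  expect_lt(abs(g - 20), 1)

  expect_error(apply_gain_filter(x, flat, 512), "odd")
  expect_error(gain_table(c(200, 100), c(0, 0)), "increasing")
})

test_that("algorithmic latency is frame plus overlap duration", {
  expect_equal(algorithmic_latency(frame_spec(80, 40, "hann"), 16000), 7.5)
  expect_equal(algorithmic_latency(frame_spec(80, 80, "rect"), 16000), 5)
  expect_equal(algorithmic_latency(frame_spec(320, 160, "hann"), 16000), 30)
})

test_that("WAV I/O round trips both sample formats", {
  x <- audio_signal(round(sin(2 * pi * 440 * (0:799) / 16000) * 0.4, 4), 16000)
  p16 <- tempfile(fileext = ".wav")
  write_wav(x, p16, bits = 16L)
  r16 <- read_wav(p16)
  expect_equal(r16$rate, 16000)
  expect_lt(max(abs(r16$samples - x$samples)), 1 / 32768)
  p32 <- tempfile(fileext = ".wav")
  write_wav(x, p32, bits = 32L)
  r32 <- read_wav(p32)
  expect_lt(max(abs(r32$samples - x$samples)), 1e-6)
  unlink(c(p16, p32))
})
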