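#' RMS in a 5-ms window centered on the peak
#'
#' The transient level used in the speech-to-transient ratio: the RMS of a
#' 5-ms rectangular window centered on the sample of maximum absolute
#' amplitude, clipped at the signal edges.
#'
#' @param x an [audio_signal()] at least 5 ms long.
#' @param window_ms window length in ms (default 5).
#' @return linear RMS amplitude.
#' @export
peak_window_rms <- function(x, window_ms = 5) {
  stopifnot(inherits(x, "audio_signal"))
  n <- length(x$samples)
  w <- round(x$rate * window_ms / 1000)
  if (n < w) stop("peak_window_rms: signal shorter than the window")
  peaks <- which(abs(x$samples) == max(abs(x$samples)))
  p <- peaks[ceiling(length(peaks) / 2)]   # plateau ties: central sample
  lo <- max(1L, p - w %/% 2L)
  hi <- min(n, lo + w - 1L)
  lo <- max(1L, hi - w + 1L)
  audio_rms(x$samples[lo:hi])
}

#' Speech-to-transient ratio (STR) in dB
#'
#' `20 log10( rms(clean) / peak_window_rms(transient) )`: the RMS level of
#' the clean speech relative to the level of the transient measured in a 5-ms
#' rectangular window around its peak. Lower (more negative) STR means a more
#' intense transient.
#'
#' @param clean clean-speech [audio_signal()].
#' @param transient transient [audio_signal()] (same rate).
#' @return STR in dB.
#' @export
compute_str <- function(clean, transient) {
  rc <- audio_rms(clean)
  rt <- peak_window_rms(transient)
  if (rc <= 0 || rt <= 0) stop("compute_str: silent input")
  lin2db(rc / rt)
}

#' Mix a transient into clean speech at a target STR
#'
#' Rescales the transient so that the measured STR equals `str_db`, then adds
#' it at `position` (a sample index, or `"random"` for a seeded uniform draw
#' over positions that keep the transient wholly inside the sentence). One
#' transient per sentence. The returned components satisfy
#' `mixture = clean + transient_placed` exactly, so the placed transient can
#' be used directly for ideal-ratio-mask computation.
#'
#' @param clean clean-speech [audio_signal()].
#' @param transient transient [audio_signal()] shorter than `clean`, same
#'   rate.
#' @param str_db target STR in dB.
#' @param position sample index of the transient onset, or `"random"`.
#' @param seed integer seed for the random position.
#' @return list with `mixture`, `clean`, `transient_placed` (full-length
#'   [audio_signal()]s), `position`, `scale`, and `str_db`.
#' @export
mix_at_str <- function(clean, transient, str_db, position = "random",
                       seed = 1L) {
  stopifnot(inherits(clean, "audio_signal"), inherits(transient, "audio_signal"))
  if (clean$rate != transient$rate) stop("mix_at_str: rate mismatch")
  if (!is.finite(str_db)) stop("mix_at_str: str_db must be finite")
  n <- length(clean$samples)
  m <- length(transient$samples)
  if (m >= n) stop("mix_at_str: transient longer than the sentence")
  if (identical(position, "random")) {
    position <- with_seed(seed, sample.int(n - m + 1L, 1L))
  }
  position <- as.integer(position)
  if (position < 1L || position + m - 1L > n)
    stop("mix_at_str: position places the transient outside the sentence")
  placed <- numeric(n)
  placed[position + seq_len(m) - 1L] <- transient$samples
  # scale against the peak-window RMS of the *placed* transient so that
  # compute_str() on the returned components recovers str_db exactly
  scale <- audio_rms(clean) /
    peak_window_rms(audio_signal(placed, clean$rate)) * db2lin(-str_db)
  placed <- placed * scale
  list(mixture = audio_signal(clean$samples + placed, clean$rate),
       clean = clean,
       transient_placed = audio_signal(placed, clean$rate),
       position = position, scale = scale, str_db = str_db)
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Sample a sentence duration
#'
#' Durations are drawn from a normal distribution with mean 1.98 s and SD
#' 0.59 s (the summary statistics of the evaluation sentences emulated by the
#' synthetic generator), truncated below at `min_s`.
#'
#' @param n number of draws.
#' @param seed integer seed.
#' @param mean_s,sd_s,min_s distribution parameters in seconds.
#' @return numeric vector of durations in seconds.
#' @export
sample_duration <- function(n = 1L, seed = 1L, mean_s = 1.98, sd_s = 0.59,
                            min_s = 0.6) {
  with_seed(seed, {
    d <- stats::rnorm(n, mean_s, sd_s)
    while (any(d < min_s)) d[d < min_s] <- stats::rnorm(sum(d < min_s),
                                                        mean_s, sd_s)
    d
  })
}

#' Generate a synthetic speech-like signal
#'
#' A voiced harmonic complex with a drifting fundamental (80-300 Hz), two to
#' three slowly moving formant-like resonances below 3.2 kHz, syllabic (3-5
#' Hz) amplitude modulation, and short silent gaps. This emulates the gross
#' spectro-temporal structure of read sentences (harmonicity, formant peaks,
#' syllable rhythm) -- it is not intelligible speech. Bit-identical output for
#' a given `(duration_s, seed)`.
#'
#' @param duration_s duration in seconds (> 0.5).
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return an [audio_signal()], peak-normalized to 0.5 full scale.
#' @export
synth_speech <- function(duration_s, rate = 16000, seed = 1L) {
  if (duration_s <= 0.5) stop("synth_speech: duration must exceed 0.5 s")
  n <- round(duration_s * rate)
  t <- (seq_len(n) - 1L) / rate
  with_seed(seed, {
    f0_base <- stats::runif(1, 100, 220)
    # slow f0 drift: sum of two low-frequency sinusoids, clipped to 80-300 Hz
    drift <- f0_base * (1 + 0.15 * sin(2 * pi * stats::runif(1, 0.3, 1) * t +
                                         stats::runif(1, 0, 2 * pi)) +
                            0.08 * sin(2 * pi * stats::runif(1, 1, 2.5) * t +
                                         stats::runif(1, 0, 2 * pi)))
    f0 <- pmin(pmax(drift, 80), 300)
    phase <- 2 * pi * cumsum(f0) / rate
    n_formants <- sample(2:3, 1)
    fmt_c <- sort(stats::runif(n_formants, 300, 3000))
    fmt_bw <- stats::runif(n_formants, 80, 250)
    fmt_mod <- stats::runif(n_formants, 0.1, 0.4)     # Hz, slow movement
    fmt_ph <- stats::runif(n_formants, 0, 2 * pi)
    n_harm <- floor(3600 / min(80, min(f0)))
    n_harm <- min(n_harm, 40L)
    sig <- numeric(n)
    for (h in seq_len(n_harm)) {
      fh <- h * f0
      keep <- fh < 3800
      if (!any(keep)) break
      amp <- 1 / h                                 # glottal-like rolloff
      res <- numeric(n)
      for (k in seq_len(n_formants)) {
        fc_t <- fmt_c[k] * (1 + 0.08 * sin(2 * pi * fmt_mod[k] * t + fmt_ph[k]))
        res <- res + 1 / (1 + ((fh - fc_t) / fmt_bw[k])^2)
      }
      sig <- sig + amp * (0.15 + res) * sin(h * phase) * keep
    }
    # syllabic modulation + silent gaps
    syl_rate <- stats::runif(1, 3, 5)
    env <- 0.55 + 0.45 * sin(2 * pi * syl_rate * t + stats::runif(1, 0, 2 * pi))
    n_gaps <- max(1L, round(duration_s))
    gap_at <- stats::runif(n_gaps, 0.1, max(duration_s - 0.2, 0.2))
    gap_len <- stats::runif(n_gaps, 0.05, 0.15)
    for (g in seq_len(n_gaps)) {
      env <- env * (1 - 0.98 * exp(-((t - gap_at[g]) / (gap_len[g] / 2))^2))
    }
    sig <- sig * env
    audio_signal(0.5 * sig / max(abs(sig)), rate)
  })
}

#' Transient generator parameters
#'
#' @param rise_time_ms 10-90% rise time in ms (< 1).
#' @param decay_time_ms exponential decay time constant in ms (tens of ms).
#' @param duration_ms total duration in ms (<= 500).
#' @param spectral_shape `"tonal"` (decaying resonances, e.g. glass or bell),
#'   `"noisy"` (broadband burst, e.g. a door slam), or `"multi_peak"`
#'   (several strikes, e.g. a bag of bottles breaking).
#' @param n_peaks number of envelope peaks for `"multi_peak"`.
#' @return an object of class `transient_params`.
#' @export
transient_params <- function(rise_time_ms = 0.5, decay_time_ms = 30,
                             duration_ms = 150,
                             spectral_shape = c("tonal", "noisy", "multi_peak"),
                             n_peaks = 3L) {
  spectral_shape <- match.arg(spectral_shape)
  if (rise_time_ms >= 1) stop("transient_params: rise_time_ms must be < 1 ms")
  if (rise_time_ms <= 0) stop("transient_params: rise_time_ms must be > 0")
  if (duration_ms > 500) stop("transient_params: duration_ms must be <= 500")
  if (duration_ms <= 0) stop("transient_params: duration_ms must be > 0")
  if (decay_time_ms <= 0) stop("transient_params: decay_time_ms must be > 0")
  if (n_peaks < 1L) stop("transient_params: n_peaks must be >= 1")
  structure(list(rise_time_ms = rise_time_ms, decay_time_ms = decay_time_ms,
                 duration_ms = duration_ms, spectral_shape = spectral_shape,
                 n_peaks = as.integer(n_peaks)),
            class = "transient_params")
}

#' Generate a synthetic transient sound
#'
#' Builds an impact-like waveform: a sharp attack (10-90% rise time below
#' 1 ms), exponential decay over tens of ms, total duration below a few
#' hundred ms. The carrier is a sum of decaying resonances (`"tonal"`),
#' filtered noise (`"noisy"`), or a few delayed strikes (`"multi_peak"`).
#'
#' @param params a [transient_params()].
#' @param rate sampling rate in Hz.
#' @param seed integer seed.
#' @return an [audio_signal()], peak-normalized to 0.9 full scale.
#' @export
synth_transient <- function(params = transient_params(), rate = 16000,
                            seed = 1L) {
  stopifnot(inherits(params, "transient_params"))
  n <- round(params$duration_ms / 1000 * rate)
  t <- (seq_len(n) - 1L) / rate
  with_seed(seed, {
    # constant-modulus FM carrier: flat amplitude envelope by construction,
    # so the waveform's measured envelope tracks the designed attack/decay
    flat_carrier <- function() {
      f_inst <- switch(params$spectral_shape,
        tonal = {                     # ringing resonance with slight vibrato
          f0 <- stats::runif(1, 400, 4000)
          f0 * (1 + 0.02 * sin(2 * pi * 5 * t + stats::runif(1, 0, 2 * pi)))
        },
        {                             # broadband: random-walk frequency
          w <- cumsum(stats::rnorm(n))
          w <- as.numeric(stats::filter(w, rep(1 / 8, 8), sides = 2))
          w[is.na(w)] <- 0
          500 + 5500 / (1 + exp(-w / 20))
        })
      cos(2 * pi * cumsum(f_inst) / rate + stats::runif(1, 0, 2 * pi))
    }
    strike_env <- function(t0, decay_s) {
      tl <- t - t0
      rise <- params$rise_time_ms / 1000 / 0.8      # 10-90% -> full ramp
      ifelse(tl < 0, 0,
             ifelse(tl < rise, tl / rise, exp(-(tl - rise) / decay_s)))
    }
    if (params$spectral_shape == "multi_peak" && params$n_peaks > 1L) {
      gap <- params$duration_ms / 1000 * 0.55 / (params$n_peaks - 1L)
      offsets <- (seq_len(params$n_peaks) - 1L) * gap +
        c(0, stats::runif(params$n_peaks - 1L, -0.1, 0.1) * gap)
      decay_s <- min(params$decay_time_ms / 1000, 0.3 * gap)
      amps <- c(1, stats::runif(params$n_peaks - 1L, 0.55, 0.75))
      env <- numeric(n)
      for (k in seq_along(offsets))
        env <- env + amps[k] * strike_env(offsets[k], decay_s)
    } else {
      env <- strike_env(0, params$decay_time_ms / 1000)
    }
    sig <- env * flat_carrier()
    audio_signal(0.9 * sig / max(abs(sig)), rate)
  })
}

#' Build a synthetic train/test corpus manifest
#'
#' Records the recipe for a set of speech-plus-transient mixtures: `n_train`
#' training sentences each mixed at every training STR, and `n_test` test
#' sentences each mixed at every test STR. Train and test use disjoint
#' speech seeds and disjoint transient generators (different seed ranges and
#' parameter draws), emulating unseen talkers and unseen transients. The
#' manifest alone reproduces every waveform bit-for-bit via
#' [realize_mixture()].
#'
#' @param n_train,n_test sentence counts (> 0).
#' @param train_strs,test_strs STR sets in dB.
#' @param seed integer master seed.
#' @param rate sampling rate in Hz.
#' @return a data.frame manifest, one row per mixture, with columns `split`,
#'   `sentence_id`, `speech_seed`, `duration_s`, `transient_seed`,
#'   `transient_shape`, `decay_ms`, `duration_ms`, `n_peaks`, `str_db`,
#'   `mix_seed`, `rate`.
#' @export
build_corpus <- function(n_train, n_test, train_strs = c(-5, -10, -15),
                         test_strs = c(-5, -10, -15, -20), seed = 1L,
                         rate = 16000) {
  if (n_train < 1L || n_test < 1L) stop("build_corpus: counts must be > 0")
  seed <- as.integer(seed)
  shapes <- c("tonal", "noisy", "multi_peak")
  make_rows <- function(split, n, strs, seed_base) {
    dur <- sample_duration(n, seed = seed_base + 7L)
    par_draw <- with_seed(seed_base + 11L, data.frame(
      transient_shape = sample(shapes, n, replace = TRUE),
      decay_ms = stats::runif(n, 15, 60),
      duration_ms = stats::runif(n, 80, 300),
      n_peaks = sample(2:4, n, replace = TRUE)))
    grid <- expand.grid(sentence_id = seq_len(n), str_db = strs)
    data.frame(split = split,
               sentence_id = grid$sentence_id,
               speech_seed = seed_base + 100L + grid$sentence_id,
               duration_s = dur[grid$sentence_id],
               transient_seed = seed_base + 5000L + grid$sentence_id,
               transient_shape = par_draw$transient_shape[grid$sentence_id],
               decay_ms = par_draw$decay_ms[grid$sentence_id],
               duration_ms = par_draw$duration_ms[grid$sentence_id],
               n_peaks = par_draw$n_peaks[grid$sentence_id],
               str_db = grid$str_db,
               mix_seed = seed_base + 9000L + grid$sentence_id +
                 1000L * match(grid$str_db, strs),
               rate = rate,
               stringsAsFactors = FALSE)
  }
  rbind(make_rows("train", n_train, train_strs, seed * 2L + 1L),
        make_rows("test", n_test, test_strs, seed * 2L + 600000L))
}

#' Realize one manifest row as waveforms
#'
#' @param row one row of a [build_corpus()] manifest.
#' @return the [mix_at_str()] result for that record.
#' @export
realize_mixture <- function(row) {
  sp <- synth_speech(row$duration_s, rate = row$rate, seed = row$speech_seed)
  tp <- transient_params(rise_time_ms = 0.5, decay_time_ms = row$decay_ms,
                         duration_ms = row$duration_ms,
                         spectral_shape = row$transient_shape,
                         n_peaks = row$n_peaks)
  tr <- synth_transient(tp, rate = row$rate, seed = row$transient_seed)
  mix_at_str(sp, tr, row$str_db, position = "random", seed = row$mix_seed)
}

#' Write a corpus manifest and its WAV files to a directory
#'
#' @param manifest a [build_corpus()] manifest.
#' @param dir output directory (created if needed).
#' @param bits WAV sample format; 32-bit float by default since mixtures at
#'   strongly negative STRs can exceed the 16-bit full scale.
#' @return the manifest with added `path` column, invisibly; also writes
#'   `manifest.json` (JSON lines, one record per mixture).
#' @export
write_corpus <- function(manifest, dir, bits = 32L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mx <- realize_mixture(manifest[i, ])
    paths[i] <- file.path(dir, sprintf("%s_s%03d_str%+03d.wav",
                                       manifest$split[i],
                                       manifest$sentence_id[i],
                                       as.integer(manifest$str_db[i])))
    write_wav(mx$mixture, paths[i], bits = bits)
  }
  manifest$path <- paths
  con <- file(file.path(dir, "manifest.json"), "w")
  for (i in seq_len(nrow(manifest)))
    writeLines(jsonlite::toJSON(as.list(manifest[i, ]), auto_unbox = TRUE), con)
  close(con)
  invisible(manifest)
}
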