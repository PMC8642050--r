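# Intrusive objective intelligibility metrics: STOI and NCM. Both compare
# band envelopes of the clean reference and the degraded/processed signal and
# return a value in [0, 1].

#' Short-time objective intelligibility (STOI)
#'
#' Implements the standard STOI recipe: both signals are resampled to 10 kHz;
#' frames in which the clean speech is more than 40 dB below its most intense
#' frame are removed; a short-time DFT (256-sample Hann frames, 50% overlap,
#' 512-point FFT) is grouped into 15 one-third-octave bands from 150 Hz;
#' within 384-ms (30-frame) segments the degraded band envelope is normalized
#' to the clean energy and clipped at -15 dB SDR; the measure is the mean
#' linear correlation of clean and clipped-degraded envelopes over all bands
#' and segments.
#'
#' @param clean,degraded [audio_signal()]s of equal length and rate; `clean`
#'   must be non-silent.
#' @return STOI value in `[0, 1]` (identical signals give 1).
#' @export
stoi <- function(clean, degraded) {
  check_metric_inputs(clean, degraded)
  fs <- 10000
  x <- resample_audio(clean, fs)$samples
  y <- resample_audio(degraded, fs)$samples
  n <- min(length(x), length(y))
  x <- x[seq_len(n)]; y <- y[seq_len(n)]
  frame_len <- 256L; hop <- 128L; nfft <- 512L
  if (n < frame_len + hop) stop("stoi: signal too short for analysis")
  spec <- frame_spec(frame_len, hop, "hann")
  xf <- frame_signal(x, spec)
  yf <- frame_signal(y, spec)
  # energy-based voice activity: keep frames within 40 dB of the loudest
  fe <- 20 * log10(sqrt(rowSums(xf^2)) + 1e-300)
  keep <- fe > (max(fe) - 40)
  if (sum(keep) < 30L)
    stop("stoi: fewer than 30 active frames in the clean reference")
  xf <- xf[keep, , drop = FALSE]
  yf <- yf[keep, , drop = FALSE]
  X <- Mod(frames_to_spectra(xf, nfft)[, 1:(nfft / 2 + 1), drop = FALSE])^2
  Y <- Mod(frames_to_spectra(yf, nfft)[, 1:(nfft / 2 + 1), drop = FALSE])^2
  # 15 one-third-octave bands, lowest center 150 Hz
  cf <- 150 * 2^((0:14) / 3)
  f_bin <- (0:(nfft / 2)) * fs / nfft
  Xb <- matrix(0, nrow(X), 15L); Yb <- matrix(0, nrow(Y), 15L)
  for (j in 1:15) {
    sel <- f_bin >= cf[j] * 2^(-1 / 6) & f_bin < cf[j] * 2^(1 / 6)
    Xb[, j] <- sqrt(rowSums(X[, sel, drop = FALSE]))
    Yb[, j] <- sqrt(rowSums(Y[, sel, drop = FALSE]))
  }
  N <- 30L
  beta_clip <- 10^(-15 / 20)
  n_frames <- nrow(Xb)
  d_sum <- 0; d_n <- 0L
  for (m in N:n_frames) {
    xi <- Xb[(m - N + 1L):m, , drop = FALSE]
    yi <- Yb[(m - N + 1L):m, , drop = FALSE]
    for (j in 1:15) {
      xs <- xi[, j]; ys <- yi[, j]
      nx <- sqrt(sum(xs^2)); ny <- sqrt(sum(ys^2))
      al <- if (ny > 0) nx / ny else 0
      yc <- pmin(al * ys, xs * (1 + beta_clip))
      xs_c <- xs - mean(xs); yc_c <- yc - mean(yc)
      den <- sqrt(sum(xs_c^2) * sum(yc_c^2))
      if (den > 0) {
        d_sum <- d_sum + sum(xs_c * yc_c) / den
        d_n <- d_n + 1L
      }
    }
  }
  val <- if (d_n > 0) d_sum / d_n else 0
  metric_result("stoi", min(max(val, 0), 1))
}

#' Normalized covariance metric (NCM)
#'
#' Filters both signals into 20 gammatone-spaced bands (150 Hz to just below
#' the Nyquist frequency), extracts Hilbert envelopes, downsamples them to
#' 25 Hz, computes the normalized covariance `r_i` of the clean and degraded
#' envelopes per band, converts it to an apparent SNR
#' `10 log10(r^2 / (1 - r^2))` clipped to \[-15, 15\] dB, maps that to a
#' transmission index `(SNR + 15) / 30`, and averages over bands (uniform
#' band-importance weights by default).
#'
#' @param clean,degraded [audio_signal()]s of equal length and rate.
#' @param n_bands number of gammatone bands.
#' @param weights optional band-importance weights (length `n_bands`).
#' @return NCM value in `[0, 1]` (identical signals give 1).
#' @export
ncm <- function(clean, degraded, n_bands = 20L, weights = NULL) {
  check_metric_inputs(clean, degraded)
  fs <- clean$rate
  x <- clean$samples; y <- degraded$samples
  n <- length(x)
  f_lo <- 150; f_hi <- min(8000, 0.45 * fs)
  cf <- erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi),
                           length.out = n_bands))
  b <- 1.019 * erb_bandwidth(cf)
  f_grid <- (0:(n - 1)) * fs / n
  f_fold <- pmin(f_grid, fs - f_grid)            # frequency of each FFT bin
  X <- stats::fft(x); Y <- stats::fft(y)
  # analytic-signal weights: double positive frequencies, zero negative
  an <- numeric(n); an[1] <- 1
  if (n %% 2L == 0L) { an[2:(n / 2)] <- 2; an[n / 2 + 1] <- 1
  } else an[2:((n + 1) / 2)] <- 2
  env_rate <- 25
  block <- max(1L, floor(fs / env_rate))
  n_blocks <- n %/% block
  if (n_blocks < 4L) stop("ncm: signal too short for envelope analysis")
  ti <- numeric(n_bands)
  for (i in seq_len(n_bands)) {
    H <- (1 + ((f_fold - cf[i]) / b[i])^2)^(-2)  # 4th-order magnitude
    ex <- Mod(stats::fft(X * H * an, inverse = TRUE)) / n
    ey <- Mod(stats::fft(Y * H * an, inverse = TRUE)) / n
    exd <- colMeans(matrix(ex[seq_len(n_blocks * block)], block))
    eyd <- colMeans(matrix(ey[seq_len(n_blocks * block)], block))
    exc <- exd - mean(exd); eyc <- eyd - mean(eyd)
    den <- sqrt(sum(exc^2) * sum(eyc^2))
    r2 <- if (den > 0) (sum(exc * eyc) / den)^2 else 0
    snr <- 10 * log10(r2 / max(1 - r2, 1e-12))
    ti[i] <- (min(max(snr, -15), 15) + 15) / 30
  }
  if (is.null(weights)) weights <- rep(1, n_bands)
  metric_result("ncm", sum(weights * ti) / sum(weights))
}

check_metric_inputs <- function(clean, degraded) {
  stopifnot(inherits(clean, "audio_signal"), inherits(degraded, "audio_signal"))
  if (clean$rate != degraded$rate)
    stop("metric: clean and degraded rates differ")
  if (length(clean$samples) != length(degraded$samples))
    stop("metric: clean and degraded lengths differ")
  if (audio_rms(clean) <= 0) stop("metric: clean reference is silent")
}

metric_result <- function(name, value) {
  structure(list(name = name, value = value), class = "metric_result")
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<%s = %.4f>\n", x$name, x$value)); invisible(x)
}

#' Evaluate processing conditions over a corpus
#'
#' Runs each processor on each mixture of the manifest and scores it against
#' the clean reference with each metric. The `NP` (no-processing) condition
#' is the untouched mixture.
#'
#' @param manifest a [build_corpus()] manifest (typically its test split).
#' @param processors named list of functions; each receives the
#'   [realize_mixture()] result and returns a processed [audio_signal()].
#' @param metrics named list of metric functions `f(clean, degraded)`
#'   returning a `metric_result` (default STOI and NCM).
#' @return list with `results` (one row per mixture x condition x metric)
#'   and `means` (mean value per condition x STR x metric).
#' @export
evaluate_conditions <- function(manifest,
                                processors,
                                metrics = list(stoi = stoi, ncm = ncm)) {
  rows <- list()
  for (i in seq_len(nrow(manifest))) {
    mx <- realize_mixture(manifest[i, ])
    for (cond in names(processors)) {
      out <- processors[[cond]](mx)
      nmin <- min(length(out$samples), length(mx$clean$samples))
      cl <- audio_signal(mx$clean$samples[seq_len(nmin)], mx$clean$rate)
      pr <- audio_signal(out$samples[seq_len(nmin)], out$rate)
      for (mname in names(metrics)) {
        val <- metrics[[mname]](cl, pr)$value
        rows[[length(rows) + 1L]] <- data.frame(
          sentence_id = manifest$sentence_id[i],
          str_db = manifest$str_db[i], condition = cond, metric = mname,
          value = val, stringsAsFactors = FALSE)
      }
    }
  }
  results <- do.call(rbind, rows)
  means <- stats::aggregate(value ~ condition + str_db + metric, results,
                            mean)
  list(results = results, means = means)
}

#' Standard processing conditions
#'
#' Builds the processor set used in the objective evaluation: `NP` (the
#' untouched mixture), `trueIRM` (mask computed from the known clean and
#' transient components), `RNN` (the trained mask estimator), and optionally
#' `MCTR`.
#'
#' @param model a trained [train_rnn()] model (or NULL to omit `RNN`).
#' @param bank a [gammatone_bank()].
#' @param include_mctr add the MCTR condition.
#' @param mctr_cfg an [mctr_config()].
#' @return named list of processor functions for [evaluate_conditions()].
#' @export
standard_processors <- function(model, bank, include_mctr = FALSE,
                                mctr_cfg = mctr_config()) {
  spec <- default_rnn_frame_spec(bank$rate)
  p <- list(
    NP = function(mx) mx$mixture,
    trueIRM = function(mx) {
      irm <- compute_irm(extract_features(mx$clean, bank, spec),
                         extract_features(mx$transient_placed, bank, spec))
      apply_mask(mx$mixture, irm, bank, spec)
    })
  if (!is.null(model))
    p$RNN <- function(mx) rnn_enhance(mx$mixture, model, bank, spec)
  if (include_mctr)
    p$MCTR <- function(mx) mctr_process(mx$mixture, mctr_cfg)
  p
}
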