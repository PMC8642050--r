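#' ERB_N-number (Cam) scale
#'
#' Converts frequency in Hz to the ERB_N-number scale,
#' `E(f) = 21.4 log10(4.37 f / 1000 + 1)`, and back. Auditory filter
#' center frequencies are spaced uniformly on this scale.
#'
#' @param f frequency in Hz.
#' @return ERB_N-number in Cams.
#' @export
erb_number <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)

#' @rdname erb_number
#' @param e ERB_N-number in Cams.
#' @export
erb_number_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' Equivalent rectangular bandwidth of the auditory filter
#' @param f center frequency in Hz.
#' @return ERB_N in Hz: `24.7 (4.37 f / 1000 + 1)`.
#' @export
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

#' Build a spectral-weighting gammatone filterbank
#'
#' Channel center frequencies are spaced at equal ERB_N-number steps from
#' `f_lo` to `f_hi` (defaults 50-8000 Hz, 64 channels). Each channel's
#' weights are the squared magnitude response of a 4th-order gammatone filter
#' with bandwidth `1.019 * ERB_N(fc)`, evaluated at the one-sided FFT bin
#' frequencies and normalized to a unit peak. Band energies are then obtained
#' by weighting short-time power spectra, rather than by time-domain
#' filtering. With a single channel the center is placed at `f_lo`.
#'
#' @param n_channels number of channels (default 64).
#' @param f_lo,f_hi lowest and highest center frequency in Hz.
#' @param rate sampling rate in Hz of the signals to be analyzed.
#' @param fft_size FFT length in samples (frames are zero-padded to this).
#' @return an object of class `gammatone_bank` with fields `n_channels`,
#'   `center_freqs`, `bin_weights` (channel x bin), `rate`, `fft_size`.
#' @export
build_bank <- function(n_channels = 64L, f_lo = 50, f_hi = 8000,
                       rate = 16000, fft_size = 128L) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 1L) stop("build_bank: n_channels must be >= 1")
  if (!(0 < f_lo && f_lo < f_hi)) stop("build_bank: need 0 < f_lo < f_hi")
  if (f_hi > rate / 2) stop("build_bank: f_hi exceeds the Nyquist frequency")
  cf <- if (n_channels == 1L) f_lo else
    erb_number_inv(seq(erb_number(f_lo), erb_number(f_hi),
                       length.out = n_channels))
  n_bins <- fft_size %/% 2L + 1L
  bin_freqs <- (seq_len(n_bins) - 1L) * rate / fft_size
  b <- 1.019 * erb_bandwidth(cf)
  # 4th-order gammatone squared magnitude: [1 + ((f - fc)/b)^2]^(-4)
  w <- outer(seq_len(n_channels), seq_len(n_bins), function(i, k) {
    (1 + ((bin_freqs[k] - cf[i]) / b[i])^2)^(-4)
  })
  structure(list(n_channels = n_channels, center_freqs = cf,
                 bin_weights = w, rate = rate, fft_size = as.integer(fft_size),
                 bin_freqs = bin_freqs),
            class = "gammatone_bank")
}

#' @export
print.gammatone_bank <- function(x, ...) {
  cat(sprintf(
    "<gammatone_bank: %d channels, %.0f-%.0f Hz, rate %g Hz, FFT %d>\n",
    x$n_channels, min(x$center_freqs), max(x$center_freqs), x$rate,
    x$fft_size))
  invisible(x)
}

#' Gammatone-weighted short-time energy features
#'
#' Frames the signal (5-ms Hann, 50% overlap by default), zero-pads each
#' windowed frame to the bank's FFT size, and computes per-channel energies
#' `E(j, i) = sum_k |X_jk|^2 w_ik` over one-sided FFT bins. Energies scale as
#' the square of the signal amplitude; a silent signal yields all zeros.
#'
#' @param x an [audio_signal()] whose rate matches `bank$rate`.
#' @param bank a [gammatone_bank()].
#' @param spec a [frame_spec()]; default 5-ms Hann frames, 50% overlap.
#' @return an object of class `feature_matrix` with fields `values`
#'   (frame x channel), `frame_times` (s, frame starts), `bank`, `spec`,
#'   `n_samples` (source length), and `phase_frames` for resynthesis.
#' @export
extract_features <- function(x, bank, spec = NULL) {
  stopifnot(inherits(x, "audio_signal"), inherits(bank, "gammatone_bank"))
  if (x$rate != bank$rate)
    stop("extract_features: signal rate does not match bank rate")
  if (is.null(spec)) spec <- default_rnn_frame_spec(bank$rate)
  frames <- frame_signal(x, spec)
  spec_mat <- frames_to_spectra(frames, bank$fft_size)
  n_bins <- bank$fft_size %/% 2L + 1L
  power <- Mod(spec_mat[, seq_len(n_bins), drop = FALSE])^2
  # 2/fft_size: one-sided Parseval scaling, so a channel's energy for a tone
  # at its center equals the windowed frame energy of that tone
  vals <- (2 / bank$fft_size) * power %*% t(bank$bin_weights)
  structure(list(values = vals,
                 frame_times = (seq_len(nrow(vals)) - 1L) * spec$hop / x$rate,
                 bank = bank, spec = spec, n_samples = length(x$samples)),
            class = "feature_matrix")
}

#' Default analysis grid for the RNN chain
#' @param rate sampling rate in Hz.
#' @return a [frame_spec()]: 5-ms Hann frames with 50% overlap.
#' @export
default_rnn_frame_spec <- function(rate = 16000) {
  frame_len <- round(rate * 0.005)
  frame_spec(frame_len, frame_len %/% 2L, "hann")
}

# Row-wise FFT of zero-padded frames (frames x fft_size complex matrix).
frames_to_spectra <- function(frames, fft_size) {
  if (ncol(frames) > fft_size)
    stop("frames_to_spectra: frame longer than FFT size")
  padded <- cbind(frames,
                  matrix(0, nrow(frames), fft_size - ncol(frames)))
  t(stats::mvfft(t(padded)))
}

spectra_to_frames <- function(spectra, frame_len) {
  fr <- Re(t(stats::mvfft(t(spectra), inverse = TRUE))) / ncol(spectra)
  fr[, seq_len(frame_len), drop = FALSE]
}

#' Ideal ratio mask from clean and transient features
#'
#' Per time-frequency unit, `IRM = S^2 / (S^2 + V^2)` where `S^2` and `V^2`
#' are the clean-speech and transient channel energies. Where the total energy
#' is below `1e-12` (digital silence) the mask is defined as 1: silence is
#' treated as "all speech" and left unattenuated. Entries always lie in
#' `[0, 1]`, and the mask is non-increasing in `V^2` at fixed `S^2`.
#'
#' @param clean_feats,transient_feats [extract_features()] results of
#'   identical shape (the clean speech `s` and the transient `v` of the
#'   additive mixture `x = s + v`).
#' @return an object of class `tf_mask` with field `values` in `[0, 1]`.
#' @export
compute_irm <- function(clean_feats, transient_feats) {
  S2 <- feature_values(clean_feats)
  V2 <- feature_values(transient_feats)
  if (!all(dim(S2) == dim(V2)))
    stop("compute_irm: feature shapes differ")
  tot <- S2 + V2
  m <- ifelse(tot < 1e-12, 1, S2 / pmax(tot, 1e-300))
  tf_mask(pmin(pmax(m, 0), 1))
}

feature_values <- function(x) {
  if (inherits(x, "feature_matrix")) x$values else as.matrix(x)
}

#' Construct a time-frequency mask
#' @param values matrix (frame x channel) with entries in `[0, 1]`.
#' @return an object of class `tf_mask`.
#' @export
tf_mask <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("tf_mask: entries must be finite and in [0, 1]")
  structure(list(values = values), class = "tf_mask")
}

#' Apply a channel mask to a waveform
#'
#' Re-analyzes the signal on the same grid as the mask's features, converts
#' the per-channel gains of each frame to per-FFT-bin gains by the
#' weight-normalized combination `g_k = sum_i m_i w_ik / sum_i w_ik` (so an
#' all-ones mask gives unit gain everywhere), scales each bin with its phase
#' preserved, and reconstructs by overlap-add. Bins with negligible total
#' weight (outside the bank's span) are passed through unchanged.
#'
#' @param x the [audio_signal()] to process (e.g. the noisy mixture).
#' @param mask a [tf_mask()] whose frame count matches the framing of `x`.
#' @param bank the [gammatone_bank()] defining channel weights.
#' @param spec the [frame_spec()] of the analysis grid.
#' @return processed [audio_signal()] of the same length as the input.
#' @export
apply_mask <- function(x, mask, bank, spec = NULL) {
  stopifnot(inherits(x, "audio_signal"), inherits(mask, "tf_mask"),
            inherits(bank, "gammatone_bank"))
  if (is.null(spec)) spec <- default_rnn_frame_spec(bank$rate)
  frames <- frame_signal(x, spec)
  if (nrow(frames) != nrow(mask$values))
    stop("apply_mask: mask frame count does not match the signal framing")
  spec_mat <- frames_to_spectra(frames, bank$fft_size)
  n_bins <- bank$fft_size %/% 2L + 1L
  wsum <- colSums(bank$bin_weights)                     # per one-sided bin
  gains_half <- mask$values %*% bank$bin_weights        # frame x bin
  gains_half <- sweep(gains_half, 2L, pmax(wsum, 1e-300), `/`)
  gains_half[, wsum < 1e-12] <- 1                       # outside bank span
  # mirror one-sided gains onto the full FFT grid (real signal symmetry)
  full <- matrix(0, nrow(gains_half), bank$fft_size)
  full[, seq_len(n_bins)] <- gains_half
  if (bank$fft_size > 2L) {
    mir <- seq(2L, n_bins - if (bank$fft_size %% 2L == 0L) 1L else 0L)
    full[, bank$fft_size + 2L - mir] <- gains_half[, mir]
  }
  out_frames <- spectra_to_frames(spec_mat * full, spec$frame_len)
  overlap_add(out_frames, spec, x$rate, length_hint = length(x$samples))
}
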