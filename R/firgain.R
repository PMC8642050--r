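#' Frequency-dependent gain table
#'
#' A per-frequency linear-amplification prescription (e.g. a hearing-aid
#' fitting formula evaluated for one audiogram): gains in dB at ascending
#' frequencies in Hz. The table is interpolated linearly in dB between its
#' points and held constant beyond its ends.
#'
#' @param frequencies strictly increasing frequencies in Hz.
#' @param gains gains in dB, one per frequency.
#' @return an object of class `gain_table`.
#' @export
gain_table <- function(frequencies, gains) {
  frequencies <- as.numeric(frequencies)
  gains <- as.numeric(gains)
  if (length(frequencies) != length(gains) || length(frequencies) < 1L)
    stop("gain_table: frequencies and gains must have equal positive length")
  if (any(diff(frequencies) <= 0))
    stop("gain_table: frequencies must be strictly increasing")
  if (!all(is.finite(frequencies)) || !all(is.finite(gains)))
    stop("gain_table: values must be finite")
  structure(list(frequencies = frequencies, gains = gains),
            class = "gain_table")
}

# dB gain of the table at arbitrary frequencies (linear interp, flat ends).
gain_table_db_at <- function(table, f) {
  if (length(table$frequencies) == 1L)
    return(rep(table$gains, length(f)))
  stats::approx(table$frequencies, table$gains, xout = f, rule = 2)$y
}

#' Apply linear frequency-dependent amplification
#'
#' Filters the signal with a linear-phase FIR filter whose magnitude response
#' follows the gain table (frequency-sampling design on a linear grid, as in
#' fir2-style tools). The output is delayed by `(n_taps - 1) / 2` samples and
#' the magnitude response matches the table within 1 dB at the table's
#' frequencies.
#'
#' @param x an [audio_signal()].
#' @param table a [gain_table()].
#' @param n_taps odd FIR length (default 513, typical for audiological
#'   linear-amplification filtering at 16-22 kHz rates).
#' @return filtered [audio_signal()] of the same length as the input.
#' @export
apply_gain_filter <- function(x, table, n_taps = 513L) {
  stopifnot(inherits(x, "audio_signal"), inherits(table, "gain_table"))
  n_taps <- as.integer(n_taps)
  if (n_taps %% 2L == 0L) stop("apply_gain_filter: n_taps must be odd")
  grid <- seq(0, 1, length.out = 512L)          # normalized to Nyquist
  mag <- db2lin(gain_table_db_at(table, grid * x$rate / 2))
  h <- signal::fir2(n_taps - 1L, grid, mag)
  y <- stats::convolve(x$samples, rev(h), type = "open")
  audio_signal(y[seq_along(x$samples)], x$rate)
}
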