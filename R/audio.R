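#' Construct an audio signal
#'
#' A minimal container for a sampled single-channel waveform: a numeric
#' vector of amplitudes on a full-scale of +/- 1.0 together with its
#' sampling rate in Hz.
#'
#' @param samples numeric vector of finite sample amplitudes (length >= 1).
#' @param rate sampling rate in Hz (> 0).
#' @return An object of class `audio_signal` with fields `samples` and `rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 440 * seq(0, 1, by = 1 / 16000)), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L)
    stop("audio_signal: 'samples' must have length >= 1")
  if (!all(is.finite(samples)))
    stop("audio_signal: 'samples' must be finite")
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("audio_signal: 'rate' must be a single positive number")
  structure(list(samples = samples, rate = as.numeric(rate)),
            class = "audio_signal")
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf("<audio_signal: %d samples @ %g Hz (%.3f s), RMS %.4g>\n",
              length(x$samples), x$rate, duration(x), audio_rms(x)))
  invisible(x)
}

#' @export
length.audio_signal <- function(x) length(x$samples)

#' Duration of an audio signal in seconds
#' @param x an `audio_signal`.
#' @return duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$rate
}

as_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}

#' Root-mean-square amplitude
#'
#' Linear RMS of a waveform or segment. Positively homogeneous:
#' `audio_rms(c * x) == abs(c) * audio_rms(x)`.
#'
#' @param x an `audio_signal` or numeric vector.
#' @return non-negative linear RMS amplitude.
#' @export
audio_rms <- function(x) {
  s <- as_samples(x)
  if (length(s) == 0L) stop("audio_rms: empty input")
  sqrt(mean(s^2))
}

#' Package-wide SPL reference
#'
#' The digital-full-scale to sound-pressure-level convention: the SPL, in dB,
#' assigned to a waveform whose RMS equals digital full scale (0 dBFS RMS).
#' Default 100 dB SPL, overridable via `options(tnrtools.spl_ref = ...)`.
#'
#' @return the reference level in dB SPL.
#' @export
spl_reference <- function() {
  getOption("tnrtools.spl_ref", 100)
}

#' Scale a signal to a nominal sound pressure level
#'
#' Rescales the waveform so that its RMS corresponds to `target_db_spl` under
#' the convention of [spl_reference()] (default: 0 dBFS RMS is 100 dB SPL, so
#' 60 dB SPL speech sits at RMS 0.01 full scale, leaving headroom for
#' transients). The waveform shape is unchanged up to a positive scale factor.
#'
#' @param x an `audio_signal` with nonzero RMS.
#' @param target_db_spl target level in dB SPL.
#' @return a rescaled `audio_signal`.
#' @export
set_level <- function(x, target_db_spl) {
  stopifnot(inherits(x, "audio_signal"))
  r <- audio_rms(x)
  if (r <= 0) stop("set_level: cannot scale a zero-RMS signal")
  target_rms <- 10^((target_db_spl - spl_reference()) / 20)
  audio_signal(x$samples * (target_rms / r), x$rate)
}

#' dB helpers
#'
#' `lin2db` converts a linear amplitude ratio to dB (20 log10); `db2lin` is
#' the inverse.
#' @param x ratio (for `lin2db`) or dB value (for `db2lin`).
#' @return converted value.
#' @export
lin2db <- function(x) 20 * log10(x)

#' @rdname lin2db
#' @export
db2lin <- function(x) 10^(x / 20)
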