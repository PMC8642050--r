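#' Analytic (Hilbert) envelope of a signal
#'
#' Magnitude of the analytic signal computed by the FFT method.
#'
#' @param x an [audio_signal()] or numeric vector.
#' @return numeric envelope, same length as the input.
#' @export
analytic_envelope <- function(x) {
  s <- as_samples(x)
  n <- length(s)
  an <- numeric(n); an[1] <- 1
  if (n %% 2L == 0L) { an[2:(n / 2)] <- 2; an[n / 2 + 1] <- 1
  } else if (n > 1L) an[2:((n + 1) / 2)] <- 2
  Mod(stats::fft(stats::fft(s) * an, inverse = TRUE)) / n
}

#' Count prominent envelope peaks
#'
#' Smooths the analytic envelope with a short moving average and counts
#' local maxima above half the global peak, merging maxima closer than
#' `min_sep_ms`.
#'
#' @param x an [audio_signal()].
#' @param smooth_ms moving-average length in ms.
#' @param min_sep_ms minimum separation between counted peaks in ms.
#' @return number of prominent peaks.
#' @export
count_envelope_peaks <- function(x, smooth_ms = 3, min_sep_ms = 10) {
  stopifnot(inherits(x, "audio_signal"))
  env <- analytic_envelope(x)
  k <- max(1L, round(x$rate * smooth_ms / 1000))
  sm <- as.numeric(stats::filter(env, rep(1 / k, k), sides = 2))
  sm[is.na(sm)] <- 0
  locmax <- which(diff(sign(diff(sm))) == -2) + 1L
  locmax <- locmax[sm[locmax] > 0.5 * max(sm)]
  if (length(locmax) == 0L) return(0L)
  min_sep <- x$rate * min_sep_ms / 1000
  kept <- locmax[1]
  for (p in locmax[-1]) if (p - kept[length(kept)] > min_sep) kept <- c(kept, p)
  length(kept)
}

#' Measured 10-90% rise time
#'
#' Rise time of the analytic envelope: the interval between the first
#' crossings of 10% and 90% of the envelope's global peak.
#'
#' @param x an [audio_signal()].
#' @return rise time in ms.
#' @export
measured_rise_time_ms <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  env <- analytic_envelope(x)
  pk <- max(env)
  i10 <- which(env >= 0.1 * pk)[1]
  i90 <- which(env >= 0.9 * pk)[1]
  1000 * (i90 - i10) / x$rate
}
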