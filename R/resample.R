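#' Resample an audio signal
#'
#' Rational-ratio polyphase resampling by windowed-sinc interpolation: each
#' output sample is an inner product of the input with a Kaiser-windowed sinc
#' kernel centred at its exact fractional input position, with the cutoff at
#' the lower of the two Nyquist frequencies. The interpolator is symmetric, so
#' the output has no net delay, and the output duration equals the input
#' duration to within one sample.
#'
#' @param x an [audio_signal()].
#' @param target_rate desired sampling rate in Hz (> 0).
#' @param half_width half-width of the interpolation kernel in input samples
#'   at the lower rate (quality knob; default 16).
#' @param beta Kaiser window shape parameter (default 8.6, ~ -90 dB sidelobes).
#' @return an [audio_signal()] at `target_rate`.
#' @export
resample_audio <- function(x, target_rate, half_width = 16L, beta = 8.6) {
  stopifnot(inherits(x, "audio_signal"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      !is.finite(target_rate) || target_rate <= 0)
    stop("resample_audio: target_rate must be a single positive number")
  if (target_rate == x$rate) return(x)
  s <- x$samples
  n <- length(s)
  m <- as.integer(round(n * target_rate / x$rate))
  if (m < 1L) m <- 1L
  ratio <- target_rate / x$rate
  fc <- 0.5 * min(1, ratio)          # cycles per input sample
  K <- ceiling(half_width / min(1, ratio))
  t <- (seq_len(m) - 1L) / ratio     # input-sample position of each output
  i0 <- floor(t)
  frac <- t - i0
  y <- numeric(m)
  for (j in (-K):(K + 1L)) {
    tau <- frac - j
    h <- 2 * fc * sinc_fn(2 * fc * tau) * kaiser_fn(tau / (K + 1), beta)
    idx <- i0 + j + 1L
    ok <- idx >= 1L & idx <= n
    if (any(ok)) y[ok] <- y[ok] + s[idx[ok]] * h[ok]
  }
  audio_signal(y, target_rate)
}

sinc_fn <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

# Kaiser window evaluated on normalized support [-1, 1]; zero outside.
kaiser_fn <- function(u, beta) {
  w <- numeric(length(u))
  inside <- abs(u) <= 1
  w[inside] <- besselI(beta * sqrt(1 - u[inside]^2), 0) / besselI(beta, 0)
  w
}
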