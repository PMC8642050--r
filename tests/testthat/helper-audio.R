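# Shared fixtures, built in code.

tone <- function(freq, dur_s = 1, rate = 16000, amp = 1) {
  audio_signal(amp * sin(2 * pi * freq * (0:(round(dur_s * rate) - 1)) / rate),
               rate)
}

white_noise <- function(dur_s = 1, rate = 16000, seed = 1, amp = 0.1) {
  set.seed(seed)
  audio_signal(amp * rnorm(round(dur_s * rate)), rate)
}

# relative error in dB between two vectors over an index range
rel_err_db <- function(ref, est, idx = seq_along(ref)) {
  20 * log10(sqrt(mean((est[idx] - ref[idx])^2)) / sqrt(mean(ref[idx]^2)))
}

# dominant frequency from the phase slope of the analytic signal interior
dominant_freq <- function(x) {
  s <- as.numeric(x$samples)
  n <- length(s)
  an <- numeric(n); an[1] <- 1
  if (n %% 2 == 0) { an[2:(n / 2)] <- 2; an[n / 2 + 1] <- 1
  } else an[2:((n + 1) / 2)] <- 2
  z <- fft(fft(s) * an, inverse = TRUE) / n
  i <- floor(n * 0.2):ceiling(n * 0.8)
  dphi <- Arg(z[i + 1] / z[i])
  mean(dphi) * x$rate / (2 * pi)
}

# a tiny training corpus + model, shared by RNN tests (built once per file)
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      man <- build_corpus(n_train = 12, n_test = 3,
                          train_strs = c(-5, -10, -15), test_strs = c(-15),
                          seed = 7)
      bank <- build_bank()
      cfg <- rnn_config(epochs = 4L, seed = 7L)
      fit <- train_on_corpus(man[man$split == "train", ], cfg, bank)
      cache <<- list(manifest = man, bank = bank, model = fit$model)
    }
    cache
  }
})
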