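#' RNN mask-estimator configuration
#'
#' Architecture and training recipe for the LSTM ideal-ratio-mask estimator:
#' three-time-step inputs of 64 gammatone features (frames j-2, j-1, j), two
#' LSTM layers with 128 and 64 units, a fully connected 64-unit output layer
#' with a logistic activation (guaranteeing mask values in [0, 1]), mean
#' squared error loss, and the Adam optimizer (learning rate 0.001,
#' beta1 0.9, beta2 0.999, epsilon 1e-8) with batch size 1500 over 5 epochs.
#'
#' @param timesteps input context length in frames.
#' @param recurrent_units LSTM layer widths.
#' @param output_units output layer width (must equal the bank channel
#'   count).
#' @param learning_rate,beta1,beta2,epsilon Adam parameters.
#' @param batch_size,epochs training schedule.
#' @param seed integer seed controlling initialization and batch shuffling.
#' @return an object of class `rnn_config`.
#' @export
rnn_config <- function(timesteps = 3L, recurrent_units = c(128L, 64L),
                       output_units = 64L, learning_rate = 0.001,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       batch_size = 1500L, epochs = 5L, seed = 1L) {
  stopifnot(timesteps >= 1L, all(recurrent_units >= 1L), output_units >= 1L,
            batch_size >= 1L, epochs >= 1L, learning_rate > 0)
  structure(list(timesteps = as.integer(timesteps),
                 recurrent_units = as.integer(recurrent_units),
                 output_units = as.integer(output_units),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed)),
            class = "rnn_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# One LSTM layer's parameters; gate column order (i, f, g, o).
init_lstm_layer <- function(n_in, n_units) {
  b <- numeric(4L * n_units)
  b[(n_units + 1L):(2L * n_units)] <- 1          # forget-gate bias 1
  list(Wx = glorot(n_in, 4L * n_units), Wh = glorot(n_units, 4L * n_units),
       b = b, n_units = n_units)
}

#' Build an untrained mask-estimation model
#'
#' Weights are Glorot-uniform, forget-gate biases 1; initialization is a
#' deterministic function of `config$seed`, so two builds with the same seed
#' produce identical predictions.
#'
#' @param config an [rnn_config()].
#' @param n_features input feature count per frame (default
#'   `config$output_units`).
#' @return an object of class `rnn_model` (parameters, config, and feature
#'   normalization statistics, initially unset).
#' @export
build_model <- function(config = rnn_config(), n_features = NULL) {
  if (is.null(n_features)) n_features <- config$output_units
  with_seed(config$seed, {
    l1 <- init_lstm_layer(n_features, config$recurrent_units[1])
    l2 <- init_lstm_layer(config$recurrent_units[1], config$recurrent_units[2])
    dense <- list(W = glorot(config$recurrent_units[2], config$output_units),
                  b = numeric(config$output_units))
    structure(list(config = config, n_features = as.integer(n_features),
                   layers = list(l1, l2), dense = dense,
                   norm = NULL, loss_history = numeric(0)),
              class = "rnn_model")
  })
}

#' @export
print.rnn_model <- function(x, ...) {
  cat(sprintf(
    "<rnn_model: %d-step LSTM (%s units) -> %d sigmoid outputs; %s>\n",
    x$config$timesteps, paste(x$config$recurrent_units, collapse = ", "),
    x$config$output_units,
    if (length(x$loss_history)) sprintf("trained, final MSE %.4g",
                                        utils::tail(x$loss_history, 1))
    else "untrained"))
  invisible(x)
}

# ---- feature normalization ------------------------------------------------

# log-compress energies; normalization stats are stored with the model.
log_compress <- function(values) log10(values + 1e-10)

normalize_features <- function(values, norm) {
  z <- log_compress(values)
  sweep(sweep(z, 2L, norm$mean, `-`), 2L, pmax(norm$sd, 1e-6), `/`)
}

#' Stack features into three-time-step training sequences
#'
#' The example for frame `j` stacks frames `(j-2, j-1, j)`; frames before the
#' start are edge-replicated, so the example count equals the frame count.
#'
#' @param features a `feature_matrix`, or a plain numeric matrix of
#'   already-normalized features (frame x channel).
#' @param mask optional [tf_mask()] of matching shape providing training
#'   targets.
#' @param timesteps context length.
#' @return list with `inputs` (list of `timesteps` matrices, each
#'   example x channel, ordered oldest first) and, when `mask` is given,
#'   `targets`.
#' @export
make_sequences <- function(features, mask = NULL, timesteps = 3L) {
  vals <- feature_values(features)
  n <- nrow(vals)
  inputs <- lapply(rev(seq_len(timesteps) - 1L), function(back) {
    idx <- pmax(seq_len(n) - back, 1L)           # edge-replicate frame 1
    vals[idx, , drop = FALSE]
  })
  out <- list(inputs = inputs)
  if (!is.null(mask)) {
    tv <- if (inherits(mask, "tf_mask")) mask$values else as.matrix(mask)
    if (!all(dim(tv) == dim(vals)))
      stop("make_sequences: mask shape does not match features")
    out$targets <- tv
  }
  out
}

# ---- forward / backward ---------------------------------------------------

lstm_forward <- function(layer, xs) {
  n_t <- length(xs)
  B <- nrow(xs[[1]])
  U <- layer$n_units
  h <- matrix(0, B, U); c <- matrix(0, B, U)
  cache <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    z <- xs[[t]] %*% layer$Wx + h %*% layer$Wh +
      matrix(layer$b, B, 4L * U, byrow = TRUE)
    i <- sigmoid(z[, 1:U, drop = FALSE])
    f <- sigmoid(z[, (U + 1):(2 * U), drop = FALSE])
    g <- tanh(z[, (2 * U + 1):(3 * U), drop = FALSE])
    o <- sigmoid(z[, (3 * U + 1):(4 * U), drop = FALSE])
    c_prev <- c
    c <- f * c_prev + i * g
    tc <- tanh(c)
    h_prev_cache <- h
    h <- o * tc
    cache[[t]] <- list(x = xs[[t]], i = i, f = f, g = g, o = o,
                       c_prev = c_prev, tc = tc, h_prev = h_prev_cache,
                       h = h)
  }
  list(hs = lapply(cache, `[[`, "h"), cache = cache)
}

lstm_backward <- function(layer, cache, dhs) {
  n_t <- length(cache)
  U <- layer$n_units
  B <- nrow(dhs[[n_t]])
  dWx <- matrix(0, nrow(layer$Wx), ncol(layer$Wx))
  dWh <- matrix(0, nrow(layer$Wh), ncol(layer$Wh))
  db <- numeric(length(layer$b))
  dxs <- vector("list", n_t)
  dh_next <- matrix(0, B, U); dc_next <- matrix(0, B, U)
  for (t in rev(seq_len(n_t))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    dc <- dc_next + dh * cc$o * (1 - cc$tc^2)
    do_ <- dh * cc$tc
    di <- dc * cc$g
    df <- dc * cc$c_prev
    dg <- dc * cc$i
    dc_next <- dc * cc$f
    dz <- cbind(di * cc$i * (1 - cc$i), df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2), do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(cc$x, dz)
    dWh <- dWh + crossprod(cc$h_prev, dz)
    db <- db + colSums(dz)
    dxs[[t]] <- dz %*% t(layer$Wx)
    dh_next <- dz %*% t(layer$Wh)
  }
  list(dWx = dWx, dWh = dWh, db = db, dxs = dxs)
}

model_forward <- function(model, xs, want_cache = FALSE) {
  f1 <- lstm_forward(model$layers[[1]], xs)
  f2 <- lstm_forward(model$layers[[2]], f1$hs)
  h_last <- f2$hs[[length(f2$hs)]]
  y <- sigmoid(h_last %*% model$dense$W +
                 matrix(model$dense$b, nrow(h_last), ncol(model$dense$W),
                        byrow = TRUE))
  if (want_cache) list(y = y, f1 = f1, f2 = f2, h_last = h_last) else y
}

model_gradients <- function(model, xs, targets) {
  fw <- model_forward(model, xs, want_cache = TRUE)
  B <- nrow(targets)
  dY <- 2 * (fw$y - targets) / (B * ncol(targets))     # d(MSE)/dy
  dz_out <- dY * fw$y * (1 - fw$y)
  gd <- list(W = crossprod(fw$h_last, dz_out), b = colSums(dz_out))
  n_t <- length(xs)
  dhs2 <- c(rep(list(matrix(0, B, model$config$recurrent_units[2])), n_t - 1L),
            list(dz_out %*% t(model$dense$W)))
  b2 <- lstm_backward(model$layers[[2]], fw$f2$cache, dhs2)
  b1 <- lstm_backward(model$layers[[1]], fw$f1$cache, b2$dxs)
  loss <- mean((fw$y - targets)^2)
  list(loss = loss, dense = gd, layer2 = b2, layer1 = b1)
}

# ---- Adam -----------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(p) if (is.matrix(p)) p * 0 else numeric(length(p))
  flat <- flatten_params(model)
  list(m = lapply(flat, zero_like), v = lapply(flat, zero_like), t = 0L)
}

flatten_params <- function(model) {
  list(Wx1 = model$layers[[1]]$Wx, Wh1 = model$layers[[1]]$Wh,
       b1 = model$layers[[1]]$b,
       Wx2 = model$layers[[2]]$Wx, Wh2 = model$layers[[2]]$Wh,
       b2 = model$layers[[2]]$b,
       Wd = model$dense$W, bd = model$dense$b)
}

unflatten_params <- function(model, flat) {
  model$layers[[1]]$Wx <- flat$Wx1; model$layers[[1]]$Wh <- flat$Wh1
  model$layers[[1]]$b <- flat$b1
  model$layers[[2]]$Wx <- flat$Wx2; model$layers[[2]]$Wh <- flat$Wh2
  model$layers[[2]]$b <- flat$b2
  model$dense$W <- flat$Wd; model$dense$b <- flat$bd
  model
}

adam_step <- function(flat, grads, state, cfg) {
  state$t <- state$t + 1L
  lr_t <- cfg$learning_rate * sqrt(1 - cfg$beta2^state$t) /
    (1 - cfg$beta1^state$t)
  for (k in names(flat)) {
    state$m[[k]] <- cfg$beta1 * state$m[[k]] + (1 - cfg$beta1) * grads[[k]]
    state$v[[k]] <- cfg$beta2 * state$v[[k]] + (1 - cfg$beta2) * grads[[k]]^2
    flat[[k]] <- flat[[k]] - lr_t * state$m[[k]] /
      (sqrt(state$v[[k]]) + cfg$epsilon)
  }
  list(flat = flat, state = state)
}

grads_flat <- function(gr) {
  list(Wx1 = gr$layer1$dWx, Wh1 = gr$layer1$dWh, b1 = gr$layer1$db,
       Wx2 = gr$layer2$dWx, Wh2 = gr$layer2$dWh, b2 = gr$layer2$db,
       Wd = gr$dense$W, bd = gr$dense$b)
}

#' Train the mask estimator
#'
#' Minimizes the mean squared error between predicted and ideal-ratio-mask
#' targets with Adam. Inputs are expected as raw energy features; they are
#' log-compressed and standardized per channel with statistics computed from
#' the training set and stored in the model. Training is a deterministic
#' function of `(model, data, config seed)`.
#'
#' @param model an untrained or previously trained [build_model()] result.
#' @param data a list with `inputs` (list of `timesteps` raw-feature
#'   matrices, as from [make_sequences()]) and `targets` (matrix in [0, 1]).
#' @param epochs,batch_size optional overrides of the model config.
#' @param verbose print per-epoch loss.
#' @return the trained `rnn_model`; `$loss_history` holds one mean training
#'   MSE per epoch.
#' @export
train_rnn <- function(model, data, epochs = NULL, batch_size = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(model, "rnn_model"))
  if (is.null(data$inputs) || is.null(data$targets) ||
      nrow(data$targets) == 0L)
    stop("train_rnn: empty training data")
  cfg <- model$config
  if (!is.null(epochs)) cfg$epochs <- as.integer(epochs)
  if (!is.null(batch_size)) cfg$batch_size <- as.integer(batch_size)
  # normalization statistics from the raw training energies
  all_logs <- log_compress(data$inputs[[length(data$inputs)]])
  model$norm <- list(mean = colMeans(all_logs),
                     sd = apply(all_logs, 2L, stats::sd))
  xs_full <- lapply(data$inputs, normalize_features, norm = model$norm)
  targets <- data$targets
  n <- nrow(targets)
  flat <- flatten_params(model)
  state <- adam_init(model)
  history <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    ord <- with_seed(cfg$seed + 1000L * ep, sample.int(n))
    losses <- numeric(0)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      xs <- lapply(xs_full, function(m) m[idx, , drop = FALSE])
      model <- unflatten_params(model, flat)
      gr <- model_gradients(model, xs, targets[idx, , drop = FALSE])
      st <- adam_step(flat, grads_flat(gr), state, cfg)
      flat <- st$flat; state <- st$state
      losses <- c(losses, gr$loss)
    }
    history[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d: MSE %.5f", ep, cfg$epochs,
                                 history[ep]))
  }
  model <- unflatten_params(model, flat)
  model$loss_history <- c(model$loss_history, history)
  model
}

#' Estimate the ideal ratio mask for a feature matrix
#'
#' @param model a trained [train_rnn()] model (normalization statistics must
#'   be present).
#' @param features a `feature_matrix` (raw energies) with
#'   `model$n_features` channels.
#' @return a [tf_mask()] with one row per frame, entries in [0, 1].
#' @export
estimate_irm <- function(model, features) {
  stopifnot(inherits(model, "rnn_model"))
  vals <- feature_values(features)
  if (ncol(vals) != model$n_features)
    stop("estimate_irm: feature channel count does not match the model")
  if (is.null(model$norm))
    stop("estimate_irm: model has no normalization statistics (untrained)")
  zn <- normalize_features(vals, model$norm)
  seqs <- make_sequences(zn, timesteps = model$config$timesteps)
  y <- model_forward(model, seqs$inputs)
  tf_mask(pmin(pmax(y, 0), 1))
}

#' End-to-end RNN enhancement of a noisy signal
#'
#' Feature extraction, three-frame sequence assembly, mask estimation and
#' mask-based overlap-add resynthesis. The signal must be at the bank's rate
#' (16 kHz by default); resample first if necessary.
#'
#' @param x noisy [audio_signal()] at `bank$rate`.
#' @param model trained [train_rnn()] model.
#' @param bank a [gammatone_bank()].
#' @param spec a [frame_spec()]; default 5-ms Hann, 50% overlap.
#' @return enhanced [audio_signal()] of the same length as the input.
#' @export
rnn_enhance <- function(x, model, bank, spec = NULL) {
  stopifnot(inherits(x, "audio_signal"))
  if (x$rate != bank$rate)
    stop("rnn_enhance: signal rate must equal the bank rate; resample first")
  if (is.null(spec)) spec <- default_rnn_frame_spec(bank$rate)
  feats <- extract_features(x, bank, spec)
  mask <- estimate_irm(model, feats)
  apply_mask(x, mask, bank, spec)
}

# ---- persistence ----------------------------------------------------------

#' Save / load a trained model
#'
#' A single JSON archive holding format version, configuration, feature
#' normalization statistics and all weights; loading restores exact
#' predictions.
#'
#' @param model an `rnn_model`.
#' @param path archive path (`.json`).
#' @return `path` invisibly (`save_model`); the restored `rnn_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rnn_model"))
  ser_mat <- function(m) list(dim = dim(m), data = as.numeric(m))
  obj <- list(
    format = "tnrtools-rnn-1",
    config = unclass(model$config),
    n_features = model$n_features,
    norm = model$norm,
    loss_history = model$loss_history,
    params = lapply(flatten_params(model), function(p)
      if (is.matrix(p)) ser_mat(p) else list(dim = NULL,
                                             data = as.numeric(p))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "tnrtools-rnn-1"))
    stop("load_model: unrecognized archive format")
  cfg <- do.call(rnn_config, obj$config[names(obj$config) %in%
                                          names(formals(rnn_config))])
  model <- build_model(cfg, n_features = obj$n_features)
  de <- function(p) if (!is.null(p$dim) && length(p$dim))
    matrix(p$data, p$dim[1], p$dim[2]) else as.numeric(p$data)
  flat <- lapply(obj$params, de)
  model <- unflatten_params(model, flat)
  if (!is.null(obj$norm))
    model$norm <- list(mean = as.numeric(obj$norm$mean),
                       sd = as.numeric(obj$norm$sd))
  model$loss_history <- as.numeric(obj$loss_history)
  model
}
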