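#' Assemble RNN training data from a corpus manifest
#'
#' Realizes every mixture of the manifest's train split, extracts gammatone
#' features of the mixture and the ideal ratio mask from its known clean and
#' transient components, and stacks everything into three-time-step training
#' sequences (one example per frame).
#'
#' @param manifest a [build_corpus()] manifest (rows with `split == "train"`
#'   are used; pass a subset to restrict).
#' @param bank a [gammatone_bank()].
#' @param spec a [frame_spec()]; default 5-ms Hann, 50% overlap.
#' @param timesteps context length in frames.
#' @return list with `inputs` (list of `timesteps` raw-energy matrices) and
#'   `targets` (IRM matrix), suitable for [train_rnn()].
#' @export
training_data_from_manifest <- function(manifest, bank, spec = NULL,
                                        timesteps = 3L) {
  if (is.null(spec)) spec <- default_rnn_frame_spec(bank$rate)
  rows <- manifest[manifest$split == "train", , drop = FALSE]
  if (nrow(rows) == 0L) rows <- manifest
  in_acc <- vector("list", nrow(rows))
  tg_acc <- vector("list", nrow(rows))
  for (i in seq_len(nrow(rows))) {
    mx <- realize_mixture(rows[i, ])
    feats <- extract_features(mx$mixture, bank, spec)
    irm <- compute_irm(extract_features(mx$clean, bank, spec),
                       extract_features(mx$transient_placed, bank, spec))
    sq <- make_sequences(feats, irm, timesteps = timesteps)
    in_acc[[i]] <- sq$inputs
    tg_acc[[i]] <- sq$targets
  }
  inputs <- lapply(seq_len(timesteps), function(t)
    do.call(rbind, lapply(in_acc, `[[`, t)))
  list(inputs = inputs, targets = do.call(rbind, tg_acc))
}

#' Train a mask estimator on a synthetic corpus
#'
#' Convenience wrapper: builds the default 64-channel bank, assembles
#' training data from the manifest and trains the default model.
#'
#' @param manifest a [build_corpus()] manifest.
#' @param config an [rnn_config()].
#' @param bank optional [gammatone_bank()] (default 64 channels, 50-8000 Hz).
#' @param verbose print per-epoch loss.
#' @return list with `model` (trained), `bank`, and `data` dimensions.
#' @export
train_on_corpus <- function(manifest, config = rnn_config(), bank = NULL,
                            verbose = FALSE) {
  if (is.null(bank)) bank <- build_bank()
  data <- training_data_from_manifest(manifest, bank,
                                      timesteps = config$timesteps)
  model <- build_model(config, n_features = bank$n_channels)
  model <- train_rnn(model, data, verbose = verbose)
  list(model = model, bank = bank,
       n_examples = nrow(data$targets))
}
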