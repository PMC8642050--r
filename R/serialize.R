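# Plain-text serialization of time-frequency objects and configs.

#' Write / read a time-frequency matrix as CSV
#'
#' One row per frame: a `frame_time` column (seconds; 0-based frame index
#' times the hop if no timing is available) followed by one column per
#' channel. Works for `feature_matrix` and `tf_mask` objects or plain
#' matrices.
#'
#' @param x a `feature_matrix`, [tf_mask()], or matrix (frame x channel).
#' @param path output CSV path.
#' @return `path` invisibly (`write_tf_csv`); a list with `frame_times` and
#'   `values` (`read_tf_csv`).
#' @export
write_tf_csv <- function(x, path) {
  vals <- if (inherits(x, "feature_matrix")) x$values
          else if (inherits(x, "tf_mask")) x$values
          else as.matrix(x)
  times <- if (inherits(x, "feature_matrix")) x$frame_times
           else seq_len(nrow(vals)) - 1L
  df <- data.frame(frame_time = times, vals)
  names(df) <- c("frame_time", sprintf("ch%02d", seq_len(ncol(vals))))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tf_csv
#' @export
read_tf_csv <- function(path) {
  df <- utils::read.csv(path)
  list(frame_times = df$frame_time,
       values = as.matrix(df[, -1, drop = FALSE]))
}

#' MCTR configuration as JSON
#'
#' Serializes an [mctr_config()] field-for-field, and rebuilds one from such
#' a file (unknown fields are rejected).
#'
#' @param config an [mctr_config()].
#' @param path JSON path.
#' @return `path` invisibly (`write_mctr_config`); an `mctr_config`
#'   (`read_mctr_config`).
#' @export
write_mctr_config <- function(config, path) {
  stopifnot(inherits(config, "mctr_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mctr_config
#' @export
read_mctr_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- names(formals(mctr_config))
  derived <- c("hop", "n_bins")                 # recomputed by the constructor
  extra <- setdiff(names(obj), c(allowed, derived))
  if (length(extra))
    stop("read_mctr_config: unknown fields: ", paste(extra, collapse = ", "))
  do.call(mctr_config, obj[intersect(names(obj), allowed)])
}
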