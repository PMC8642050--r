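# Paired-comparison preference machinery: balanced trial lists, slider
# scoring on the +/-3 continuum, per-participant aggregation, and exact
# Wilcoxon signed-rank tests.

default_pairs <- function() {
  list(c("RNN", "NP"), c("RNN", "MCTR"), c("MCTR", "NP"))
}

#' Build a balanced paired-comparison trial list
#'
#' One trial per (pair x presentation order x sentence x STR); each pair of
#' conditions occurs in both presentation orders for every sentence and STR,
#' so the default design (3 pairs, 12 sentences, 2 STRs) yields 144 trials.
#' Trial order is randomized with a seed.
#'
#' @param pairs list of 2-vectors of condition labels; the first element of
#'   each pair is its canonical first condition.
#' @param sentences number of sentences (or a vector of sentence ids).
#' @param strs STR set in dB.
#' @param part `"intelligibility"` or `"comfort"`.
#' @param seed integer seed for the presentation-order randomization.
#' @return data.frame with columns `trial`, `comparison`, `first`, `second`,
#'   `sentence_id`, `str_db`, `part`.
#' @export
build_trial_list <- function(pairs = default_pairs(), sentences = 12L,
                             strs = c(-10, -15),
                             part = c("intelligibility", "comfort"),
                             seed = 1L) {
  part <- match.arg(part)
  if (length(sentences) == 1L) sentences <- seq_len(sentences)
  stopifnot(length(pairs) >= 1L, length(sentences) >= 1L, length(strs) >= 1L)
  rows <- list()
  for (p in pairs) {
    stopifnot(length(p) == 2L, p[1] != p[2])
    comparison <- paste(p[1], "vs", p[2])
    for (ord in 1:2) {
      firsts <- if (ord == 1L) p[1] else p[2]
      seconds <- if (ord == 1L) p[2] else p[1]
      g <- expand.grid(sentence_id = sentences, str_db = strs)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = comparison, first = firsts, second = seconds,
        sentence_id = g$sentence_id, str_db = g$str_db, part = part,
        stringsAsFactors = FALSE)
    }
  }
  trials <- do.call(rbind, rows)
  trials <- trials[with_seed(seed, sample.int(nrow(trials))), ]
  trials$trial <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials[, c("trial", "comparison", "first", "second", "sentence_id",
             "str_db", "part")]
}

#' Canonical score of one trial
#'
#' The raw slider runs from -3 ("interval 1 much better") to +3 ("interval 2
#' much better"). The canonical score is sign-corrected so that, regardless
#' of presentation order, a positive value means the pair's canonical first
#' condition was preferred.
#'
#' @param slider raw slider position in `[-3, 3]`.
#' @param trial one row of a [build_trial_list()] data.frame.
#' @return canonical score in `[-3, 3]`.
#' @export
score_trial <- function(slider, trial) {
  if (any(abs(slider) > 3)) stop("score_trial: slider outside [-3, 3]")
  canon_first <- vapply(strsplit(trial$comparison, " vs "), `[`, "", 1L)
  ifelse(trial$first == canon_first, -slider, slider)
}

#' Aggregate canonical scores per participant
#'
#' One preference score per (participant, comparison, STR): the mean of the
#' canonical scores over all sentences and both presentation orders. The
#' trial set of every participant must be complete (both orders of every
#' sentence at every STR); missing cells raise an error naming them.
#'
#' @param responses data.frame with columns `participant`, `comparison`,
#'   `first`, `sentence_id`, `str_db`, `score` (canonical scores).
#' @return data.frame with columns `participant`, `comparison`, `str_db`,
#'   `score`, and `n_trials` averaged per row.
#' @export
aggregate_scores <- function(responses) {
  need <- c("participant", "comparison", "first", "sentence_id", "str_db",
            "score")
  if (!all(need %in% names(responses)))
    stop("aggregate_scores: responses need columns ",
         paste(need, collapse = ", "))
  counts <- stats::aggregate(
    score ~ participant + comparison + str_db + sentence_id + first,
    responses, length)
  if (any(counts$score != 1L))
    stop("aggregate_scores: duplicated trials detected")
  cell <- stats::aggregate(score ~ participant + comparison + str_db,
                           responses, length)
  expected <- max(cell$score)
  bad <- cell[cell$score != expected, , drop = FALSE]
  if (nrow(bad) > 0L)
    stop("aggregate_scores: incomplete cells: ",
         paste(sprintf("%s/%s/%g dB (%d of %d trials)", bad$participant,
                       bad$comparison, bad$str_db, bad$score, expected),
               collapse = "; "))
  out <- stats::aggregate(score ~ participant + comparison + str_db,
                          responses, mean)
  out$n_trials <- expected
  out
}

#' Exact Wilcoxon signed-rank test against zero
#'
#' Zero values are dropped; the remaining absolute values are ranked with
#' midranks for ties; `W` is the smaller of the positive- and negative-rank
#' sums. The two-tailed p-value is exact: twice the null probability of a
#' rank sum at or below `W` under the uniform distribution over all `2^n`
#' sign assignments (computed by convolution over ranks, identical to full
#' enumeration), capped at 1. With n = 10 and no ties this reproduces the
#' classical exact table (e.g. W = 4 gives p = .014, W = 8 gives p = .049).
#'
#' @param values one score per participant.
#' @param mu0 null location (default 0).
#' @return list of class `wilcoxon_exact` with `W`, `n` (after dropping
#'   zeros), and `p_two_tailed`.
#' @export
wilcoxon_exact <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("wilcoxon_exact: all differences are zero")
  r <- rank(abs(d))                       # midranks for ties
  w_pos <- sum(r[d > 0])
  w_neg <- sum(r[d < 0])
  W <- min(w_pos, w_neg)
  # exact null distribution of the positive-rank sum over 2^n sign flips,
  # on a doubled-rank integer grid so midranks stay exact
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)           # counts[s + 1] = #assignments
  counts[1] <- 1
  for (rk in r2) {
    shifted <- c(numeric(rk), counts[seq_len(total + 1L - rk)])
    counts <- counts + shifted
  }
  probs <- counts / 2^n
  p <- 2 * sum(probs[seq_len(as.integer(round(2 * W)) + 1L)])
  structure(list(W = W, n = n, p_two_tailed = min(p, 1)),
            class = "wilcoxon_exact")
}

#' @export
print.wilcoxon_exact <- function(x, ...) {
  cat(sprintf("Exact Wilcoxon signed-rank: W = %g, n = %d, p = %.3f\n",
              x$W, x$n, x$p_two_tailed))
  invisible(x)
}

#' Simulate slider responses for a trial list
#'
#' A test double for human participants: the raw slider response of each
#' trial is the order-signed true preference of its comparison plus Gaussian
#' noise, clipped to the +/-3 continuum. With zero noise, [score_trial()]
#' followed by [aggregate_scores()] recovers the true preferences exactly.
#'
#' @param trials a [build_trial_list()] data.frame.
#' @param true_preferences named numeric vector, one canonical preference
#'   per comparison label.
#' @param noise_sd response noise SD (>= 0).
#' @param seed integer seed.
#' @param participant participant id attached to the responses.
#' @return `trials` with added `slider` (raw), `score` (canonical) and
#'   `participant` columns.
#' @export
simulate_listener <- function(trials, true_preferences, noise_sd = 0.5,
                              seed = 1L, participant = "P01") {
  if (noise_sd < 0) stop("simulate_listener: noise_sd must be >= 0")
  canon_first <- vapply(strsplit(trials$comparison, " vs "), `[`, "", 1L)
  pref <- true_preferences[trials$comparison]
  if (any(is.na(pref)))
    stop("simulate_listener: missing preference for some comparison")
  # slider sign: positive favors interval 2
  raw <- ifelse(trials$first == canon_first, -pref, pref)
  noise <- with_seed(seed, stats::rnorm(nrow(trials), 0, noise_sd))
  slider <- pmin(pmax(raw + noise, -3), 3)
  trials$slider <- slider
  trials$score <- score_trial(slider, trials)
  trials$participant <- participant
  trials
}
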