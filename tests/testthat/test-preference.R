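# Brute-force oracle: exact two-tailed p by enumerating all 2^n sign
# assignments of the ranked absolute values.
wilcoxon_brute <- function(values) {
  d <- values[values != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- min(sum(r[d > 0]), sum(r[d < 0]))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  tplus <- as.numeric(signs %*% r)
  min(1, 2 * mean(tplus <= W + 1e-9))
}

test_that("the default paired-comparison design yields 144 balanced trials", {
  trials <- build_trial_list(seed = 3)
  expect_equal(nrow(trials), 144)
  # each (pair, sentence, STR) cell holds exactly one trial per order
  cells <- table(trials$comparison, trials$sentence_id, trials$str_db,
                 trials$first)
  expect_true(all(cells[cells > 0] == 1))
  expect_equal(sum(cells), 144)
  small <- build_trial_list(pairs = list(c("A", "B")), sentences = 1,
                            strs = -10)
  expect_equal(nrow(small), 2)
  expect_setequal(small$first, c("A", "B"))
  t1 <- build_trial_list(seed = 5)
  t2 <- build_trial_list(seed = 5)
  expect_identical(t1, t2)
})

test_that("slider scoring is order-corrected onto the canonical scale", {
  trials <- data.frame(comparison = c("RNN vs NP", "RNN vs NP"),
                       first = c("NP", "RNN"), second = c("RNN", "NP"),
                       stringsAsFactors = FALSE)
  expect_equal(score_trial(c(0, 0), trials), c(0, 0))
  # RNN presented second, slider +1.5 toward interval 2 -> +1.5 canonical
  expect_equal(score_trial(1.5, trials[1, ]), 1.5)
  # same preference with flipped order: raw slider flips, canonical does not
  expect_equal(score_trial(-1.5, trials[2, ]), 1.5)
  expect_error(score_trial(3.5, trials[1, ]), "slider")
})

test_that("aggregation averages sentences and orders per participant", {
  trials <- build_trial_list(seed = 7)
  resp <- trials
  resp$participant <- "P01"
  resp$score <- 1
  agg <- aggregate_scores(resp)
  expect_true(all(agg$score == 1))
  expect_true(all(agg$n_trials == 24))          # 12 sentences x 2 orders
  expect_equal(nrow(agg), 6)                    # 3 comparisons x 2 STRs

  # antisymmetric responses cancel
  resp2 <- trials
  resp2$participant <- "P01"
  canon_first <- vapply(strsplit(resp2$comparison, " vs "), `[`, "", 1L)
  resp2$score <- ifelse(resp2$first == canon_first, 0.7, -0.7)
  agg2 <- aggregate_scores(resp2)
  expect_true(all(abs(agg2$score) < 1e-12))

  expect_error(aggregate_scores(resp[-1, ]), "incomplete")
})

test_that("exact Wilcoxon reproduces the classical n = 10 table", {
  # construct no-tie samples whose negative part is a single rank
  cases <- list(c(4, 0.014), c(1, 0.004), c(5, 0.02), c(2, 0.006),
                c(7, 0.037), c(8, 0.049))
  for (cs in cases) {
    v <- 1:10
    v[cs[1]] <- -v[cs[1]]
    r <- wilcoxon_exact(v)
    expect_equal(r$W, cs[1])
    expect_equal(r$n, 10)
    expect_equal(round(r$p_two_tailed, 3), cs[2])
  }
})

test_that("the convolution p-value equals full 2^n enumeration", {
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    v <- round(rnorm(n), sample(0:1, 1))        # rounding induces ties
    v <- v[v != 0]
    if (length(v) < 2) next
    r <- wilcoxon_exact(v)
    expect_equal(r$p_two_tailed, wilcoxon_brute(v), tolerance = 1e-12)
    # symmetric under a global sign flip
    expect_equal(wilcoxon_exact(-v)$p_two_tailed, r$p_two_tailed)
  }
  # every achievable W for n = 10 agrees with enumeration
  for (W in 0:15) {
    v <- 1:10
    neg <- integer(0); left <- W
    for (k in 10:1) if (k <= left) { neg <- c(neg, k); left <- left - k }
    if (left != 0) next
    v[neg] <- -v[neg]
    expect_equal(wilcoxon_exact(v)$p_two_tailed, wilcoxon_brute(v),
                 tolerance = 1e-12)
  }
  expect_error(wilcoxon_exact(c(0, 0)), "zero")
  # zeros are dropped and n reflects that
  expect_equal(wilcoxon_exact(c(0, 1, -2, 3))$n, 3)
})

test_that("simulated listeners are recovered exactly in the noiseless limit", {
  trials <- build_trial_list(seed = 9)
  prefs <- c("RNN vs NP" = 0.8, "RNN vs MCTR" = 0.4, "MCTR vs NP" = -0.2)
  resp <- simulate_listener(trials, prefs, noise_sd = 0, seed = 1)
  agg <- aggregate_scores(resp)
  for (cmp in names(prefs))
    expect_equal(agg$score[agg$comparison == cmp],
                 rep(prefs[[cmp]], 2), tolerance = 1e-12)
})

test_that("the exact test has near-nominal power and size in simulation", {
  trials <- build_trial_list(pairs = list(c("RNN", "NP")), sentences = 12,
                             strs = c(-10, -15), seed = 10)
  # power: true preference 1.0, noise 0.5, 10 listeners, 200 replicates
  rejections <- 0L
  for (rep in 1:200) {
    scores <- vapply(1:10, function(p) {
      resp <- simulate_listener(trials, c("RNN vs NP" = 1.0), noise_sd = 0.5,
                                seed = rep * 100L + p)
      mean(resp$score[resp$str_db == -10])
    }, 0)
    if (wilcoxon_exact(scores)$p_two_tailed < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / 200, 0.9)

  # size: true preference 0 -> empirical type-I error within 0.05 +/- 0.03
  set.seed(11)
  fp <- 0L
  for (rep in 1:500) {
    scores <- rnorm(10, 0, 0.3)                 # aggregated null scores
    if (wilcoxon_exact(scores)$p_two_tailed < 0.05) fp <- fp + 1L
  }
  expect_lt(abs(fp / 500 - 0.05), 0.03)
})
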