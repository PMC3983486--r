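test_that("reverse coding mirrors the 1-8 scale and is an involution", {
  expect_equal(reverse_code(3, "negative"), 6)
  expect_equal(reverse_code(5, "positive"), 5)
  g <- feedback_grid()
  expect_equal(reverse_code(reverse_code(g, "negative"), "negative"), g)
  expect_true(all(is_on_feedback_grid(reverse_code(g, "negative"))))
  expect_error(reverse_code(0.5, "positive"), "\\[1, 8\\]")
})

test_that("desirability classification matches the worked trait examples", {
  # positive trait: feedback above own rating is desirable
  expect_equal(as.character(classify_desirability(
    reverse_code(6, "positive"), reverse_code(8, "positive"))), "desirable")
  # negative trait, raw first 3 and raw feedback 5: undesirable after recoding
  expect_equal(as.character(classify_desirability(
    reverse_code(3, "negative"), reverse_code(5, "negative"))), "undesirable")
  # negative trait, raw feedback below own rating: desirable
  expect_equal(as.character(classify_desirability(
    reverse_code(3, "negative"), reverse_code(1, "negative"))), "desirable")
  expect_equal(as.character(classify_desirability(4, 4)), "neutral")
  expect_true(is.na(classify_desirability(NA, 5)))
})

test_that("discrepancy, update, and memory error equal their defining arithmetic", {
  g <- feedback_grid()
  # exhaustive over all rating x grid pairs
  pairs <- expand.grid(first = 1:8, fb = g)
  expect_equal(feedback_discrepancy(pairs$first, pairs$fb),
               abs(pairs$fb - pairs$first))
  # invariant under reverse coding of both arguments
  expect_equal(feedback_discrepancy(9 - pairs$first, 9 - pairs$fb),
               feedback_discrepancy(pairs$first, pairs$fb))
  rat <- expand.grid(first = 1:8, second = 1:8)
  expect_equal(rating_update(rat$first, rat$second), rat$second - rat$first)
  expect_equal(memory_error(7.0, 5.5), 1.5)
  set.seed(1)
  a <- sample(g, 500, TRUE); b <- sample(g, 500, TRUE)
  expect_equal(mean(memory_error(a, b)), mean(abs(a - b)))
})

test_that("an agent moving 30% toward feedback scores 0.3 in every cell", {
  set.seed(21)
  n <- 400
  trials <- data.frame(
    participant_id = "P1",
    run = 1L,
    target = sample(c("self", "other"), n, TRUE),
    adjective = sprintf("a%03d", seq_len(n)),
    valence = sample(c("positive", "negative"), n, TRUE),
    first_rating = sample(2:7, n, TRUE),
    feedback = sample(feedback_grid(), n, TRUE),
    stringsAsFactors = FALSE
  )
  # second rating exactly 30% of the discrepancy toward the feedback
  rc <- function(x, v) ifelse(v == "negative", 9 - x, x)
  first_rec <- rc(trials$first_rating, trials$valence)
  fb_rec <- rc(trials$feedback, trials$valence)
  second_rec <- first_rec + 0.3 * (fb_rec - first_rec)
  trials$second_rating <- ifelse(trials$valence == "negative",
                                 9 - second_rec, second_rec)
  trials$recollection <- trials$feedback
  sc <- score_trials(trials)
  filled <- sc[sc$n_trials_final > 0, ]
  expect_gt(nrow(filled), 0)
  expect_equal(filled$relative_absolute_mean_update,
               rep(0.3, nrow(filled)), tolerance = 1e-12)
  # and a perfect conformist scores exactly 1 in every cell
  trials2 <- trials
  trials2$second_rating <- trials2$feedback
  sc2 <- score_trials(trials2)
  filled2 <- sc2[sc2$n_trials_final > 0, ]
  expect_equal(filled2$relative_absolute_mean_update,
               rep(1, nrow(filled2)), tolerance = 1e-12)
  # memory: recollection equal to feedback gives zero error
  expect_equal(filled$mean_absolute_memory_error,
               rep(0, nrow(filled)))
})

test_that("a non-updating cohort scores exactly zero everywhere", {
  set.seed(22)
  t <- random_trial_table(3, 60, missing_prob = 0)
  t$second_rating <- t$first_rating
  sc <- score_trials(t)
  vals <- sc$relative_absolute_mean_update[sc$n_trials_final > 0]
  expect_equal(vals, rep(0, length(vals)))
})

test_that("scoring matches an independently coded brute-force aggregator", {
  set.seed(23)
  for (i in 1:12) {
    t <- random_trial_table(n_participants = 3, n_trials = 50,
                            missing_prob = 0.08)
    got <- as.data.frame(score_trials(t))
    want <- brute_force_cell_scores(t)
    m <- merge(got, want,
               by = c("participant_id", "target", "desirability"),
               suffixes = c("", ".bf"))
    expect_equal(nrow(m), nrow(want))
    expect_equal(m$n_trials_final, m$n_trials_final.bf)
    expect_equal(m$relative_absolute_mean_update,
                 m$relative_absolute_mean_update.bf, tolerance = 1e-12)
    expect_equal(m$mean_feedback_discrepancy,
                 m$mean_feedback_discrepancy.bf, tolerance = 1e-12)
    expect_equal(m$mean_absolute_memory_error,
                 m$mean_absolute_memory_error.bf, tolerance = 1e-12)
  }
})

test_that("scores are invariant under mirroring the whole log", {
  set.seed(24)
  t <- random_trial_table(4, 60, missing_prob = 0.05)
  mirror <- t
  mirror$valence <- ifelse(t$valence == "positive", "negative", "positive")
  mirror$first_rating <- 9L - t$first_rating
  mirror$second_rating <- 9L - t$second_rating
  mirror$feedback <- 9 - t$feedback
  mirror$recollection <- 9 - t$recollection
  a <- score_trials(t)
  b <- score_trials(mirror)
  expect_equal(a$relative_absolute_mean_update,
               b$relative_absolute_mean_update, tolerance = 1e-12)
  expect_equal(a$mean_feedback_discrepancy, b$mean_feedback_discrepancy,
               tolerance = 1e-12)
  expect_equal(a$mean_absolute_memory_error, b$mean_absolute_memory_error,
               tolerance = 1e-12)
})

test_that("the score is a ratio of means, not a mean of per-trial ratios", {
  # two desirable self trials: updates 1 and 0, discrepancies 1 and 3
  t <- data.frame(
    participant_id = "P1", run = 1L, target = "self",
    adjective = c("a", "b"), valence = "positive",
    first_rating = c(4L, 4L), feedback = c(5, 7),
    second_rating = c(5L, 4L), recollection = NA_real_,
    stringsAsFactors = FALSE
  )
  sc <- score_trials(t)
  got <- sc$relative_absolute_mean_update[sc$n_trials_final > 0]
  expect_equal(got, 0.25) # (1+0)/2 over (1+3)/2
  mean_of_ratios <- mean(c(1 / 1, 0 / 3))
  expect_false(isTRUE(all.equal(got, mean_of_ratios)))
})

test_that("exclusion accounting is exact and missingness follows the rules", {
  set.seed(25)
  t <- random_trial_table(5, 80, missing_prob = 0.1)
  ex <- tally_exclusions(t)
  expect_true(all(ex$n_scheduled ==
                    ex$n_missing + ex$n_zero_discrepancy + ex$n_final))
  expect_equal(sum(ex$n_scheduled), nrow(t))
  # trials missing only the second rating still feed memory scoring
  t2 <- data.frame(
    participant_id = "P1", run = 1L, target = "self",
    adjective = c("a", "b"), valence = "positive",
    first_rating = c(4L, 4L), feedback = c(6, 6),
    second_rating = c(NA_integer_, 5L), recollection = c(5, NA_real_),
    stringsAsFactors = FALSE
  )
  sc2 <- score_trials(t2)
  cell <- sc2[sc2$target == "self" & sc2$desirability == "desirable", ]
  expect_equal(cell$n_trials_final, 1L) # only the answered trial
  expect_equal(cell$n_memory_trials, 1L) # only the recollected trial
  expect_equal(cell$mean_absolute_memory_error, 1)
})

test_that("valence-split scoring agrees with scoring each valence alone", {
  set.seed(26)
  t <- random_trial_table(3, 80, missing_prob = 0.05)
  by_val <- score_trials(t, by_valence = TRUE)
  expect_equal(nrow(by_val), 3 * 2 * 2 * 2)
  for (v in c("positive", "negative")) {
    solo <- score_trials(t[t$valence == v, ])
    sub <- by_val[by_val$valence == v, names(solo)]
    m <- merge(as.data.frame(solo), as.data.frame(sub),
               by = c("participant_id", "target", "desirability"),
               suffixes = c(".a", ".b"))
    expect_equal(m$relative_absolute_mean_update.a,
                 m$relative_absolute_mean_update.b, tolerance = 1e-12)
  }
})
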