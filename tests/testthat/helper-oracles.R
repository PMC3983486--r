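# Independent brute-force implementations used as oracles. Deliberately
# written with plain loops and no shared code with the package internals.

# Per-participant (target x desirability) cell scores, straight from the
# verbal scoring rules.
brute_force_cell_scores <- function(trials) {
  out <- list()
  for (pid in unique(trials$participant_id)) {
    for (tg in c("self", "other")) {
      rows <- trials[trials$participant_id == pid &
                       as.character(trials$target) == tg, ]
      # recode everything for negative traits
      neg <- as.character(rows$valence) == "negative"
      rc <- function(x) ifelse(neg, 9 - x, x)
      first <- rc(rows$first_rating)
      second <- rc(rows$second_rating)
      fb <- rc(rows$feedback)
      for (ds in c("desirable", "undesirable")) {
        cmp <- if (ds == "desirable") fb > first else fb < first
        keep <- !is.na(rows$first_rating) & !is.na(rows$second_rating) &
          !is.na(cmp) & cmp
        upd <- numeric(0); dsc <- numeric(0)
        for (i in which(keep)) {
          upd <- c(upd, second[i] - first[i])
          dsc <- c(dsc, abs(fb[i] - first[i]))
        }
        mem <- numeric(0)
        keep_mem <- !is.na(rows$first_rating) & !is.na(rows$recollection) &
          !is.na(cmp) & cmp
        for (i in which(keep_mem)) {
          mem <- c(mem, abs(rows$feedback[i] - rows$recollection[i]))
        }
        rel <- if (length(upd)) (mean(upd) / mean(dsc)) else NA_real_
        flip <- if (ds == "undesirable") -1 else 1
        out[[length(out) + 1L]] <- data.frame(
          participant_id = pid, target = tg, desirability = ds,
          n_trials_final = length(upd),
          mean_feedback_discrepancy = if (length(dsc)) mean(dsc) else NA_real_,
          relative_absolute_mean_update = flip * rel,
          mean_absolute_memory_error = if (length(mem)) mean(mem) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

# Random but schema-valid trial table (not via the cohort simulator).
random_trial_table <- function(n_participants = 4, n_trials = 40,
                               missing_prob = 0.05) {
  g <- conformity::feedback_grid()
  rows <- n_participants * n_trials
  t <- data.frame(
    participant_id = rep(sprintf("S%02d", seq_len(n_participants)),
                         each = n_trials),
    run = rep_len(1:4, rows),
    target = sample(c("self", "other"), rows, replace = TRUE),
    adjective = sprintf("adj%04d", seq_len(rows)),
    valence = sample(c("positive", "negative"), rows, replace = TRUE),
    first_rating = sample(1:8, rows, replace = TRUE),
    feedback = sample(g, rows, replace = TRUE),
    second_rating = sample(1:8, rows, replace = TRUE),
    recollection = sample(g, rows, replace = TRUE),
    stringsAsFactors = FALSE
  )
  t$first_rating[runif(rows) < missing_prob] <- NA
  t$second_rating[runif(rows) < missing_prob] <- NA
  t$recollection[runif(rows) < missing_prob] <- NA
  t
}

# Pair of vectors whose sample Pearson correlation is exactly r.
make_cor_pair <- function(r, n, seed = 1) {
  set.seed(seed)
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  z2 <- residuals(lm(z2 ~ z1))
  z1 <- as.vector(scale(z1))
  z2 <- as.vector(scale(z2))
  list(x = z1, y = r * z1 + sqrt(1 - r^2) * z2)
}

# Bivariate normal sample with population correlation rho.
rbvn <- function(n, rho) {
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  cbind(z1, rho * z1 + sqrt(1 - rho^2) * z2)
}
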