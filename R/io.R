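#' Read and validate a trial log
#'
#' Trial logs are UTF-8 comma-delimited text with a header and one trial per
#' row. Required columns: `participant_id`, `run`, `target`
#' (`self`/`other`), `adjective`, `valence` (`positive`/`negative`),
#' `first_rating` (integer 1--8 or empty), `feedback` (a [feedback_grid()]
#' value), `second_rating` (integer 1--8 or empty), `recollection` (grid
#' value or empty). An `order_index` column is kept when present. All
#' violations are collected and reported with their file line numbers.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_trial_log <- function(path) {
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  miss <- setdiff(
    c("participant_id", "run", "target", "adjective", "valence",
      "first_rating", "feedback", "second_rating", "recollection"),
    hdr
  )
  if (length(miss)) {
    stop("trial log ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      run = readr::col_integer(),
      target = readr::col_character(),
      adjective = readr::col_character(),
      valence = readr::col_character(),
      first_rating = readr::col_integer(),
      feedback = readr::col_double(),
      second_rating = readr::col_integer(),
      recollection = readr::col_double(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  probs <- readr::problems(trials)
  if (nrow(probs)) {
    stop("trial log ", path, " has unparseable fields at lines: ",
         paste(utils::head(unique(probs$row + 1L), 10), collapse = ", "))
  }
  issues <- character()
  flag <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      lines <- which(bad) + 1L # header occupies line 1
      issues <<- c(issues, paste0(
        what, " (lines ", paste(utils::head(lines, 10), collapse = ", "),
        if (sum(bad, na.rm = TRUE) > 10) ", ..." else "", ")"
      ))
    }
  }
  flag(!trials$target %in% c("self", "other"),
       "target must be 'self' or 'other'")
  flag(!trials$valence %in% c("positive", "negative"),
       "valence must be 'positive' or 'negative'")
  flag(!is.na(trials$run) & trials$run < 1, "run must be >= 1")
  rating_bad <- function(x) !is.na(x) & (x < 1 | x > 8)
  flag(rating_bad(trials$first_rating), "first_rating outside 1..8")
  flag(rating_bad(trials$second_rating), "second_rating outside 1..8")
  flag(is.na(trials$feedback), "feedback missing")
  flag(!is.na(trials$feedback) & !is_on_feedback_grid(trials$feedback),
       "feedback not on the feedback grid")
  flag(!is.na(trials$recollection) & !is_on_feedback_grid(trials$recollection),
       "recollection not on the feedback grid")
  if (length(issues)) {
    stop("invalid trial log ", path, ":\n  ",
         paste(issues, collapse = "\n  "))
  }
  trials$target <- factor(trials$target, levels = c("self", "other"))
  trials$valence <- factor(trials$valence, levels = c("positive", "negative"))
  trials
}

#' @rdname read_trial_log
#' @param trials Trial table to write.
#' @export
write_trial_log <- function(trials, path) {
  check_trial_columns(trials)
  out <- trials
  out$feedback <- sprintf("%.1f", out$feedback)
  out$recollection <- ifelse(is.na(out$recollection), NA,
                             sprintf("%.1f", out$recollection))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write a participant table
#'
#' Comma-delimited with columns `participant_id`, `culture`, `place`,
#' `interdependence`, `independence`, `self_esteem`, `perceived_similarity`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_participants <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c("participant_id", "culture", "place", "interdependence",
                    "independence", "self_esteem", "perceived_similarity"),
                  names(p))
  if (length(miss)) {
    stop("participant table ", path, " is missing columns: ",
         paste(miss, collapse = ", "))
  }
  p$culture <- factor(p$culture, levels = c("German", "Chinese"))
  p$place <- factor(p$place, levels = c("Berlin", "Beijing"))
  p
}

#' @rdname read_participants
#' @param participants Participant table to write.
#' @export
write_participants <- function(participants, path) {
  out <- participants
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 6))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Read / write a condition-score table
#'
#' The tidy per-participant-per-cell output of [score_trials()], serialized
#' with scores at six decimals.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_scores <- function(path) {
  sc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  sc$target <- factor(sc$target, levels = c("self", "other"))
  sc$desirability <- factor(sc$desirability,
                            levels = c("desirable", "undesirable"))
  sc
}

#' @rdname read_scores
#' @param scores Score table to write.
#' @export
write_scores <- function(scores, path) {
  out <- scores
  num <- vapply(out, is.double, TRUE)
  out[num] <- lapply(out[num], function(x) round(x, 6))
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
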