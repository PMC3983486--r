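#' Reverse-code ratings of negative traits
#'
#' Ratings (and feedback values) for negative trait adjectives are mirrored
#' on the 1--8 scale (`9 - x`) so that higher always means more socially
#' desirable. Positive-trait values are returned unchanged. The feedback grid
#' is closed under this reflection.
#'
#' @param x Numeric vector of ratings or feedback values in \[1, 8\].
#' @param valence Character/factor vector (`"positive"`/`"negative"`),
#'   recycled to the length of `x`.
#' @return Numeric vector on the desirability scale.
#' @export
#' @examples
#' reverse_code(c(3, 5), c("negative", "positive"))
reverse_code <- function(x, valence) {
  stopifnot(is.numeric(x))
  bad <- !is.na(x) & (x < 1 | x > 8)
  if (any(bad)) {
    stop("values must lie in [1, 8]; offending values: ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "))
  }
  valence <- rep_len(as.character(valence), length(x))
  ifelse(valence == "negative", 9 - x, x)
}

#' Classify feedback desirability
#'
#' On the reverse-coded (desirability) scale, feedback above the first own
#' rating is desirable, below it undesirable, and exactly equal feedback is
#' neutral (a zero-discrepancy trial, excluded from scoring). Missing inputs
#' yield `NA`.
#'
#' @param first_recoded,feedback_recoded Numeric vectors on the
#'   reverse-coded scale.
#' @return Factor with levels `"desirable"`, `"undesirable"`, `"neutral"`.
#' @export
#' @examples
#' classify_desirability(reverse_code(6, "positive"), reverse_code(8, "positive"))
#' classify_desirability(reverse_code(3, "negative"), reverse_code(5, "negative"))
classify_desirability <- function(first_recoded, feedback_recoded) {
  d <- feedback_recoded - first_recoded
  factor(
    dplyr::case_when(
      is.na(d) ~ NA_character_,
      d > 0 ~ "desirable",
      d < 0 ~ "undesirable",
      TRUE ~ "neutral"
    ),
    levels = c("desirable", "undesirable", "neutral")
  )
}

#' Feedback discrepancy
#'
#' The absolute difference between the feedback rating and the first own
#' rating -- the experimentally manipulated social-comparison term. Invariant
#' under reverse coding of both arguments.
#'
#' @param first,feedback Numeric vectors (both on the same scale).
#' @return Non-negative numeric vector; `NA` where either input is missing.
#' @export
feedback_discrepancy <- function(first, feedback) {
  abs(feedback - first)
}

#' Trial-level update
#'
#' The change in the participant's own rating after feedback. On the
#' reverse-coded scale a positive update is movement in the socially
#' desirable direction.
#'
#' @param first,second Numeric vectors (same scale).
#' @return Signed numeric vector; `NA` where either input is missing.
#' @export
rating_update <- function(first, second) {
  second - first
}

#' Feedback-memory error
#'
#' The absolute difference between the feedback rating shown and the
#' participant's later recollection of it, on the raw (non-recoded) scale.
#'
#' @param feedback,recollection Numeric vectors on the raw scale.
#' @return Non-negative numeric vector; `NA` where either input is missing.
#' @export
memory_error <- function(feedback, recollection) {
  abs(feedback - recollection)
}

#' Score a trial log into per-participant condition scores
#'
#' Applies the full preprocessing chain and produces one row per participant
#' per (target x desirability) cell (optionally further split by trait
#' valence):
#'
#' * ratings and feedback for negative traits are reverse-coded;
#' * trials with a missing first or second rating are excluded from update
#'   scoring (they are retained for memory scoring when the first rating and
#'   the recollection are present);
#' * trials with a feedback discrepancy of exactly zero are excluded;
#' * within each cell the *relative mean update* is the mean update divided
#'   by the mean feedback discrepancy (a ratio of means, not a mean of
#'   ratios), and the *relative absolute mean update* flips its sign for
#'   undesirable feedback so that positive values always mean movement toward
#'   the feedback. A value of 0.3 means ratings moved on average 30% of the
#'   way toward the feedback.
#'
#' Empty cells yield `NA` scores with `n_trials_final = 0`.
#'
#' @param trials A trial log (see [read_trial_log()] for the schema); ratings
#'   may be non-integer (the scoring arithmetic does not require Likert
#'   rounding).
#' @param by_valence Also split cells by trait valence (for the five-factor
#'   analysis)?
#' @return A tibble with columns `participant_id`, `target`, `desirability`
#'   (and `valence` when `by_valence`), `n_trials_final`,
#'   `mean_feedback_discrepancy`, `mean_update`, `relative_mean_update`,
#'   `relative_absolute_mean_update`, `mean_absolute_update`,
#'   `mean_absolute_memory_error`, `n_memory_trials`.
#' @seealso [tally_exclusions()] for the exclusion bookkeeping,
#'   [overall_updating()] for the per-participant average.
#' @export
score_trials <- function(trials, by_valence = FALSE) {
  check_trial_columns(trials)
  first_rec <- reverse_code(trials$first_rating, trials$valence)
  second_rec <- reverse_code(trials$second_rating, trials$valence)
  fb_rec <- reverse_code(trials$feedback, trials$valence)
  work <- tibble::tibble(
    participant_id = trials$participant_id,
    target = factor(as.character(trials$target), levels = c("self", "other")),
    valence = factor(as.character(trials$valence),
                     levels = c("positive", "negative")),
    desirability = classify_desirability(first_rec, fb_rec),
    discrepancy = feedback_discrepancy(first_rec, fb_rec),
    update = rating_update(first_rec, second_rec),
    mem_err = memory_error(trials$feedback, trials$recollection)
  )
  keys <- c("participant_id", "target", "desirability",
            if (by_valence) "valence")
  scored <- work |>
    dplyr::filter(
      .data$desirability %in% c("desirable", "undesirable")
    ) |>
    dplyr::mutate(desirability = factor(as.character(.data$desirability),
                                        levels = c("desirable", "undesirable"))) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      n_trials_final = sum(!is.na(.data$update)),
      mean_feedback_discrepancy = mean_or_na(.data$discrepancy[!is.na(.data$update)]),
      mean_update = mean_or_na(.data$update[!is.na(.data$update)]),
      n_memory_trials = sum(!is.na(.data$mem_err)),
      mean_absolute_memory_error = mean_or_na(.data$mem_err[!is.na(.data$mem_err)]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      relative_mean_update = .data$mean_update / .data$mean_feedback_discrepancy,
      sign_flip = ifelse(.data$desirability == "undesirable", -1, 1),
      relative_absolute_mean_update = .data$sign_flip * .data$relative_mean_update,
      mean_absolute_update = .data$sign_flip * .data$mean_update
    ) |>
    dplyr::select(-"sign_flip")
  # ensure every cell exists for every participant, even if empty
  full <- tidyr::complete(
    scored,
    !!!rlang::syms(keys),
    fill = list(n_trials_final = 0L, n_memory_trials = 0L)
  )
  dplyr::arrange(full, .data$participant_id, .data$target, .data$desirability)
}

#' Exclusion accounting per participant and target
#'
#' For every participant x target combination, counts the scheduled trials,
#' those excluded for a missing first or second rating, those (answered)
#' trials excluded for a zero feedback discrepancy, and the trials entering
#' update scoring. The four counts satisfy
#' `n_scheduled = n_missing + n_zero_discrepancy + n_final`.
#'
#' @param trials A trial log.
#' @return A tibble with columns `participant_id`, `target`, `n_scheduled`,
#'   `n_missing`, `n_zero_discrepancy`, `n_final`.
#' @export
tally_exclusions <- function(trials) {
  check_trial_columns(trials)
  first_rec <- reverse_code(trials$first_rating, trials$valence)
  fb_rec <- reverse_code(trials$feedback, trials$valence)
  tibble::tibble(
    participant_id = trials$participant_id,
    target = factor(as.character(trials$target), levels = c("self", "other")),
    missing = is.na(trials$first_rating) | is.na(trials$second_rating),
    zero = !is.na(first_rec) & fb_rec == first_rec
  ) |>
    dplyr::group_by(.data$participant_id, .data$target) |>
    dplyr::summarise(
      n_scheduled = dplyr::n(),
      n_missing = sum(.data$missing),
      n_zero_discrepancy = sum(!.data$missing & .data$zero),
      n_final = sum(!.data$missing & !.data$zero),
      .groups = "drop"
    )
}

#' Per-participant overall updating
#'
#' Averages the relative absolute mean updates across the four
#' (target x desirability) cells -- the participant-level social-conformity
#' score used for the individual-difference correlations. Participants with
#' any undefined cell get `NA`.
#'
#' @param scores Output of [score_trials()].
#' @return A tibble with columns `participant_id`, `overall_update`.
#' @export
overall_updating <- function(scores) {
  scores |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      overall_update = mean(.data$relative_absolute_mean_update),
      .groups = "drop"
    )
}

mean_or_na <- function(x) {
  if (length(x) == 0) NA_real_ else mean(x)
}

check_trial_columns <- function(trials) {
  needed <- c("participant_id", "target", "valence", "first_rating",
              "feedback", "second_rating", "recollection")
  miss <- setdiff(needed, names(trials))
  if (length(miss)) {
    stop("trial table is missing columns: ", paste(miss, collapse = ", "))
  }
  invisible(trials)
}
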