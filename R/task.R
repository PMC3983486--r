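#' Build a trait-adjective stimulus set
#'
#' The paradigm uses a balanced set of positive and negative trait adjectives
#' (40 of each by default). Labels can be supplied (e.g. real translated
#' adjectives); otherwise deterministic placeholder labels are generated.
#'
#' @param n_positive,n_negative Number of positive / negative adjectives
#'   (each at least 1).
#' @param labels Optional character vector of unique labels, positive traits
#'   first, of length `n_positive + n_negative`.
#' @return A tibble with columns `adjective` (character, unique) and
#'   `valence` (factor, `"positive"`/`"negative"`).
#' @export
#' @examples
#' build_stimulus_set()
#' build_stimulus_set(1, 1, labels = c("polite", "aggressive"))
build_stimulus_set <- function(n_positive = 40, n_negative = 40, labels = NULL) {
  stopifnot(n_positive >= 1, n_negative >= 1)
  n <- n_positive + n_negative
  if (is.null(labels)) {
    labels <- c(
      sprintf("pos%03d", seq_len(n_positive)),
      sprintf("neg%03d", seq_len(n_negative))
    )
  }
  if (length(labels) != n) {
    stop("`labels` must have length n_positive + n_negative (", n, ")")
  }
  if (anyDuplicated(labels)) {
    stop("adjective labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  tibble::tibble(
    adjective = as.character(labels),
    valence = factor(rep(c("positive", "negative"), c(n_positive, n_negative)),
                     levels = c("positive", "negative"))
  )
}

#' Build a feedback-task trial schedule
#'
#' Adjectives are randomly divided over runs, balanced by valence (10 positive
#' and 10 negative per run at the defaults), and each adjective appears twice
#' within its run: once in the self condition and once in the other condition,
#' with self and other trials randomly intermixed.
#'
#' @param stimuli Stimulus set from [build_stimulus_set()].
#' @param n_runs Number of runs; both valence counts must be divisible by it.
#' @param seed Optional integer seed for reproducible allocation. When `NULL`
#'   the current RNG stream is consumed.
#' @return A tibble with one row per trial slot: `run`, `order_index`,
#'   `target` (`"self"`/`"other"`), `adjective`, `valence`.
#' @export
#' @examples
#' sched <- build_schedule(build_stimulus_set(), n_runs = 4, seed = 1)
#' nrow(sched) # 4 runs x 20 adjectives x 2 targets
build_schedule <- function(stimuli, n_runs = 4, seed = NULL) {
  stopifnot(is.data.frame(stimuli), n_runs >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  counts <- table(stimuli$valence)
  if (any(counts %% n_runs != 0)) {
    stop("stimulus counts per valence (", paste(counts, collapse = "/"),
         ") must be divisible by n_runs = ", n_runs)
  }
  per_run <- split(
    seq_len(nrow(stimuli)),
    stimuli$valence
  )
  # randomly allocate adjectives of each valence to runs
  run_of <- integer(nrow(stimuli))
  for (idx in per_run) {
    run_of[sample(idx)] <- rep(seq_len(n_runs), each = length(idx) / n_runs)
  }
  slots <- lapply(seq_len(n_runs), function(r) {
    rows <- which(run_of == r)
    slot <- tibble::tibble(
      run = r,
      target = factor(rep(c("self", "other"), each = length(rows)),
                      levels = c("self", "other")),
      adjective = rep(stimuli$adjective[rows], 2L),
      valence = rep(stimuli$valence[rows], 2L)
    )
    slot <- slot[sample(nrow(slot)), ]
    slot$order_index <- seq_len(nrow(slot))
    slot
  })
  out <- dplyr::bind_rows(slots)
  out[, c("run", "order_index", "target", "adjective", "valence")]
}

#' Feedback-engine parameters
#'
#' Controls how the feedback value shown on each trial is generated from the
#' participant's first rating. With probability `zero_discrepancy_probability`
#' the feedback equals the first rating (a zero-discrepancy trial, excluded
#' from scoring downstream). Otherwise a discrepancy magnitude is drawn
#' uniformly over whole grid steps within `discrepancy_range` (rating units;
#' one grid step is 1/3 of a rating point) and applied toward the desirable
#' direction with probability `desirable_probability` (on the reverse-coded
#' scale), then clamped to the grid range \[1, 8\].
#'
#' The defaults produce realized mean absolute discrepancies of roughly
#' 1.8--2.0 rating points and about 5--6 zero-discrepancy trials per 80
#' (deliberate zero draws plus discrepancies collapsed to zero by clamping
#' at the top of the scale).
#'
#' @param discrepancy_range Length-2 numeric, non-negative, increasing.
#' @param zero_discrepancy_probability,desirable_probability Probabilities.
#' @return A list of class `"feedback_engine_params"`.
#' @export
feedback_engine_params <- function(discrepancy_range = c(0.3, 4.0),
                                   zero_discrepancy_probability = 0.04,
                                   desirable_probability = 0.5) {
  stopifnot(
    length(discrepancy_range) == 2, all(discrepancy_range >= 0),
    discrepancy_range[1] <= discrepancy_range[2],
    zero_discrepancy_probability >= 0, zero_discrepancy_probability <= 1,
    desirable_probability >= 0, desirable_probability <= 1
  )
  steps <- c(max(1L, as.integer(round(discrepancy_range[1] * 3))),
             as.integer(round(discrepancy_range[2] * 3)))
  structure(
    list(
      discrepancy_range = as.numeric(discrepancy_range),
      discrepancy_steps = steps,
      zero_discrepancy_probability = zero_discrepancy_probability,
      desirable_probability = desirable_probability
    ),
    class = "feedback_engine_params"
  )
}

#' Generate feedback values
#'
#' Draws a feedback rating for each trial given the participant's first
#' rating and the trait's valence. Desirability is defined on the
#' reverse-coded scale, so for negative traits the desirable direction is
#' toward lower raw feedback. Values outside the scale are clamped to the
#' grid endpoints (so at extreme first ratings a nominally desirable draw can
#' collapse onto a zero discrepancy).
#'
#' @param first_rating Integer vector of first ratings (1--8), raw scale.
#' @param valence Character/factor vector (`"positive"`/`"negative"`),
#'   recycled to the length of `first_rating`.
#' @param params A [feedback_engine_params()] object.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   consumed.
#' @return Numeric vector of feedback values on [feedback_grid()], raw scale.
#' @export
#' @examples
#' generate_feedback(c(5, 5, 2), c("positive", "negative", "positive"),
#'                   feedback_engine_params(), seed = 1)
generate_feedback <- function(first_rating, valence,
                              params = feedback_engine_params(),
                              seed = NULL) {
  stopifnot(inherits(params, "feedback_engine_params"))
  check_rating(first_rating, "first_rating")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(first_rating)
  valence <- rep_len(as.character(valence), n)
  k_first <- 3L * as.integer(first_rating)
  zero <- stats::runif(n) < params$zero_discrepancy_probability
  steps <- params$discrepancy_steps
  mag <- sample_int_range(steps[1], steps[2], n)
  desirable <- stats::runif(n) < params$desirable_probability
  # sign on the reverse-coded scale, mapped back to the raw scale
  sign_recoded <- ifelse(desirable, 1L, -1L)
  sign_raw <- ifelse(valence == "negative", -sign_recoded, sign_recoded)
  k <- ifelse(zero, k_first, pmin(pmax(k_first + sign_raw * mag, 3L), 24L))
  grid_value(k)
}

# uniform over the integers lo..hi, vectorized
sample_int_range <- function(lo, hi, n) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

check_rating <- function(x, what) {
  bad <- !is.na(x) & (x < 1 | x > 8 | x != round(x))
  if (any(bad)) {
    stop("`", what, "` must be integer ratings in 1..8; offending values: ",
         paste(utils::head(unique(x[bad]), 5), collapse = ", "))
  }
  invisible(x)
}
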