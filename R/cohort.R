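#' Agent (participant-behavior) parameters
#'
#' The generative model of a participant is linear partial adjustment with
#' Gaussian noise and Likert rounding: on the reverse-coded scale the second
#' rating is `round(first + alpha * (feedback - first) + noise)`, clamped to
#' 1..8, where `alpha` is the update fraction for the trial's
#' (target x desirability) cell. Its sufficient statistic under the scoring
#' pipeline is exactly the relative mean update, which is what makes
#' parameter recovery a meaningful validation.
#'
#' `alpha` entries are latent logit-scale locations expressed as
#' probabilities: per-participant cell alphas are drawn on the logit scale
#' (see [cohort_config()] for the heterogeneity and covariate links), so with
#' heterogeneity the population mean cell score is pulled slightly toward
#' 0.5. The defaults are calibrated so that a default cohort reproduces the
#' reference cell means (relative updates of roughly 0.4 after desirable and
#' 0.1 after undesirable feedback, other slightly above self for undesirable
#' feedback).
#'
#' @param alpha Named numeric vector in \[0, 1\] with entries
#'   `self_desirable`, `self_undesirable`, `other_desirable`,
#'   `other_undesirable`.
#' @param alpha_interdependence_slope Additive effect of interdependence
#'   (centered at the cohort reference) on the logit of every cell alpha.
#' @param update_noise_sd Trial-level SD of the update noise, Likert units.
#' @param first_rating_mean_self,first_rating_mean_other Population means of
#'   first ratings on the reverse-coded scale.
#' @param first_rating_sd Trial-level SD of first ratings, Likert units.
#' @param memory_noise_sd_self,memory_noise_sd_other SD of recollection
#'   noise, rating units (self below other by default: own feedback is
#'   remembered more accurately).
#' @param response_missing_probability Probability that any single response
#'   (first rating, second rating, recollection) is missing.
#' @return A list of class `"agent_params"`.
#' @export
agent_params <- function(alpha = c(self_desirable = 0.465,
                                   self_undesirable = 0.03,
                                   other_desirable = 0.475,
                                   other_undesirable = 0.055),
                         alpha_interdependence_slope = 0.27,
                         update_noise_sd = 1.6,
                         first_rating_mean_self = 5.6,
                         first_rating_mean_other = 5.4,
                         first_rating_sd = 1.3,
                         memory_noise_sd_self = 2.3,
                         memory_noise_sd_other = 2.65,
                         response_missing_probability = 0.02) {
  alpha <- alpha[c("self_desirable", "self_undesirable",
                   "other_desirable", "other_undesirable")]
  stopifnot(
    !anyNA(alpha), all(alpha >= 0), all(alpha <= 1),
    update_noise_sd >= 0, first_rating_sd >= 0,
    memory_noise_sd_self >= 0, memory_noise_sd_other >= 0,
    response_missing_probability >= 0, response_missing_probability <= 1
  )
  structure(
    list(
      alpha = alpha,
      alpha_interdependence_slope = alpha_interdependence_slope,
      update_noise_sd = update_noise_sd,
      first_rating_mean_self = first_rating_mean_self,
      first_rating_mean_other = first_rating_mean_other,
      first_rating_sd = first_rating_sd,
      memory_noise_sd_self = memory_noise_sd_self,
      memory_noise_sd_other = memory_noise_sd_other,
      response_missing_probability = response_missing_probability
    ),
    class = "agent_params"
  )
}

#' Cohort configuration
#'
#' Group structure, questionnaire-covariate distributions, and the
#' between-participant heterogeneity of the update fractions. The defaults
#' encode the reference study conditions: four groups (culture x place) of
#' sizes 27/24/28/25 whose covariate means and SDs match the reference
#' participant table, Chinese more interdependent than Germans, Germans more
#' independent and higher in self-esteem, self-esteem correlated with
#' independence but not interdependence, and update fractions that increase
#' with interdependence (plus a residual culture offset), so that
#' interdependence correlates with overall updating across the cohort.
#'
#' Per-participant heterogeneity on the logit of alpha has a component shared
#' across all four cells (`alpha_logit_sd_shared`, a stable conformity trait)
#' and a larger cell-specific component (`alpha_logit_sd_cell`), consistent
#' with the modest cross-cell correlation of observed condition scores.
#'
#' @param group_sizes Named integer vector over
#'   `German_Berlin`, `German_Beijing`, `Chinese_Berlin`, `Chinese_Beijing`.
#' @param covariates Data frame of per-group truncated-normal parameters
#'   (see `default_covariate_table()`); must have columns `culture`, `place`,
#'   `covariate`, `mean`, `sd`, `lower`, `upper`.
#' @param esteem_independence_cor Target correlation between self-esteem and
#'   independence.
#' @param group_alpha_offsets Named numeric vector (`German`, `Chinese`):
#'   additive culture offsets on the logit of alpha beyond the
#'   interdependence link.
#' @param alpha_logit_sd_shared,alpha_logit_sd_cell SDs of the shared and
#'   cell-specific participant effects on logit(alpha).
#' @param first_rating_mean_sd Between-participant SD of the personal mean
#'   first rating (applied to self and other independently), Likert units.
#' @param interdependence_reference Centering constant for the
#'   interdependence link (the default-cohort population mean).
#' @param rng_seed Default seed used by [simulate_cohort_trials()].
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(group_sizes = c(German_Berlin = 27,
                                          German_Beijing = 24,
                                          Chinese_Berlin = 28,
                                          Chinese_Beijing = 25),
                          covariates = default_covariate_table(),
                          esteem_independence_cor = 0.32,
                          group_alpha_offsets = c(German = -0.16,
                                                  Chinese = 0.16),
                          alpha_logit_sd_shared = 0.22,
                          alpha_logit_sd_cell = 1.1,
                          first_rating_mean_sd = 0.55,
                          interdependence_reference = 3.57,
                          rng_seed = 1L) {
  stopifnot(
    all(group_sizes >= 0),
    all(c("German_Berlin", "German_Beijing",
          "Chinese_Berlin", "Chinese_Beijing") %in% names(group_sizes)),
    is.data.frame(covariates),
    abs(esteem_independence_cor) <= 1,
    alpha_logit_sd_shared >= 0, alpha_logit_sd_cell >= 0,
    first_rating_mean_sd >= 0
  )
  structure(
    list(
      group_sizes = group_sizes,
      covariates = covariates,
      esteem_independence_cor = esteem_independence_cor,
      group_alpha_offsets = group_alpha_offsets,
      alpha_logit_sd_shared = alpha_logit_sd_shared,
      alpha_logit_sd_cell = alpha_logit_sd_cell,
      first_rating_mean_sd = first_rating_mean_sd,
      interdependence_reference = interdependence_reference,
      rng_seed = as.integer(rng_seed)
    ),
    class = "cohort_config"
  )
}

#' Default questionnaire-covariate distributions
#'
#' Per-group truncated-normal parameters for the four questionnaire scores:
#' interdependent and independent self-construal (1--7 scale means),
#' Rosenberg self-esteem (10--40), and perceived similarity to the other
#' person (1--8). Means and SDs are the reference study's group statistics.
#'
#' @return A tibble with columns `culture`, `place`, `covariate`, `mean`,
#'   `sd`, `lower`, `upper`.
#' @export
default_covariate_table <- function() {
  grp <- function(culture, place, inter, indep, esteem, simil) {
    tibble::tibble(
      culture = culture, place = place,
      covariate = c("interdependence", "independence",
                    "self_esteem", "perceived_similarity"),
      mean = c(inter[1], indep[1], esteem[1], simil[1]),
      sd = c(inter[2], indep[2], esteem[2], simil[2]),
      lower = c(1, 1, 10, 1),
      upper = c(7, 7, 40, 8)
    )
  }
  dplyr::bind_rows(
    grp("German", "Berlin", c(3.10, 0.53), c(3.72, 0.30), c(23.0, 5.35), c(3.67, 1.47)),
    grp("German", "Beijing", c(3.58, 0.38), c(3.85, 0.32), c(23.6, 3.57), c(4.06, 1.63)),
    grp("Chinese", "Berlin", c(3.71, 0.38), c(3.58, 0.36), c(20.6, 5.40), c(3.79, 1.77)),
    grp("Chinese", "Beijing", c(3.89, 0.41), c(3.47, 0.43), c(21.7, 4.36), c(4.24, 1.13))
  )
}

#' Simulate a participant table
#'
#' Draws questionnaire covariates from per-group truncated normals.
#' Self-esteem is generated with the configured correlation to independence.
#'
#' @param config A [cohort_config()].
#' @param seed Optional seed; when `NULL` the current RNG stream is consumed.
#' @return A tibble with columns `participant_id`, `culture`, `place`,
#'   `interdependence`, `independence`, `self_esteem`,
#'   `perceived_similarity`.
#' @export
simulate_participants <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) withr::local_seed(seed)
  groups <- strsplit(names(config$group_sizes), "_", fixed = TRUE)
  out <- vector("list", length(groups))
  id0 <- 0L
  for (i in seq_along(groups)) {
    culture <- groups[[i]][1]
    place <- groups[[i]][2]
    n <- as.integer(config$group_sizes[i])
    pars <- config$covariates[config$covariates$culture == culture &
                                config$covariates$place == place, ]
    if (nrow(pars) == 0) stop("no covariate parameters for group ", culture, "_", place)
    p <- function(cv, field) pars[[field]][pars$covariate == cv]
    inter <- rtrunc_norm(n, p("interdependence", "mean"), p("interdependence", "sd"),
                         p("interdependence", "lower"), p("interdependence", "upper"))
    indep <- rtrunc_norm(n, p("independence", "mean"), p("independence", "sd"),
                         p("independence", "lower"), p("independence", "upper"))
    rho <- config$esteem_independence_cor
    z_ind <- if (p("independence", "sd") > 0) {
      (indep - p("independence", "mean")) / p("independence", "sd")
    } else {
      rep(0, n)
    }
    esteem <- p("self_esteem", "mean") +
      p("self_esteem", "sd") * (rho * z_ind + sqrt(1 - rho^2) * stats::rnorm(n))
    esteem <- pmin(pmax(esteem, p("self_esteem", "lower")), p("self_esteem", "upper"))
    simil <- rtrunc_norm(n, p("perceived_similarity", "mean"),
                         p("perceived_similarity", "sd"),
                         p("perceived_similarity", "lower"),
                         p("perceived_similarity", "upper"))
    out[[i]] <- tibble::tibble(
      participant_id = sprintf("P%03d", id0 + seq_len(n)),
      culture = factor(culture, levels = c("German", "Chinese")),
      place = factor(place, levels = c("Berlin", "Beijing")),
      interdependence = inter,
      independence = indep,
      self_esteem = esteem,
      perceived_similarity = simil
    )
    id0 <- id0 + n
  }
  dplyr::bind_rows(out)
}

#' Simulate first ratings
#'
#' Draws first ratings on the reverse-coded scale as a rounded, clamped
#' normal around the target-specific mean (self above other by default: a
#' positivity bias toward the self).
#'
#' @param agent An [agent_params()] object.
#' @param target `"self"` or `"other"`, recycled to `n`.
#' @param n Number of draws.
#' @param mean Optional per-draw means overriding the agent's population
#'   means (used for participant-specific rating tendencies).
#' @return Integer vector of ratings 1..8 (reverse-coded scale).
#' @export
simulate_first_rating <- function(agent = agent_params(), target = "self",
                                  n = length(target), mean = NULL) {
  stopifnot(inherits(agent, "agent_params"))
  target <- rep_len(as.character(target), n)
  if (is.null(mean)) {
    mean <- ifelse(target == "self",
                   agent$first_rating_mean_self,
                   agent$first_rating_mean_other)
  }
  clamp_likert(round(stats::rnorm(n, mean, agent$first_rating_sd)))
}

#' Simulate second ratings (partial updating toward feedback)
#'
#' On the reverse-coded scale:
#' `second = round(first + alpha * (feedback - first) + noise)`, clamped to
#' 1..8. `alpha` is looked up per trial from the agent's
#' (target x desirability) map unless given explicitly.
#'
#' @param agent An [agent_params()] object.
#' @param first Integer first ratings (reverse-coded scale).
#' @param feedback Feedback values (reverse-coded scale).
#' @param target,desirability Character vectors, recycled.
#' @param alpha Optional numeric vector of per-trial update fractions
#'   overriding the agent map.
#' @return Integer vector of second ratings 1..8 (reverse-coded scale).
#' @export
simulate_update <- function(agent = agent_params(), first, feedback,
                            target = "self", desirability = "desirable",
                            alpha = NULL) {
  stopifnot(inherits(agent, "agent_params"))
  n <- length(first)
  if (is.null(alpha)) {
    cell <- paste(rep_len(as.character(target), n),
                  rep_len(as.character(desirability), n), sep = "_")
    alpha <- unname(agent$alpha[cell])
    alpha[is.na(alpha)] <- 0 # neutral trials: feedback == first anyway
  }
  raw <- first + alpha * (feedback - first) +
    stats::rnorm(n, 0, agent$update_noise_sd)
  clamp_likert(round(raw))
}

#' Simulate feedback recollections
#'
#' Adds target-specific Gaussian noise to the feedback value and snaps the
#' result back to the feedback grid (recollections are entered in the same
#' one-decimal format as the feedback itself).
#'
#' @param agent An [agent_params()] object.
#' @param feedback Feedback values (raw scale).
#' @param target `"self"` or `"other"`, recycled.
#' @return Numeric vector of grid values.
#' @export
simulate_recollection <- function(agent = agent_params(), feedback,
                                  target = "self") {
  stopifnot(inherits(agent, "agent_params"))
  n <- length(feedback)
  target <- rep_len(as.character(target), n)
  sd <- ifelse(target == "self",
               agent$memory_noise_sd_self, agent$memory_noise_sd_other)
  snap_to_feedback_grid(feedback + stats::rnorm(n, 0, sd))
}

#' Simulate a full cohort trial log
#'
#' Composes the paradigm end to end: participants and covariates, a
#' per-participant run schedule, first ratings, engine-generated feedback,
#' desirability-dependent partial updating, feedback recollection, and
#' missing-response injection. Fully deterministic under a fixed seed.
#'
#' @param config A [cohort_config()].
#' @param engine A [feedback_engine_params()].
#' @param agent An [agent_params()].
#' @param stimuli Stimulus set (default 40 positive + 40 negative).
#' @param n_runs Number of runs (default 4).
#' @param seed Integer seed (defaults to `config$rng_seed`).
#' @return A list with elements `trials` (one row per trial; raw-scale
#'   columns `participant_id`, `run`, `order_index`, `target`, `adjective`,
#'   `valence`, `first_rating`, `feedback`, `second_rating`, `recollection`)
#'   and `participants` (the covariate table).
#' @export
#' @examples
#' sim <- simulate_cohort_trials(seed = 42)
#' nrow(sim$trials) / nrow(sim$participants) # 160 trials per participant
simulate_cohort_trials <- function(config = cohort_config(),
                                   engine = feedback_engine_params(),
                                   agent = agent_params(),
                                   stimuli = build_stimulus_set(),
                                   n_runs = 4,
                                   seed = config$rng_seed) {
  stopifnot(inherits(config, "cohort_config"),
            inherits(engine, "feedback_engine_params"),
            inherits(agent, "agent_params"))
  withr::local_seed(seed)

  participants <- simulate_participants(config)
  n_p <- nrow(participants)
  if (n_p == 0) {
    stop("cohort has zero participants")
  }

  # participant-level latent parameters
  lat <- latent_agents(participants, config, agent)

  # per-participant schedules
  trials <- dplyr::bind_rows(lapply(seq_len(n_p), function(i) {
    s <- build_schedule(stimuli, n_runs = n_runs)
    s$participant_id <- participants$participant_id[i]
    s
  }))
  trials <- dplyr::left_join(trials, lat, by = "participant_id")
  n <- nrow(trials)
  is_self <- trials$target == "self"

  # first ratings on the reverse-coded scale
  first_rec <- simulate_first_rating(
    agent, trials$target, n,
    mean = ifelse(is_self, trials$mu_first_self, trials$mu_first_other)
  )

  # feedback on the reverse-coded scale: desirability is defined there, so
  # the engine is driven with "positive" valence and recoded first ratings
  fb_rec <- generate_feedback(first_rec, "positive", engine)

  desir <- classify_desirability(first_rec, fb_rec)
  alpha <- dplyr::case_when(
    is_self & desir == "desirable" ~ trials$alpha_self_desirable,
    is_self & desir == "undesirable" ~ trials$alpha_self_undesirable,
    !is_self & desir == "desirable" ~ trials$alpha_other_desirable,
    !is_self & desir == "undesirable" ~ trials$alpha_other_undesirable,
    TRUE ~ 0 # neutral: feedback == first, the update term vanishes
  )
  second_rec <- simulate_update(agent, first_rec, fb_rec,
                                alpha = alpha)
  rec_rec <- simulate_recollection(agent, fb_rec, trials$target)

  # missing-response injection
  p_miss <- agent$response_missing_probability
  first_rec[stats::runif(n) < p_miss] <- NA_integer_
  second_rec[stats::runif(n) < p_miss] <- NA_integer_
  rec_rec[stats::runif(n) < p_miss] <- NA_real_

  # back to the raw scale for negative traits
  neg <- trials$valence == "negative"
  back <- function(x) ifelse(neg, 9 - x, x)
  out <- tibble::tibble(
    participant_id = trials$participant_id,
    run = trials$run,
    order_index = trials$order_index,
    target = trials$target,
    adjective = trials$adjective,
    valence = trials$valence,
    first_rating = as.integer(back(first_rec)),
    feedback = back(fb_rec),
    second_rating = as.integer(back(second_rec)),
    recollection = back(rec_rec)
  )
  list(trials = out, participants = participants)
}

# Draw participant-level latent parameters: cell alphas on the logit scale
# (base + culture offset + interdependence link + shared and cell-specific
# heterogeneity) and personal mean first ratings.
latent_agents <- function(participants, config, agent) {
  n <- nrow(participants)
  base <- stats::qlogis(pmin(pmax(agent$alpha, 1e-6), 1 - 1e-6))
  offs <- config$group_alpha_offsets[as.character(participants$culture)]
  link <- agent$alpha_interdependence_slope *
    (participants$interdependence - config$interdependence_reference)
  u <- stats::rnorm(n, 0, config$alpha_logit_sd_shared)
  cells <- names(base)
  out <- tibble::tibble(participant_id = participants$participant_id)
  for (cell in cells) {
    v <- stats::rnorm(n, 0, config$alpha_logit_sd_cell)
    out[[paste0("alpha_", cell)]] <- stats::plogis(base[[cell]] + offs + link + u + v)
  }
  out$mu_first_self <- agent$first_rating_mean_self +
    stats::rnorm(n, 0, config$first_rating_mean_sd)
  out$mu_first_other <- agent$first_rating_mean_other +
    stats::rnorm(n, 0, config$first_rating_mean_sd)
  out
}

clamp_likert <- function(x) {
  as.integer(pmin(pmax(x, 1), 8))
}

# truncated normal via inverse-CDF; exact and vectorized
rtrunc_norm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}
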