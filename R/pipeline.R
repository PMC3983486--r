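#' Default pipeline configuration
#'
#' Bundles the cohort, feedback-engine, and agent parameter sets with a seed
#' into one object that [run_simulate()] consumes and that round-trips
#' through JSON via [read_pipeline_config()] / [write_pipeline_config()].
#' The defaults reproduce the calibrated reference simulation.
#'
#' @param cohort A [cohort_config()].
#' @param engine A [feedback_engine_params()].
#' @param agent An [agent_params()].
#' @param seed Integer seed for the simulation.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            engine = feedback_engine_params(),
                            agent = agent_params(),
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            inherits(engine, "feedback_engine_params"),
            inherits(agent, "agent_params"))
  structure(
    list(cohort = cohort, engine = engine, agent = agent,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path JSON file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  plain <- list(
    seed = config$seed,
    cohort = unclass(config$cohort),
    engine = unclass(config$engine)[c("discrepancy_range",
                                      "zero_discrepancy_probability",
                                      "desirable_probability")],
    agent = unclass(config$agent)
  )
  plain$cohort$group_sizes <- as.list(config$cohort$group_sizes)
  plain$cohort$group_alpha_offsets <- as.list(config$cohort$group_alpha_offsets)
  plain$agent$alpha <- as.list(config$agent$alpha)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` (for writing).
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  plain <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cohort_args <- plain$cohort
  if (!is.null(cohort_args$group_sizes)) {
    cohort_args$group_sizes <- unlist(cohort_args$group_sizes)
  }
  if (!is.null(cohort_args$group_alpha_offsets)) {
    cohort_args$group_alpha_offsets <- unlist(cohort_args$group_alpha_offsets)
  }
  if (!is.null(cohort_args$covariates)) {
    cohort_args$covariates <- tibble::as_tibble(cohort_args$covariates)
  }
  agent_args <- plain$agent
  if (!is.null(agent_args$alpha)) agent_args$alpha <- unlist(agent_args$alpha)
  pipeline_config(
    cohort = do.call(cohort_config, cohort_args %||% list()),
    engine = do.call(feedback_engine_params, plain$engine %||% list()),
    agent = do.call(agent_params, agent_args %||% list()),
    seed = plain$seed %||% 1L
  )
}

#' Simulate a cohort and write the canonical tables
#'
#' Runs [simulate_cohort_trials()] under the config and writes
#' `trials.csv`, `participants.csv`, `config.json` and `manifest.txt` into
#' `out_dir`. Identical config + seed yields byte-identical data files.
#'
#' @param config A [pipeline_config()] (or path to its JSON file).
#' @param out_dir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulate <- function(config = pipeline_config(), out_dir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort_trials(
    config = config$cohort, engine = config$engine, agent = config$agent,
    seed = config$seed
  )
  paths <- c(
    trials = file.path(out_dir, "trials.csv"),
    participants = file.path(out_dir, "participants.csv"),
    config = file.path(out_dir, "config.json"),
    manifest = file.path(out_dir, "manifest.txt")
  )
  write_trial_log(sim$trials, paths[["trials"]])
  write_participants(sim$participants, paths[["participants"]])
  write_pipeline_config(config, paths[["config"]])
  write_run_manifest(
    paths[["manifest"]],
    config_path = paths[["config"]],
    seed = config$seed,
    tables = list(trials = sim$trials, participants = sim$participants),
    data_paths = paths[c("trials", "participants")]
  )
  invisible(paths)
}

#' Score a trial log from file
#'
#' @param trials_path Path to a trial-log CSV.
#' @param out_path Path for the condition-score CSV.
#' @return Invisibly, the score tibble.
#' @export
run_score <- function(trials_path, out_path) {
  trials <- read_trial_log(trials_path)
  scores <- score_trials(trials)
  write_scores(scores, out_path)
  invisible(scores)
}

#' Analyze condition scores
#'
#' Reproduces the factorial and correlational analysis battery on a scored
#' cohort: the 2 (target) x 2 (desirability) x 2 (culture) x 2 (place)
#' split-plot ANOVA on relative absolute mean updates (and its companions on
#' feedback discrepancies and memory errors), the correlation of
#' interdependence with overall updating (with Fisher-z CI), its comparison
#' between cultures (Fisher z), the dependent-correlation comparison of
#' self-esteem with independence vs interdependence (Williams t), and the
#' hierarchical regression of overall updating on culture then
#' interdependence (F-change).
#'
#' @param scores Condition scores from [score_trials()] (or a file path).
#' @param participants Participant table (or a file path).
#' @return A list of class `"cohort_analysis"`: `updating_anova`,
#'   `discrepancy_anova`, `memory_anova`, `correlations` (tibble),
#'   `fisher_z_culture`, `williams_esteem`, `f_change_interdependence`,
#'   `n_participants_anova`.
#' @export
analyze_scores <- function(scores, participants) {
  if (is.character(scores)) scores <- read_scores(scores)
  if (is.character(participants)) participants <- read_participants(participants)
  d <- dplyr::left_join(scores, participants, by = "participant_id")

  updating <- split_plot_anova(
    d, dv = "relative_absolute_mean_update", subject = "participant_id",
    within = c("target", "desirability"), between = c("culture", "place")
  )
  discrepancy <- split_plot_anova(
    d, dv = "mean_feedback_discrepancy", subject = "participant_id",
    within = c("target", "desirability"), between = c("culture", "place")
  )
  memory <- split_plot_anova(
    d, dv = "mean_absolute_memory_error", subject = "participant_id",
    within = c("target", "desirability"), between = c("culture", "place")
  )

  ov <- overall_updating(scores)
  ovp <- dplyr::inner_join(ov, participants, by = "participant_id")
  ovp <- ovp[stats::complete.cases(ovp$overall_update, ovp$interdependence), ]
  corr_inter <- pearson_with_ci(ovp$interdependence, ovp$overall_update)
  corr_indep <- pearson_with_ci(ovp$independence, ovp$overall_update)
  corr_esteem <- pearson_with_ci(ovp$self_esteem, ovp$overall_update)
  correlations <- dplyr::bind_rows(
    dplyr::mutate(corr_inter, predictor = "interdependence", .before = 1),
    dplyr::mutate(corr_indep, predictor = "independence", .before = 1),
    dplyr::mutate(corr_esteem, predictor = "self_esteem", .before = 1)
  )

  gz <- lapply(split(ovp, ovp$culture), function(g) {
    pearson_with_ci(g$interdependence, g$overall_update)
  })
  fisher_cult <- fisher_z_independent(gz$German$r, gz$German$n,
                                      gz$Chinese$r, gz$Chinese$n)

  r_ei <- stats::cor(ovp$self_esteem, ovp$independence)
  r_et <- stats::cor(ovp$self_esteem, ovp$interdependence)
  r_it <- stats::cor(ovp$independence, ovp$interdependence)
  williams <- hotelling_williams_t(r_ei, r_et, r_it, nrow(ovp))

  f_change <- hierarchical_f_change(
    ovp, response = "overall_update",
    base_terms = "culture", added_terms = "interdependence"
  )

  structure(
    list(
      updating_anova = updating,
      discrepancy_anova = discrepancy,
      memory_anova = memory,
      correlations = correlations,
      fisher_z_culture = fisher_cult,
      williams_esteem = williams,
      f_change_interdependence = f_change,
      n_participants_anova = length(unique(d$participant_id))
    ),
    class = "cohort_analysis"
  )
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis (", x$n_participants_anova, " participants)\n\n", sep = "")
  cat("Split-plot ANOVA on relative absolute mean updates:\n")
  print(as.data.frame(x$updating_anova), digits = 3)
  cat("\nCorrelations with overall updating:\n")
  print(as.data.frame(x$correlations), digits = 3)
  cat("\nInterdependence-updating correlation, German vs Chinese: z = ",
      round(x$fisher_z_culture$z, 2), ", p = ",
      signif(x$fisher_z_culture$p, 3), "\n", sep = "")
  cat("Self-esteem with independence vs interdependence (Williams): t(",
      x$williams_esteem$df, ") = ", round(x$williams_esteem$t, 2),
      ", p = ", signif(x$williams_esteem$p, 3), "\n", sep = "")
  cat("F-change, interdependence beyond culture: F(",
      x$f_change_interdependence$df_num, ", ",
      x$f_change_interdependence$df_den, ") = ",
      round(x$f_change_interdependence$F_change, 2), ", p = ",
      signif(x$f_change_interdependence$p, 3), "\n", sep = "")
  invisible(x)
}

#' Run the analysis step on files
#'
#' Writes the updating-ANOVA effects table as delimited text and the full
#' analysis battery as a JSON report keyed by effect name.
#'
#' @param scores_path,participants_path Input CSV paths.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the [analyze_scores()] result.
#' @export
run_analyze <- function(scores_path, participants_path, out_dir) {
  res <- analyze_scores(scores_path, participants_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  effects <- dplyr::mutate(
    res$updating_anova,
    dplyr::across(dplyr::where(is.double), ~ round(.x, 6))
  )
  readr::write_csv(effects, file.path(out_dir, "effects.csv"), progress = FALSE)
  report <- list(
    updating_anova = stats::setNames(
      lapply(seq_len(nrow(res$updating_anova)), function(i) {
        as.list(res$updating_anova[i, c("df_num", "df_den", "F", "p",
                                        "partial_eta_sq")])
      }),
      res$updating_anova$effect
    ),
    correlations = res$correlations,
    fisher_z_culture = res$fisher_z_culture,
    williams_esteem = res$williams_esteem,
    f_change_interdependence = res$f_change_interdependence,
    n_participants = res$n_participants_anova
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(res)
}

#' Parameter-recovery experiment
#'
#' Simulates homogeneous cohorts whose every (target x desirability) update
#' fraction equals a known `alpha`, scores them with the standard pipeline,
#' and summarises how well the relative absolute mean updates recover the
#' generating value. Heterogeneity, covariate links, zero-discrepancy
#' feedback and missing responses are switched off so that the estimate
#' isolates the scoring chain itself (trial noise and Likert rounding
#' remain).
#'
#' @param alphas Generating update fractions.
#' @param n_participants Cohort size per alpha.
#' @param update_noise_sd Trial-level update noise SD, Likert units.
#' @param seed Integer seed.
#' @return A tibble with one row per alpha x cell: `alpha_true`, `target`,
#'   `desirability`, `mean_recovered`, `bias`, plus a pooled row per alpha
#'   (`target = "pooled"`).
#' @export
recover_alpha <- function(alphas = c(0, 0.25, 0.5, 0.75, 1),
                          n_participants = 100,
                          update_noise_sd = 0.5,
                          seed = 1L) {
  withr::local_seed(seed)
  out <- lapply(alphas, function(a) {
    cfg <- cohort_config(
      group_sizes = c(German_Berlin = n_participants, German_Beijing = 0,
                      Chinese_Berlin = 0, Chinese_Beijing = 0),
      group_alpha_offsets = c(German = 0, Chinese = 0),
      alpha_logit_sd_shared = 0,
      alpha_logit_sd_cell = 0,
      first_rating_mean_sd = 0
    )
    ag <- agent_params(
      alpha = c(self_desirable = a, self_undesirable = a,
                other_desirable = a, other_undesirable = a),
      alpha_interdependence_slope = 0,
      update_noise_sd = update_noise_sd,
      response_missing_probability = 0
    )
    en <- feedback_engine_params(zero_discrepancy_probability = 0)
    sim <- simulate_cohort_trials(cfg, en, ag,
                                  seed = sample.int(.Machine$integer.max, 1))
    sc <- score_trials(sim$trials)
    cells <- sc |>
      dplyr::group_by(.data$target, .data$desirability) |>
      dplyr::summarise(
        mean_recovered = mean(.data$relative_absolute_mean_update, na.rm = TRUE),
        .groups = "drop"
      )
    pooled <- tibble::tibble(
      target = "pooled", desirability = "pooled",
      mean_recovered = mean(sc$relative_absolute_mean_update, na.rm = TRUE)
    )
    cells$target <- as.character(cells$target)
    cells$desirability <- as.character(cells$desirability)
    dplyr::bind_rows(cells, pooled) |>
      dplyr::mutate(alpha_true = a, bias = .data$mean_recovered - a,
                    .before = 1)
  })
  dplyr::bind_rows(out)
}

#' Run the parameter-recovery step and write its summary
#'
#' Repeats [recover_alpha()] over `n_reps` seeds and writes a bias/RMSE
#' summary per generating alpha.
#'
#' @param out_path Output CSV path.
#' @param alphas Generating update fractions.
#' @param n_participants Cohort size per alpha and repetition.
#' @param n_reps Number of seeded repetitions.
#' @param update_noise_sd Trial-level update noise SD.
#' @param seed Base seed.
#' @return Invisibly, the summary tibble.
#' @export
run_recover <- function(out_path, alphas = c(0, 0.25, 0.5, 0.75, 1),
                        n_participants = 100, n_reps = 3,
                        update_noise_sd = 0.5, seed = 1L) {
  reps <- lapply(seq_len(n_reps), function(i) {
    recover_alpha(alphas, n_participants, update_noise_sd,
                  seed = seed + i - 1L) |>
      dplyr::mutate(rep = i)
  })
  summary <- dplyr::bind_rows(reps) |>
    dplyr::filter(.data$target == "pooled") |>
    dplyr::group_by(.data$alpha_true) |>
    dplyr::summarise(
      mean_recovered = mean(.data$mean_recovered),
      bias = mean(.data$bias),
      rmse = sqrt(mean(.data$bias^2)),
      n_reps = dplyr::n(),
      .groups = "drop"
    )
  readr::write_csv(
    dplyr::mutate(summary,
                  dplyr::across(dplyr::where(is.double), ~ round(.x, 6))),
    out_path, progress = FALSE
  )
  invisible(summary)
}

# manifest: plain-text key/value lines; identical config+seed => identical
# data hashes (timestamps excluded from any hashing)
write_run_manifest <- function(path, config_path, seed, tables, data_paths) {
  lines <- c(
    paste0("package_version: ",
           as.character(utils::packageVersion("conformity"))),
    paste0("seed: ", seed),
    paste0("config_md5: ", unname(tools::md5sum(config_path))),
    paste0("created: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(tables), function(nm) {
      paste0("rows_", nm, ": ", nrow(tables[[nm]]))
    }, ""),
    vapply(names(data_paths), function(nm) {
      paste0("md5_", nm, ": ", unname(tools::md5sum(data_paths[[nm]])))
    }, "")
  )
  tmp <- paste0(path, ".tmp")
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
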