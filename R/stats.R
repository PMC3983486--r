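#' Split-plot (mixed) factorial ANOVA with partial eta-squared
#'
#' Factorial ANOVA with any number of two-level within-subject factors and
#' crossed between-subject factors (possibly unbalanced), the design used for
#' condition scores: e.g. 2 (target) x 2 (desirability) within by
#' 2 (culture) x 2 (place) between.
#'
#' Each within-subject effect (including its interactions with the between
#' factors) is tested against its own subject-by-effect error stratum: the
#' per-participant contrast score for that effect is computed across the
#' within cells and submitted to a between-subjects linear model. Between
#' effects are tested on the per-participant cell means. Sums of squares are
#' Type III with sum-to-zero contrasts (the between groups may be
#' unbalanced); with all within factors at two levels no sphericity
#' correction is needed. Participants with any missing within cell are
#' dropped listwise. Partial eta-squared is
#' `SS_effect / (SS_effect + SS_error)`.
#'
#' @param data Long data frame: one row per participant x within-cell.
#' @param dv Name of the response column.
#' @param subject Name of the participant-identifier column.
#' @param within Character vector of within-subject factor columns (each must
#'   have exactly two levels); may be empty.
#' @param between Character vector of between-subject factor columns; may be
#'   empty.
#' @param covariates Optional character vector of numeric participant-level
#'   covariate columns entered additively into every between-subjects model
#'   (e.g. an age robustness check).
#' @return A tibble with columns `effect`, `df_num`, `df_den`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
#' @examples
#' sim <- simulate_cohort_trials(seed = 7)
#' sc <- score_trials(sim$trials)
#' sc <- merge(sc, sim$participants, by = "participant_id")
#' split_plot_anova(sc, dv = "relative_absolute_mean_update",
#'                  subject = "participant_id",
#'                  within = c("target", "desirability"),
#'                  between = c("culture", "place"))
split_plot_anova <- function(data, dv, subject, within = character(),
                             between = character(), covariates = NULL) {
  data <- as.data.frame(data)
  for (col in c(dv, subject, within, between, covariates)) {
    if (!col %in% names(data)) stop("column not found: ", col)
  }
  for (w in within) {
    data[[w]] <- droplevels(factor(data[[w]]))
    if (nlevels(data[[w]]) != 2) {
      stop("within factor `", w, "` must have exactly 2 levels ",
           "(has ", nlevels(data[[w]]), "); higher-order within designs ",
           "are not supported")
    }
  }
  for (b in between) data[[b]] <- droplevels(factor(data[[b]]))

  # one row per subject per within cell -> wide matrix of cell values
  if (length(within)) {
    cell_id <- interaction(data[within], drop = FALSE, sep = ".")
    wide <- stats::reshape(
      data.frame(subject = data[[subject]], cell = cell_id, y = data[[dv]]),
      idvar = "subject", timevar = "cell", direction = "wide"
    )
    cell_cols <- setdiff(names(wide), "subject")
    cell_levels <- sub("^y\\.", "", cell_cols)
    y_mat <- as.matrix(wide[, cell_cols, drop = FALSE])
  } else {
    wide <- data.frame(subject = data[[subject]], y = data[[dv]])
    if (anyDuplicated(wide$subject)) {
      wide <- stats::aggregate(y ~ subject, wide, mean)
    }
    y_mat <- matrix(wide$y, ncol = 1)
    cell_levels <- "all"
  }
  meta_cols <- unique(c(between, covariates))
  meta <- unique(data[, c(subject, meta_cols), drop = FALSE])
  if (anyDuplicated(meta[[subject]])) {
    stop("between factors/covariates vary within subject")
  }
  wide <- cbind(wide,
                meta[match(wide$subject, meta[[subject]]), meta_cols,
                     drop = FALSE])
  keep <- stats::complete.cases(wide)
  wide <- wide[keep, , drop = FALSE]
  y_mat <- y_mat[keep, , drop = FALSE]
  if (length(between)) {
    tab <- table(wide[between])
    if (any(tab == 0)) stop("empty between-subject cell(s): design not estimable")
  }

  # per-cell within-factor level codes (+1 first level, -1 second)
  codes <- within_cell_codes(within, cell_levels)

  rhs <- paste(c(if (length(between)) paste(between, collapse = " * "),
                 covariates), collapse = " + ")
  if (rhs == "") rhs <- "1"
  contrasts_arg <- stats::setNames(
    rep(list("contr.sum"), length(between)), between
  )

  subsets <- within_effect_subsets(within)
  res <- list()
  for (s in subsets) {
    if (length(s) == 0) {
      score <- rowMeans(y_mat)
    } else {
      coef <- apply(codes[s, , drop = FALSE], 2, prod)
      score <- as.vector(y_mat %*% coef) / ncol(y_mat)
    }
    df_fit <- wide
    df_fit$.score <- score
    fit <- stats::lm(stats::as.formula(paste(".score ~", rhs)),
                     data = df_fit,
                     contrasts = if (length(between)) contrasts_arg)
    a3 <- tryCatch(
      car::Anova(fit, type = 3),
      error = function(e) type3_zero_residual_table(fit)
    )
    ss <- a3[["Sum Sq"]]
    names(ss) <- rownames(a3)
    ss_err <- ss[["Residuals"]]
    df_err <- a3["Residuals", "Df"]
    rows <- setdiff(rownames(a3), "Residuals")
    if (length(s) == 0) {
      rows <- setdiff(rows, "(Intercept)") # grand mean: not a reported effect
    }
    for (r in rows) {
      eff <- if (r == "(Intercept)") {
        paste(s, collapse = ":")
      } else if (length(s) == 0) {
        r
      } else {
        paste(paste(s, collapse = ":"), r, sep = ":")
      }
      ss_eff <- ss[[r]]
      f_val <- a3[r, "F value"]
      p_val <- a3[r, "Pr(>F)"]
      eta <- ss_eff / (ss_eff + ss_err)
      if (ss_eff == 0) { # degenerate stratum: no effect variance at all
        f_val <- 0; p_val <- 1; eta <- 0
      }
      res[[length(res) + 1L]] <- tibble::tibble(
        effect = eff,
        df_num = a3[r, "Df"],
        df_den = df_err,
        F = f_val,
        p = p_val,
        partial_eta_sq = eta
      )
    }
  }
  dplyr::bind_rows(res)
}

# Type III table for the degenerate case with (numerically) zero residual
# variance, where car::Anova refuses to divide. Same drop-one-term sums of
# squares; F is 0 for zero effect SS and +Inf otherwise.
type3_zero_residual_table <- function(fit) {
  X <- stats::model.matrix(fit)
  y <- stats::model.response(stats::model.frame(fit))
  rss <- function(M) {
    if (ncol(M) == 0) return(sum(y^2))
    sum(stats::lm.fit(M, y)$residuals^2)
  }
  rss_full <- rss(X)
  df_err <- nrow(X) - ncol(X)
  asgn <- attr(X, "assign")
  terms_idx <- sort(unique(asgn))
  rn <- c(ifelse(terms_idx == 0, "(Intercept)",
                 attr(stats::terms(fit), "term.labels")[terms_idx]),
          "Residuals")
  tab <- data.frame(
    `Sum Sq` = c(vapply(terms_idx, function(i) {
      rss(X[, asgn != i, drop = FALSE]) - rss_full
    }, 0), rss_full),
    Df = c(vapply(terms_idx, function(i) sum(asgn == i), 0L), df_err),
    row.names = rn, check.names = FALSE
  )
  eff <- seq_len(nrow(tab) - 1L)
  tab$`F value` <- NA_real_
  tab$`Pr(>F)` <- NA_real_
  tab$`F value`[eff] <- ifelse(tab$`Sum Sq`[eff] <= 1e-12, 0, Inf)
  tab$`Pr(>F)`[eff] <- ifelse(tab$`Sum Sq`[eff] <= 1e-12, 1, 0)
  tab$`Sum Sq`[eff][tab$`Sum Sq`[eff] <= 1e-12] <- 0
  tab
}

# +1/-1 code of each within factor in each cell, rows = factors, cols = cells
within_cell_codes <- function(within, cell_levels) {
  if (!length(within)) return(NULL)
  parts <- strsplit(cell_levels, ".", fixed = TRUE)
  codes <- matrix(NA_real_, nrow = length(within), ncol = length(cell_levels),
                  dimnames = list(within, cell_levels))
  for (i in seq_along(within)) {
    lev <- unique(vapply(parts, `[[`, "", i))
    codes[i, ] <- ifelse(vapply(parts, `[[`, "", i) == lev[1], 1, -1)
  }
  codes
}

# all subsets of the within factors, ordered mean first, then by size
within_effect_subsets <- function(within) {
  subsets <- list(character())
  if (length(within)) {
    for (k in seq_along(within)) {
      cmb <- utils::combn(within, k, simplify = FALSE)
      subsets <- c(subsets, cmb)
    }
  }
  subsets
}

#' One-sample t-test
#'
#' Two-sided t-test of the mean against `mu`. With zero variance the t
#' statistic is reported as `0` (mean equal to `mu`) or signed infinity.
#'
#' @param x Numeric vector (`NA` dropped), at least 2 values.
#' @param mu Null-hypothesis mean.
#' @return A tibble with columns `estimate`, `t`, `df`, `p`.
#' @export
one_sample_t <- function(x, mu = 0) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 non-missing values")
  if (stats::sd(x) == 0) {
    m <- mean(x)
    t_val <- if (m == mu) 0 else sign(m - mu) * Inf
    return(tibble::tibble(estimate = m, t = t_val,
                          df = length(x) - 1L, p = if (m == mu) 1 else 0))
  }
  ht <- stats::t.test(x, mu = mu)
  tibble::tibble(estimate = unname(ht$estimate), t = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-sided Pearson correlation test with the confidence interval
#' `tanh(atanh(r) +/- z / sqrt(n - 3))`.
#'
#' @param x,y Numeric vectors; pairs with missing values are dropped.
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble with columns `r`, `n`, `ci_low`, `ci_high`, `p`.
#' @export
#' @examples
#' set.seed(1)
#' x <- rnorm(104); y <- 0.25 * x + rnorm(104)
#' pearson_with_ci(x, y)
pearson_with_ci <- function(x, y, conf_level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: constant input")
  }
  ht <- stats::cor.test(x, y, conf.level = conf_level)
  tibble::tibble(
    r = unname(ht$estimate), n = n,
    ci_low = ht$conf.int[1], ci_high = ht$conf.int[2],
    p = ht$p.value
  )
}

#' Fisher's z-test for two independent correlations
#'
#' Compares correlations observed in two independent samples:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-sided p
#' from the standard normal.
#'
#' @param r1,r2 Sample correlations (strictly inside (-1, 1)).
#' @param n1,n2 Sample sizes (at least 4).
#' @return A tibble with columns `z`, `p`.
#' @export
#' @examples
#' fisher_z_independent(0.05, 27, 0.53, 28)
fisher_z_independent <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must lie strictly inside (-1, 1)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Williams' t-test for two dependent correlations sharing a variable
#'
#' Tests whether `cor(x1, x2)` differs from `cor(x1, x3)` within one sample
#' of size `n` (Williams' modification of Hotelling's procedure), with
#' `df = n - 3`:
#' \deqn{t = (r_{12} - r_{13}) \sqrt{\frac{(n-1)(1+r_{23})}
#'   {2\frac{n-1}{n-3}|R| + \bar r^2 (1-r_{23})^3}}}
#' where `|R|` is the determinant of the 3 x 3 correlation matrix and
#' `rbar = (r12 + r13) / 2`.
#'
#' @param r12,r13 The two correlations being compared (sharing variable 1).
#' @param r23 Correlation between the two non-shared variables.
#' @param n Sample size (at least 5).
#' @return A tibble with columns `t`, `df`, `p` (two-sided).
#' @export
#' @examples
#' hotelling_williams_t(0.32, 0.02, -0.01, 104)
hotelling_williams_t <- function(r12, r13, r23, n) {
  stopifnot(n >= 5)
  R <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3, 3)
  detR <- det(R)
  if (any(abs(c(r12, r13, r23)) > 1) || detR < -1e-8) {
    stop("correlations do not form a positive semidefinite matrix")
  }
  detR <- max(detR, 0)
  rbar <- (r12 + r13) / 2
  denom <- 2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3
  t_val <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / denom)
  df <- n - 3
  tibble::tibble(t = t_val, df = df, p = 2 * stats::pt(-abs(t_val), df))
}

#' Hierarchical-regression F-change test
#'
#' Tests whether predictors added to a base linear model explain additional
#' variance:
#' `F = ((R2_full - R2_base) / k_added) / ((1 - R2_full) / (n - k_full - 1))`,
#' computed via the nested-model F-test.
#'
#' @param data Data frame.
#' @param response Name of the response column.
#' @param base_terms Character vector of base-model terms (may include
#'   factors); `"1"` for an intercept-only base.
#' @param added_terms Character vector of terms added in the second step.
#' @return A tibble with columns `F_change`, `df_num`, `df_den`, `p`,
#'   `r_squared_base`, `r_squared_full`.
#' @export
#' @examples
#' d <- data.frame(y = rnorm(50), g = rep(c("a", "b"), 25), x = rnorm(50))
#' hierarchical_f_change(d, "y", "g", "x")
hierarchical_f_change <- function(data, response, base_terms, added_terms) {
  data <- as.data.frame(data)
  f_base <- stats::as.formula(
    paste(response, "~", paste(base_terms, collapse = " + "))
  )
  f_full <- stats::as.formula(
    paste(response, "~", paste(c(base_terms, added_terms), collapse = " + "))
  )
  m_base <- stats::lm(f_base, data = data)
  m_full <- stats::lm(f_full, data = data)
  if (any(is.na(stats::coef(m_base))) || any(is.na(stats::coef(m_full)))) {
    stop("rank-deficient design: predictors are collinear")
  }
  cmp <- stats::anova(m_base, m_full)
  tibble::tibble(
    F_change = cmp$F[2],
    df_num = cmp$Df[2],
    df_den = cmp$Res.Df[2],
    p = cmp$`Pr(>F)`[2],
    r_squared_base = summary(m_base)$r.squared,
    r_squared_full = summary(m_full)$r.squared
  )
}
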