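# independent Type III oracle: model-comparison with sum-to-zero contrasts
type3_oracle <- function(data, dv, factors) {
  for (f in factors) {
    data[[f]] <- factor(data[[f]])
    stats::contrasts(data[[f]]) <- stats::contr.sum(nlevels(data[[f]]))
  }
  form <- stats::as.formula(paste(dv, "~", paste(factors, collapse = "*")))
  X <- stats::model.matrix(form, data)
  y <- data[[dv]]
  rss <- function(M) sum(stats::lm.fit(M, y)$residuals^2)
  rss_full <- rss(X)
  df_err <- nrow(X) - ncol(X)
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(form), "term.labels")
  out <- list()
  for (i in seq_along(labs)) {
    drop <- which(asgn == i)
    rss_red <- rss(X[, -drop, drop = FALSE])
    ss <- rss_red - rss_full
    f_val <- (ss / length(drop)) / (rss_full / df_err)
    out[[labs[i]]] <- list(ss = ss, F = f_val, df = length(drop))
  }
  list(effects = out, rss = rss_full, df_err = df_err)
}

test_that("a two-group between-only design reduces to the pooled t-test", {
  set.seed(51)
  for (n in list(c(20, 20), c(27, 28))) {
    d <- data.frame(
      id = sprintf("s%02d", seq_len(sum(n))),
      g = rep(c("a", "b"), n),
      y = rnorm(sum(n), mean = rep(c(0, 0.5), n))
    )
    an <- split_plot_anova(d, "y", "id", between = "g")
    tt <- t.test(y ~ g, data = d, var.equal = TRUE)
    expect_equal(an$F[an$effect == "g"], unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(an$p[an$effect == "g"], tt$p.value, tolerance = 1e-10)
    expect_equal(an$df_den[an$effect == "g"], sum(n) - 2)
  }
})

test_that("balanced split-plot results match aov error-strata output exactly", {
  set.seed(52)
  n_per <- 8
  d <- expand.grid(
    id = sprintf("s%02d", 1:(2 * n_per)),
    target = c("self", "other"),
    desirability = c("desirable", "undesirable"),
    stringsAsFactors = FALSE
  )
  d$culture <- ifelse(as.integer(sub("s", "", d$id)) <= n_per,
                      "German", "Chinese")
  d$y <- rnorm(nrow(d)) +
    0.8 * (d$desirability == "desirable") +
    0.3 * (d$culture == "Chinese")
  an <- split_plot_anova(d, "y", "id",
                         within = c("target", "desirability"),
                         between = "culture")
  fit <- stats::aov(
    y ~ target * desirability * culture +
      Error(id / (target * desirability)),
    data = transform(d, target = factor(target),
                     desirability = factor(desirability),
                     culture = factor(culture))
  )
  sm <- summary(fit)
  ref <- list()
  for (stratum in sm) {
    tab <- stratum[[1]]
    ss_err <- tab["Residuals", "Sum Sq"]
    for (r in setdiff(rownames(tab), "Residuals")) {
      nm <- gsub(" ", "", r)
      ref[[nm]] <- c(F = tab[r, "F value"], p = tab[r, "Pr(>F)"],
                     eta = tab[r, "Sum Sq"] / (tab[r, "Sum Sq"] + ss_err),
                     df1 = tab[r, "Df"], df2 = tab["Residuals", "Df"])
    }
  }
  canon <- function(e) paste(sort(strsplit(e, ":")[[1]]), collapse = ":")
  ref_keys <- setNames(names(ref), vapply(names(ref), canon, ""))
  for (i in seq_len(nrow(an))) {
    key <- canon(an$effect[i])
    expect_true(key %in% names(ref_keys))
    want <- ref[[ref_keys[[key]]]]
    expect_equal(an$F[i], unname(want["F"]), tolerance = 1e-8)
    expect_equal(an$p[i], unname(want["p"]), tolerance = 1e-8)
    expect_equal(an$partial_eta_sq[i], unname(want["eta"]), tolerance = 1e-8)
    expect_equal(an$df_num[i], unname(want["df1"]))
    expect_equal(an$df_den[i], unname(want["df2"]))
  }
})

test_that("unbalanced between effects are Type III (model-comparison oracle)", {
  set.seed(53)
  d <- data.frame(
    id = sprintf("s%03d", 1:104),
    culture = rep(c("German", "German", "Chinese", "Chinese"), c(27, 24, 28, 25)),
    place = rep(c("Berlin", "Beijing", "Berlin", "Beijing"), c(27, 24, 28, 25))
  )
  d$y <- rnorm(104) + 0.4 * (d$culture == "Chinese") +
    0.2 * (d$place == "Beijing") * (d$culture == "German")
  an <- split_plot_anova(d, "y", "id", between = c("culture", "place"))
  orc <- type3_oracle(d, "y", c("culture", "place"))
  for (eff in c("culture", "place", "culture:place")) {
    expect_equal(an$F[an$effect == eff], orc$effects[[eff]]$F,
                 tolerance = 1e-10)
  }
  expect_true(all(an$df_den == 100))
})

test_that("degenerate and invalid designs are handled as documented", {
  set.seed(54)
  # duplicating the desirable cell into undesirable kills the effect
  d <- expand.grid(id = sprintf("s%02d", 1:12),
                   desirability = c("desirable", "undesirable"),
                   stringsAsFactors = FALSE)
  d$g <- rep(c("a", "b"), each = 6)[match(d$id, unique(d$id))]
  base_y <- rnorm(12)
  d$y <- base_y[match(d$id, unique(d$id))] # identical in both cells
  an <- split_plot_anova(d, "y", "id", within = "desirability", between = "g")
  expect_equal(an$F[an$effect == "desirability"], 0)
  expect_equal(an$p[an$effect == "desirability"], 1)

  # three-level within factor unsupported
  d3 <- expand.grid(id = sprintf("s%02d", 1:6), w = c("a", "b", "c"),
                    stringsAsFactors = FALSE)
  d3$y <- rnorm(nrow(d3))
  expect_error(split_plot_anova(d3, "y", "id", within = "w"), "2 levels")

  # empty between cell
  d4 <- expand.grid(id = sprintf("s%02d", 1:8),
                    desirability = c("desirable", "undesirable"),
                    stringsAsFactors = FALSE)
  idn <- as.integer(sub("s", "", d4$id))
  d4$place <- ifelse(idn <= 4, "Berlin", "Beijing")
  d4$culture <- ifelse(idn <= 4, "German", "Chinese") # diagonal cells only
  d4$y <- rnorm(nrow(d4))
  expect_error(
    split_plot_anova(d4, "y", "id", within = "desirability",
                     between = c("culture", "place")),
    "empty between"
  )
})

test_that("participants with missing cells are dropped listwise", {
  set.seed(55)
  d <- expand.grid(id = sprintf("s%02d", 1:20),
                   desirability = c("desirable", "undesirable"),
                   stringsAsFactors = FALSE)
  d$g <- rep(c("a", "b"), each = 10)[match(d$id, unique(d$id))]
  d$y <- rnorm(nrow(d))
  d$y[d$id == "s01" & d$desirability == "undesirable"] <- NA
  an <- split_plot_anova(d, "y", "id", within = "desirability", between = "g")
  expect_true(all(an$df_den == 19 - 2)) # 19 complete subjects, 2 groups
})

test_that("a numeric covariate enters the between model and spends one df", {
  set.seed(56)
  d <- expand.grid(id = sprintf("s%02d", 1:30),
                   desirability = c("desirable", "undesirable"),
                   stringsAsFactors = FALSE)
  ids <- unique(d$id)
  d$g <- rep(c("a", "b"), each = 15)[match(d$id, ids)]
  d$age <- rep(rnorm(30, 25, 3), 2)[match(d$id, ids)]
  d$y <- rnorm(nrow(d))
  an <- split_plot_anova(d, "y", "id", within = "desirability",
                         between = "g", covariates = "age")
  expect_true(all(an$df_den == 30 - 2 - 1))
  expect_true("age" %in% an$effect)
})

test_that("one-sample t-test matches the closed form and handles edges", {
  set.seed(57)
  x <- rnorm(30, 0.4)
  got <- one_sample_t(x)
  t_manual <- mean(x) / (sd(x) / sqrt(30))
  expect_equal(got$t, t_manual, tolerance = 1e-12)
  expect_equal(got$df, 29)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 29), tolerance = 1e-12)

  expect_equal(one_sample_t(c(2, 2, 2), mu = 2)$t, 0)
  expect_equal(one_sample_t(c(2, 2, 2), mu = 1)$t, Inf)
  expect_equal(one_sample_t(rnorm(104))$df, 103)
  expect_error(one_sample_t(1), "at least 2")
})

test_that("Fisher-z confidence intervals reproduce the reference bounds", {
  p1 <- make_cor_pair(0.25, 104)
  got1 <- pearson_with_ci(p1$x, p1$y)
  expect_equal(got1$r, 0.25, tolerance = 1e-12)
  expect_equal(round(got1$ci_low, 2), 0.06)
  expect_equal(round(got1$ci_high, 2), 0.42)

  p2 <- make_cor_pair(0.52, 104)
  got2 <- pearson_with_ci(p2$x, p2$y)
  expect_equal(round(got2$ci_low, 2), 0.36)
  expect_equal(round(got2$ci_high, 2), 0.65)

  # closed form
  ci <- tanh(atanh(0.25) + c(-1, 1) * qnorm(0.975) / sqrt(101))
  expect_equal(c(got1$ci_low, got1$ci_high), ci, tolerance = 1e-10)

  p0 <- make_cor_pair(0, 50)
  got0 <- pearson_with_ci(p0$x, p0$y)
  expect_equal(got0$ci_low, -got0$ci_high, tolerance = 1e-10)

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("Fisher z for independent correlations matches the formula", {
  expect_equal(fisher_z_independent(0.4, 30, 0.4, 40)$z, 0)
  got <- fisher_z_independent(0.05, 27, 0.53, 28)
  expect_equal(abs(got$z), 1.89, tolerance = 0.005)
  z_manual <- (atanh(0.05) - atanh(0.53)) / sqrt(1 / 24 + 1 / 25)
  expect_equal(got$z, z_manual, tolerance = 1e-12)
  expect_equal(got$p, 2 * pnorm(-abs(z_manual)), tolerance = 1e-12)
  expect_error(fisher_z_independent(1, 30, 0.2, 30), "inside")
})

test_that("Williams' t matches its reference value, df rule, and edge cases", {
  expect_equal(hotelling_williams_t(0.4, 0.4, 0.2, 50)$t, 0)
  got <- hotelling_williams_t(0.32, 0.02, -0.01, 104)
  expect_equal(got$df, 101)
  expect_equal(got$t, 2.22, tolerance = 0.005)
  expect_lt(got$p, 0.05)
  expect_error(hotelling_williams_t(0.9, 0.9, -0.9, 50), "semidefinite")
})

test_that("F-change matches a from-scratch sum-of-squares oracle", {
  set.seed(58)
  for (i in 1:5) {
    n <- 60
    d <- data.frame(y = rnorm(n), x1 = rnorm(n), x2 = rnorm(n),
                    g = sample(c("a", "b"), n, TRUE))
    got <- hierarchical_f_change(d, "y", c("g", "x1"), "x2")
    # oracle via R-squared arithmetic
    r2 <- function(f) summary(lm(f, d))$r.squared
    r2b <- r2(y ~ g + x1); r2f <- r2(y ~ g + x1 + x2)
    k_full <- 3
    f_manual <- ((r2f - r2b) / 1) / ((1 - r2f) / (n - k_full - 1))
    expect_equal(got$F_change, f_manual, tolerance = 1e-10)
    expect_equal(got$df_num, 1)
    expect_equal(got$df_den, n - k_full - 1)
  }
  # df pattern of the reference analysis: n = 104, one base predictor, add one
  d2 <- data.frame(y = rnorm(104), g = rep(c("a", "b"), 52), x = rnorm(104))
  got2 <- hierarchical_f_change(d2, "y", "g", "x")
  expect_equal(c(got2$df_num, got2$df_den), c(1, 101))

  # an added predictor with zero partial correlation explains nothing
  set.seed(59)
  n <- 50
  base <- rnorm(n); y <- base + rnorm(n)
  extra <- residuals(lm(rnorm(n) ~ y + base)) # orthogonal to y given base
  d3 <- data.frame(y = y, base = base, extra = extra)
  got3 <- hierarchical_f_change(d3, "y", "base", "extra")
  expect_lt(got3$F_change, 1e-20)

  # collinearity is refused
  d4 <- data.frame(y = rnorm(20), a = 1:20, b = 2 * (1:20))
  expect_error(hierarchical_f_change(d4, "y", "a", "b"), "collinear")
})
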