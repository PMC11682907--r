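# Shared fixture: a two-condition, per-subject-moderated dataset with
# known structure, small enough to refit repeatedly.
make_model_data <- function(n_subj = 40, n_per = 12, beta_bdi = 0.3,
                            delta_cond = 0.5, seed = 50) {
  set.seed(seed)
  subj <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n_subj)),
    bdi = sample(0:30, n_subj, replace = TRUE),
    preference = rnorm(n_subj, 2, 1.5),
    age = runif(n_subj, 35, 75),
    b_i = rnorm(n_subj, 0, 0.5)
  )
  tidyr::expand_grid(subj, trial = seq_len(n_per)) |>
    dplyr::mutate(
      condition = rep_len(c("positive-neutral", "negative-neutral"),
                          dplyr::n()),
      y = 5 + beta_bdi * (bdi - 15) / 8 +
        delta_cond * (condition == "positive-neutral") +
        b_i + rnorm(dplyr::n())
    )
}

test_that("standardize/unstandardize are exact inverses with a record", {
  d <- tibble::tibble(a = c(1, 2, 3, 10), b = c(-1, 0, 2, 4))
  z <- standardize(d, c("a", "b"))
  expect_equal(mean(z$a), 0, tolerance = 1e-12)
  expect_equal(sd(z$b), 1, tolerance = 1e-12)
  sc <- attr(z, "scaling")
  expect_equal(sc$variable, c("a", "b"))
  expect_equal(sc$mean[1], 4)
  back <- unstandardize(z)
  expect_equal(back$a, d$a, tolerance = 1e-12)
  expect_equal(back$b, d$b, tolerance = 1e-12)

  expect_error(standardize(d, "missing_col"), "not in data")
  expect_error(standardize(tibble::tibble(a = rep(2, 5)), "a"),
               "zero variance")
  expect_error(unstandardize(d), "scaling")
})

test_that("fit_lmm recovers a planted standardized slope", {
  set.seed(51)
  n_subj <- 40
  d <- tidyr::expand_grid(
    subject_id = sprintf("S%03d", seq_len(n_subj)), obs = 1:10) |>
    dplyr::mutate(x = rnorm(dplyr::n()))
  b_i <- rnorm(n_subj, 0, 0.5)
  names(b_i) <- sprintf("S%03d", seq_len(n_subj))
  d$y <- 2 + 0.37 * d$x + b_i[d$subject_id] + rnorm(nrow(d))

  fit <- fit_lmm(d, y ~ x + (1 | subject_id), scale_vars = c("y", "x"))
  expect_s3_class(fit, "gazebias_fit")
  expect_equal(fit$n_observations, 400)
  expect_equal(fit$n_subjects, 40)

  # independent path: z-score by hand and fit lme4 directly
  dz <- d
  dz$x <- as.numeric(scale(dz$x))
  dz$y <- as.numeric(scale(dz$y))
  ref <- lme4::lmer(y ~ x + (1 | subject_id), data = dz, REML = FALSE)
  got <- fit$fixed_effects[fit$fixed_effects$term == "x", ]
  expect_equal(got$estimate, unname(lme4::fixef(ref)["x"]),
               tolerance = 1e-6)

  # the planted slope on the standardized scale sits inside the 95% CI
  planted_std <- 0.37 * sd(d$x) / sd(d$y)
  expect_gt(planted_std, got$ci_lo)
  expect_lt(planted_std, got$ci_hi)

  # the type-III F line for x equals the square of the t test
  fline <- fit$anova_lines[fit$anova_lines$term == "x", ]
  expect_equal(fline$f, got$t^2, tolerance = 1e-6)
  expect_equal(fline$df2, got$df, tolerance = 1e-3)

  # tidy/glance accessors
  expect_identical(tidy(fit), fit$fixed_effects)
  expect_identical(tidy(fit, effects = "anova"), fit$anova_lines)
  expect_equal(glance(fit)$n_observations, 400)
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("fit_lmm rejects degenerate inputs and survives zero variance", {
  d <- make_model_data(n_subj = 12, n_per = 6)
  one_cond <- dplyr::filter(d, condition == "positive-neutral")
  expect_error(
    fit_lmm(one_cond, y ~ bdi * condition + (1 | subject_id)),
    "single level")
  expect_error(fit_lmm(d, y ~ nope + (1 | subject_id)), "not in data")

  # no subject-level variance: fit is singular but still reported
  set.seed(52)
  flat <- d
  flat$y <- flat$y - flat$b_i  # remove the random intercept exactly
  fit <- suppressWarnings(
    fit_lmm(flat, y ~ bdi + (1 | subject_id), scale_vars = c("y", "bdi")))
  expect_true(is.logical(fit$singular))
})

test_that("emmeans_over_range equals prediction averaging over the grid", {
  d <- make_model_data()
  fit <- fit_lmm(d, y ~ bdi * condition + (1 | subject_id),
                 scale_vars = c("y", "bdi"))
  ct <- suppressWarnings(
    emmeans_over_range(fit, "condition", "bdi", c(0, 8),
                       label = "low-bdi contrast"))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$label, "low-bdi contrast")

  # independent computation: mean fixed-effect prediction difference
  sc <- fit$scaling
  i <- match("bdi", sc$variable)
  grid <- (0:8 - sc$mean[i]) / sc$sd[i]
  pred <- function(cond) {
    nd <- tibble::tibble(bdi = grid, condition = cond)
    mean(predict(fit$model, newdata = nd, re.form = NA))
  }
  want <- pred("negative-neutral") - pred("positive-neutral")
  # emmeans orders the pairwise contrast by factor level
  expect_equal(ct$estimate, want, tolerance = 1e-8)

  # the planted condition effect has the right sign: positive-neutral is
  # higher, so (negative - positive) < 0
  expect_lt(ct$estimate, 0)
  # over the central BDI range, away from the extrapolated low end, the
  # planted contrast is also clearly detected
  ct_mid <- emmeans_over_range(fit, "condition", "bdi", c(11, 19))
  expect_lt(ct_mid$estimate, 0)
  expect_lt(ct_mid$p, 0.05)

  expect_error(emmeans_over_range(fit, "condition", "age", c(0, 8)),
               "not in the model")
  expect_warning(emmeans_over_range(fit, "condition", "bdi", c(0, 80)),
                 "beyond observed")
})

test_that("age slopes are constant without an interaction and linear with one", {
  d <- make_model_data()
  set.seed(53)
  d$y <- d$y + 0.2 * (d$age - 55) / 12

  # no age-by-preference term: the probe level cannot matter
  fit0 <- fit_lmm(d, y ~ age * condition + preference + (1 | subject_id),
                  scale_vars = c("y", "age", "preference"))
  sl0 <- age_slopes_at_levels(fit0, moderator = "preference",
                              levels = c(0, 2, 4))
  expect_equal(nrow(sl0), 6)  # 3 levels x 2 conditions
  for (cond in unique(sl0$condition)) {
    s <- sl0$slope[sl0$condition == cond]
    expect_lt(diff(range(s)), 1e-10)
  }

  # with the interaction, slopes are linear in the moderator level
  fit1 <- fit_lmm(d, y ~ age * condition * preference + (1 | subject_id),
                  scale_vars = c("y", "age", "preference"))
  sl1 <- age_slopes_at_levels(fit1, moderator = "preference",
                              levels = c(0, 1, 2))
  for (cond in unique(sl1$condition)) {
    s <- sl1$slope[sl1$condition == cond]
    expect_equal(s[2], (s[1] + s[3]) / 2, tolerance = 1e-8)
  }

  # default levels carry the SD multipliers
  sl2 <- age_slopes_at_levels(fit1)
  expect_equal(sort(unique(sl2$multiplier)), c(-1.5, -1, 0, 1, 1.5))
  m <- mean(d$preference); s <- sd(d$preference)
  expect_equal(sort(unique(sl2$moderator_level)),
               m + c(-1.5, -1, 0, 1, 1.5) * s, tolerance = 1e-8)

  expect_error(age_slopes_at_levels(fit0, moderator = "bdi"), "bdi")
})

test_that("location terms in the pair model are null-calibrated", {
  # the generator assigns sides at random, so every location-involving
  # term in m1 is a true null; count rejections across replicates
  n_rep <- 20
  rejections <- 0
  n_tests <- 0
  for (rep in seq_len(n_rep)) {
    co <- generate_cohort(12, 0, seed = 600 + rep)
    sim <- simulate_cohort_gaze(co, seed = 700 + rep)
    td <- compute_trial_dwell(sim$samples, sim$trials)
    long <- td |>
      dplyr::filter(condition != "neutral-neutral") |>
      tidyr::pivot_longer(c("dwell_emotional_ms", "dwell_neutral_ms"),
                          names_to = "emotion", values_to = "dwell") |>
      dplyr::mutate(emotion = sub("dwell_(.*)_ms", "\\1", emotion),
                    pair = condition, location = emotional_side)
    m1 <- suppressWarnings(
      fit_lmm(long, dwell ~ emotion * pair * location + (1 | subject_id),
              scale_vars = "dwell"))
    loc <- m1$anova_lines[grepl("location", m1$anova_lines$term), ]
    rejections <- rejections + sum(loc$p < 0.05)
    n_tests <- n_tests + nrow(loc)
  }
  expect_equal(n_tests, n_rep * 4)
  # 80 tests at alpha = .05: P(>12 rejections) < 1e-4 under the null
  expect_lte(rejections, 12)
})

test_that("the full model suite fits and exposes the planned structure", {
  co <- generate_cohort(8, 6, seed = 60)
  sim <- simulate_cohort_gaze(co, seed = 61)
  td <- compute_trial_dwell(sim$samples, sim$trials)
  kept <- qc_exclude(td)$kept

  suite <- suppressWarnings(run_model_suite(kept, co))
  expect_s3_class(suite, "gazebias_suite")
  for (nm in c("m1", "m1b", "m2", "m3_control", "m3_mdd", "m4")) {
    expect_s3_class(suite[[nm]], "gazebias_fit")
  }
  expect_equal(suite$dv, "dwell")
  expect_true("emotion:pair:location" %in% suite$m1$anova_lines$term)
  expect_true("bdi:condition" %in% suite$m2$anova_lines$term)
  expect_true("age:condition:preference" %in%
                suite$m3_control$anova_lines$term)
  expect_true("age:condition:preference:bdi" %in% suite$m4$anova_lines$term)

  # per-image long table conserves the dwell totals
  long <- suite$data$long
  emo <- dplyr::filter(kept, condition != "neutral-neutral")
  expect_equal(sum(long$dwell),
               sum(emo$dwell_emotional_ms + emo$dwell_neutral_ms))

  # bias DV variant uses bias scores as y
  suite_b <- suppressWarnings(run_model_suite(kept, co, dv = "bias"))
  expect_equal(suite_b$dv, "bias")
  expect_true(all(suite_b$data$moderation$y >= 0 &
                    suite_b$data$moderation$y <= 1))

  expect_output(print(suite), "m3_control")
  expect_s3_class(plot_bias_by_condition(suite$data$bias), "ggplot")
})
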