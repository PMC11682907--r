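#' Standardize analysis variables
#'
#' Centers and scales the named columns by their sample mean and SD over
#' the supplied (already filtered) analysis subset, so fitted coefficients
#' are standardized betas. The scaling record is attached as the
#' `"scaling"` attribute and allows exact back-transformation.
#'
#' @param data A data frame.
#' @param variables Character vector of numeric columns to standardize.
#' @return The data with the named columns z-scored and a `"scaling"`
#'   attribute (tibble `variable`, `mean`, `sd`).
#' @seealso [unstandardize()]
#' @export
standardize <- function(data, variables) {
  data <- as_tibble(data)
  scaling <- purrr::map_dfr(variables, function(v) {
    if (!v %in% names(data)) abort(sprintf("variable `%s` not in data", v))
    m <- mean(data[[v]], na.rm = TRUE)
    s <- sd(data[[v]], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      abort(sprintf("variable `%s` has zero variance; cannot standardize", v))
    }
    tibble(variable = v, mean = m, sd = s)
  })
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    data[[v]] <- (data[[v]] - scaling$mean[i]) / scaling$sd[i]
  }
  attr(data, "scaling") <- scaling
  data
}

#' Undo [standardize()]
#'
#' @param data A data frame whose columns were z-scored.
#' @param scaling A scaling record (the `"scaling"` attribute set by
#'   [standardize()]; defaults to the one attached to `data`).
#' @return The data on the original scale.
#' @export
unstandardize <- function(data, scaling = attr(data, "scaling")) {
  if (is.null(scaling)) abort("no scaling record supplied or attached")
  for (i in seq_len(nrow(scaling))) {
    v <- scaling$variable[i]
    data[[v]] <- data[[v]] * scaling$sd[i] + scaling$mean[i]
  }
  attr(data, "scaling") <- NULL
  data
}

#' Fit a Gaussian linear mixed model with Satterthwaite inference
#'
#' Fits `formula` by maximum likelihood with a subject random intercept
#' (the random term is part of the formula), using sum-to-zero contrasts
#' for factors so the type-III F lines are marginal tests. Continuous
#' variables named in `scale_vars` are standardized over `data` first, so
#' reported coefficients are standardized betas. Fixed-effect t tests and
#' the per-term F table use Satterthwaite degrees of freedom.
#'
#' @param data The analysis subset (one row per observation).
#' @param formula An lme4-style formula, e.g.
#'   `dwell ~ age * condition * preference + (1 | subject_id)`.
#' @param scale_vars Character vector of columns to standardize before
#'   fitting (outcome and continuous predictors); NULL fits on the given
#'   scale.
#' @return An object of class `gazebias_fit`: a list with `model` (the
#'   lmerTest fit), `fixed_effects` (standardized estimate, SE,
#'   Satterthwaite df, t, p, 95% CI per term), `anova_lines` (type-III F
#'   table), `scaling`, `n_observations`, `n_subjects`, `converged` and
#'   `singular`.
#' @export
fit_lmm <- function(data, formula, scale_vars = NULL) {
  data <- as_tibble(data)
  if (!is.null(scale_vars)) data <- standardize(data, scale_vars)
  vars <- all.vars(formula)
  miss <- setdiff(vars, names(data))
  if (length(miss)) {
    abort(paste0("model variables not in data: ", paste(miss, collapse = ", ")))
  }
  data <- filter(data, complete.cases(data[vars]))
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]]) && nlevels(droplevels(data[[v]])) < 2 &&
        v != all.vars(formula)[1]) {
      abort(sprintf("factor `%s` has a single level after filtering", v))
    }
    if (is.factor(data[[v]])) data[[v]] <- droplevels(data[[v]])
  }
  factors <- vars[vapply(data[vars], is.factor, TRUE)]
  # random-grouping factors keep treatment coding; fixed factors get
  # sum-to-zero so the type-III table tests marginal effects
  bars <- lme4::findbars(formula)
  grp_vars <- unique(unlist(lapply(bars, function(b) all.vars(b[[3]]))))
  contr <- lapply(setdiff(factors, grp_vars), function(v) "contr.sum")
  names(contr) <- setdiff(factors, grp_vars)

  fit <- lmerTest::lmer(formula, data = data, REML = FALSE,
                        contrasts = if (length(contr)) contr else NULL)
  conv_msgs <- fit@optinfo$conv$lme4$messages
  converged <- is.null(conv_msgs) || !length(conv_msgs)
  if (!converged) {
    warn(paste0("mixed-model convergence warning: ",
                paste(conv_msgs, collapse = "; ")))
  }

  sm <- as.data.frame(summary(fit)$coefficients)
  fixed <- tibble(
    term = rownames(sm),
    estimate = sm$Estimate,
    se = sm$`Std. Error`,
    df = sm$df,
    t = sm$`t value`,
    p = sm$`Pr(>|t|)`
  ) %>%
    mutate(ci_lo = .data$estimate - qt(0.975, .data$df) * .data$se,
           ci_hi = .data$estimate + qt(0.975, .data$df) * .data$se)

  av <- as.data.frame(stats::anova(fit, type = 3))
  anova_lines <- tibble(
    term = rownames(av),
    f = av$`F value`,
    df1 = av$NumDF,
    df2 = av$DenDF,
    p = av$`Pr(>F)`
  )

  structure(
    list(model = fit, formula = formula, fixed_effects = fixed,
         anova_lines = anova_lines,
         scaling = attr(data, "scaling"),
         data = data,
         n_observations = nrow(data),
         n_subjects = if (length(grp_vars))
           dplyr::n_distinct(data[[grp_vars[1]]]) else NA_integer_,
         converged = converged,
         singular = lme4::isSingular(fit)),
    class = "gazebias_fit"
  )
}

#' @export
print.gazebias_fit <- function(x, ...) {
  cat("Linear mixed model (ML, Satterthwaite df)\n")
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d observations, %s subjects%s%s\n\n",
              x$n_observations, x$n_subjects,
              if (!x$converged) ", NOT CONVERGED" else "",
              if (x$singular) ", singular fit" else ""))
  cat("Type-III F tests:\n")
  print(as.data.frame(x$anova_lines), row.names = FALSE, digits = 4)
  cat("\nStandardized fixed effects:\n")
  print(as.data.frame(x$fixed_effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x A `gazebias_fit`.
#' @param effects `"fixed"` for the coefficient table, `"anova"` for the
#'   type-III F lines.
#' @param ... Unused.
#' @method tidy gazebias_fit
#' @export
tidy.gazebias_fit <- function(x, effects = c("fixed", "anova"), ...) {
  effects <- match.arg(effects)
  if (effects == "fixed") x$fixed_effects else x$anova_lines
}

#' @rdname fit_lmm
#' @method glance gazebias_fit
#' @export
glance.gazebias_fit <- function(x, ...) {
  tibble(
    n_observations = x$n_observations,
    n_subjects = x$n_subjects,
    sigma = stats::sigma(x$model),
    logLik = as.numeric(logLik(x$model)),
    AIC = stats::AIC(x$model),
    converged = x$converged,
    singular = x$singular
  )
}

# Estimate, Satterthwaite df and CI for a fixed-effect linear combination.
fixef_combo <- function(fit, L, label = "combo") {
  ct <- as.data.frame(lmerTest::contest1D(fit$model, L, confint = TRUE))
  tibble(
    label = label,
    estimate = ct$Estimate,
    se = ct$`Std. Error`,
    df = ct$df,
    t = ct$`t value`,
    p = ct$`Pr(>|t|)`,
    ci_lo = ct$lower,
    ci_hi = ct$upper
  )
}

model_scale <- function(fit, variable, raw_values) {
  sc <- fit$scaling
  if (is.null(sc) || !variable %in% sc$variable) return(raw_values)
  i <- match(variable, sc$variable)
  (raw_values - sc$mean[i]) / sc$sd[i]
}

#' Factor contrast averaged over a covariate range
#'
#' Computes estimated marginal means for each level of `factor` with the
#' model's predictions averaged, with equal weight, over an integer grid
#' spanning `range` of `covariate` (on the raw scale; the grid is mapped
#' through the fit's scaling record), then the pairwise contrast between
#' the factor levels. This is the "contrast averaged across the BDI range
#' of each group" follow-up for a covariate-by-factor interaction.
#'
#' @param fit A `gazebias_fit` whose model contains `factor` and
#'   `covariate`.
#' @param factor Name of the factor to contrast (e.g. `"condition"`).
#' @param covariate Name of the continuous moderator (e.g. `"bdi"`).
#' @param range Length-2 numeric: inclusive raw-scale bounds of the
#'   averaging grid (integer steps).
#' @param label Label carried into the output.
#' @param adjust P-value adjustment over the contrasts (`"none"` or
#'   `"bonferroni"`).
#' @return A tibble with one row per pairwise contrast: `label`,
#'   `contrast`, `estimate`, `se`, `df`, `t`, `p`, `ci_lo`, `ci_hi`.
#' @export
emmeans_over_range <- function(fit, factor, covariate, range,
                               label = NULL, adjust = "none") {
  stopifnot(inherits(fit, "gazebias_fit"))
  vars <- all.vars(fit$formula)
  if (!covariate %in% vars) {
    abort(sprintf("covariate `%s` is not in the model", covariate))
  }
  obs <- fit$data[[covariate]]
  grid_raw <- seq(ceiling(range[1]), floor(range[2]))
  grid <- model_scale(fit, covariate, grid_raw)
  if (min(grid) < min(obs) - 1e-9 || max(grid) > max(obs) + 1e-9) {
    warn(sprintf("averaging range [%s, %s] extends beyond observed `%s`",
                 range[1], range[2], covariate))
  }
  at <- list(grid)
  names(at) <- covariate
  em <- suppressMessages(
    emmeans::emmeans(fit$model, specs = factor, at = at,
                     lmer.df = "satterthwaite", lmerTest.limit = 1e6))
  ct <- summary(emmeans::contrast(em, method = "pairwise"),
                adjust = adjust, infer = TRUE)
  tibble(
    label = label %||% sprintf("%s contrast over %s in [%s, %s]",
                               factor, covariate, range[1], range[2]),
    contrast = as.character(ct$contrast),
    estimate = ct$estimate,
    se = ct$SE,
    df = ct$df,
    t = ct$t.ratio,
    p = ct$p.value,
    ci_lo = ct$lower.CL,
    ci_hi = ct$upper.CL
  )
}

#' Age simple slopes at moderator levels
#'
#' The slope of (standardized) age on the outcome, evaluated per condition
#' at fixed levels of the ERQ preference moderator, with Satterthwaite t
#' tests and 95% CIs — the follow-up that unpacks an
#' age-by-condition-by-preference interaction. Levels default to the
#' moderator mean plus \{-1.5, -1, 0, +1, +1.5\} SD computed on the raw
#' scale of the analysis subset.
#'
#' @param fit A `gazebias_fit` containing `age`, the moderator and their
#'   interaction.
#' @param moderator Name of the moderator column (default `"preference"`).
#' @param levels Raw-scale moderator levels; NULL uses mean + multiples
#'   of SD.
#' @param multipliers SD multiples used when `levels` is NULL.
#' @param by Optional factor to condition on (default `"condition"` when
#'   present in the model).
#' @return A tibble with `moderator_level` (raw scale), `multiplier`
#'   (when derived from SDs), the conditioning level, and `slope`, `se`,
#'   `df`, `t`, `p`, `ci_lo`, `ci_hi` of age.
#' @export
age_slopes_at_levels <- function(fit, moderator = "preference",
                                 levels = NULL,
                                 multipliers = c(-1.5, -1, 0, 1, 1.5),
                                 by = NULL) {
  stopifnot(inherits(fit, "gazebias_fit"))
  vars <- all.vars(fit$formula)
  if (!all(c("age", moderator) %in% vars)) {
    abort(sprintf("model must contain `age` and `%s`", moderator))
  }
  if (is.null(by) && "condition" %in% vars) by <- "condition"

  sc <- fit$scaling
  mult <- NULL
  if (is.null(levels)) {
    if (!is.null(sc) && moderator %in% sc$variable) {
      i <- match(moderator, sc$variable)
      m <- sc$mean[i]; s <- sc$sd[i]
    } else {
      m <- mean(fit$data[[moderator]]); s <- sd(fit$data[[moderator]])
    }
    levels <- m + multipliers * s
    mult <- multipliers
  }
  level_model <- model_scale(fit, moderator, levels)

  out <- purrr::map_dfr(seq_along(levels), function(i) {
    at <- list(level_model[i])
    names(at) <- moderator
    tr <- suppressMessages(
      emmeans::emtrends(fit$model, specs = by, var = "age", at = at,
                        lmer.df = "satterthwaite", lmerTest.limit = 1e6))
    s <- summary(tr, infer = TRUE)
    tibble(
      moderator_level = levels[i],
      multiplier = if (is.null(mult)) NA_real_ else mult[i],
      by_level = if (is.null(by)) NA_character_ else as.character(s[[by]]),
      slope = s$age.trend,
      se = s$SE,
      df = s$df,
      t = s$t.ratio,
      p = s$p.value,
      ci_lo = s$lower.CL,
      ci_hi = s$upper.CL
    )
  })
  if (!is.null(by)) names(out)[names(out) == "by_level"] <- by
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit the full affective-bias model suite
#'
#' Runs the four moderation analyses on QC-passed dwell data joined to
#' participant traits, each on its own subset with variables standardized
#' within that subset:
#' \describe{
#'   \item{m1}{Emotional pairs, one row per image per trial: dwell time by
#'     image emotion x image pair x image location, testing the overall
#'     emotional bias and its independence from screen side.}
#'   \item{m1b}{Neutral-neutral pairs: dwell time by image location only.}
#'   \item{m2}{Per-trial bias scores: BDI x condition, the depression
#'     moderation of the positivity bias.}
#'   \item{m3_control, m3_mdd}{Age x condition x ERQ preference on the
#'     emotional-image DV, separately per group — the positivity-effect
#'     moderation by emotion-regulation preference.}
#'   \item{m4}{Age x condition x preference x BDI across all
#'     participants.}
#' }
#'
#' @param trial_dwell QC-passed dwell rows (the `kept` table of
#'   [qc_exclude()]).
#' @param participants The cohort table with `age`, `bdi_sum`, `group` and
#'   ERQ items.
#' @param dv Dependent variable for m3/m4: `"dwell"` (per-trial dwell time
#'   on the emotional image, ms; the default) or `"bias"` (the bias
#'   proportion).
#' @return A list of class `gazebias_suite` of `gazebias_fit` objects
#'   (`m1`, `m1b`, `m2`, `m3_control`, `m3_mdd`, `m4`) plus the assembled
#'   analysis tables in `$data`.
#' @export
run_model_suite <- function(trial_dwell, participants, dv = c("dwell", "bias")) {
  dv <- match.arg(dv)
  td <- as_tibble(trial_dwell)
  traits <- as_tibble(participants) %>%
    left_join(select(erq_scores(participants), "subject_id", "preference"),
              by = "subject_id") %>%
    select("subject_id", "group", "age", bdi = "bdi_sum", "preference")

  emo <- filter(td, .data$condition %in% c("positive-neutral",
                                           "negative-neutral"))
  if (!nrow(emo)) abort("no emotional-pair trials after filtering")

  # one row per image per trial
  long <- emo %>%
    select("subject_id", "trial_id", "condition", "emotional_side",
           "dwell_emotional_ms", "dwell_neutral_ms") %>%
    tidyr::pivot_longer(c("dwell_emotional_ms", "dwell_neutral_ms"),
                        names_to = "emotion", values_to = "dwell") %>%
    mutate(emotion = if_else(.data$emotion == "dwell_emotional_ms",
                             "emotional", "neutral"),
           pair = .data$condition,
           location = .data$emotional_side)

  m1 <- fit_lmm(long, dwell ~ emotion * pair * location + (1 | subject_id),
                scale_vars = "dwell")

  neu <- filter(td, .data$condition == "neutral-neutral") %>%
    select("subject_id", "trial_id", "dwell_left_ms", "dwell_right_ms") %>%
    tidyr::pivot_longer(c("dwell_left_ms", "dwell_right_ms"),
                        names_to = "location", values_to = "dwell") %>%
    mutate(location = if_else(.data$location == "dwell_left_ms",
                              "left", "right"))
  m1b <- if (nrow(neu)) {
    fit_lmm(neu, dwell ~ location + (1 | subject_id), scale_vars = "dwell")
  } else NULL

  bias <- suppressWarnings(bias_scores(td)) %>%
    left_join(traits, by = "subject_id")
  m2 <- fit_lmm(bias, bias ~ bdi * condition + (1 | subject_id),
                scale_vars = c("bias", "bdi"))

  mod_data <- if (dv == "bias") {
    rename(bias, y = "bias")
  } else {
    emo %>%
      left_join(traits, by = "subject_id") %>%
      rename(y = "dwell_emotional_ms")
  }
  fit_m3 <- function(g) {
    sub <- filter(mod_data, .data$group == g)
    if (!nrow(sub)) return(NULL)
    fit_lmm(sub, y ~ age * condition * preference + (1 | subject_id),
            scale_vars = c("y", "age", "preference"))
  }
  m3_control <- fit_m3("control")
  m3_mdd <- fit_m3("mdd")
  m4 <- fit_lmm(mod_data,
                y ~ age * condition * preference * bdi + (1 | subject_id),
                scale_vars = c("y", "age", "preference", "bdi"))

  structure(
    list(m1 = m1, m1b = m1b, m2 = m2, m3_control = m3_control,
         m3_mdd = m3_mdd, m4 = m4, dv = dv,
         data = list(long = long, neutral = neu, bias = bias,
                     moderation = mod_data)),
    class = "gazebias_suite"
  )
}

#' @export
print.gazebias_suite <- function(x, ...) {
  cat("Affective-bias model suite (DV for m3/m4:", x$dv, ")\n\n")
  for (nm in c("m1", "m1b", "m2", "m3_control", "m3_mdd", "m4")) {
    if (is.null(x[[nm]])) next
    cat("==", nm, "==\n")
    print(as.data.frame(x[[nm]]$anova_lines), row.names = FALSE, digits = 4)
    cat("\n")
  }
  invisible(x)
}
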