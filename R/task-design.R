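#' Build the 48-trial paired-image design
#'
#' Pairs a 96-image stimulus set (16 positive, 16 negative, 64 neutral) into
#' 48 free-viewing trials: 16 positive-neutral, 16 negative-neutral and 16
#' neutral-neutral pairs. Following the task's list procedure, one list holds
#' 48 randomly ordered neutral images and a second list holds the remaining
#' 16 neutral images together with all 16 positive and 16 negative images in
#' random order; trials are formed by index-wise pairing of the two lists,
#' each pair's left/right side assignment is random, and the trial order is
#' itself random. Every image is used exactly once.
#'
#' @param images A data frame of stimuli with columns `image_id` (unique) and
#'   `category` (`"positive"`, `"negative"` or `"neutral"`); exactly 16
#'   positive, 16 negative and 64 neutral rows are required.
#' @param seed Optional integer seed; the same seed reproduces the same lists.
#' @return A tibble of 48 rows with columns `trial_id` (1..48), `condition`
#'   (`positive-neutral`, `negative-neutral`, `neutral-neutral`),
#'   `left_image`, `right_image`, and `emotional_side` (`left`, `right`, or
#'   `none` for neutral-neutral pairs).
#' @examples
#' trials <- build_trial_lists(synthetic_image_set(), seed = 1)
#' dplyr::count(trials, condition)
#' @export
build_trial_lists <- function(images, seed = NULL) {
  images <- as_tibble(images)
  if (!all(c("image_id", "category") %in% names(images))) {
    abort("`images` must have columns `image_id` and `category`")
  }
  if (anyDuplicated(images$image_id)) {
    dup <- unique(images$image_id[duplicated(images$image_id)])
    abort(paste0("duplicate image_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  counts <- table(factor(images$category,
                         levels = c("positive", "negative", "neutral")))
  if (counts[["positive"]] != 16 || counts[["negative"]] != 16 ||
      counts[["neutral"]] != 64) {
    abort(sprintf(
      "need 16 positive / 16 negative / 64 neutral images, got %d/%d/%d",
      counts[["positive"]], counts[["negative"]], counts[["neutral"]]))
  }

  with_local_seed(seed, {
    neutral <- sample(images$image_id[images$category == "neutral"])
    list_a <- neutral[1:48]
    list_b <- sample(c(neutral[49:64],
                       images$image_id[images$category == "positive"],
                       images$image_id[images$category == "negative"]))
    cat_of <- setNames(images$category, images$image_id)
    trials <- tibble(
      a_image = list_a,
      b_image = list_b,
      b_category = unname(cat_of[list_b])
    ) %>%
      mutate(
        condition = dplyr::case_when(
          .data$b_category == "positive" ~ "positive-neutral",
          .data$b_category == "negative" ~ "negative-neutral",
          TRUE ~ "neutral-neutral"
        ),
        b_on_left = runif(dplyr::n()) < 0.5,
        left_image = if_else(.data$b_on_left, .data$b_image, .data$a_image),
        right_image = if_else(.data$b_on_left, .data$a_image, .data$b_image),
        emotional_side = dplyr::case_when(
          .data$condition == "neutral-neutral" ~ "none",
          .data$b_on_left ~ "left",
          TRUE ~ "right"
        )
      )
    trials <- trials[sample(nrow(trials)), ] %>%
      mutate(trial_id = row_number()) %>%
      select("trial_id", "condition", "left_image", "right_image",
             "emotional_side")
    trials
  })
}

#' Validate a stimulus set against its normative ratings
#'
#' Checks that the three image categories are dissociated on valence and
#' arousal while matched on low-level visual features, the standard
#' stimulus-set validation for affective picture tasks. For each rating
#' dimension a one-way between-category linear model is fitted and all three
#' pairwise category contrasts are tested against the pooled error term
#' (df = N - 3), with Bonferroni correction over the 3 contrasts. Low-level
#' features (any numeric columns beyond `valence`/`arousal`) get the same
#' one-way F test; the set passes the matching check when every corrected
#' low-level p-value exceeds 0.05.
#'
#' @param images A data frame with `image_id`, `category`, `valence`,
#'   `arousal` (both on the 1-9 normative scale) and optionally further
#'   numeric low-level feature columns (e.g. luminosity, contrast).
#' @return A list of class `gazebias_stimcheck` with elements `anova`
#'   (per-dimension F, df and p), `contrasts` (per-dimension pairwise
#'   estimates, t, Bonferroni-corrected p, 95% CI), `low_level` (per-feature
#'   F tests, if any) and `low_level_pass` (TRUE when all corrected
#'   low-level p > 0.05, NA when no features supplied).
#' @examples
#' validate_stimulus_set(synthetic_image_set(seed = 1))
#' @export
validate_stimulus_set <- function(images) {
  images <- as_tibble(images)
  need <- c("image_id", "category", "valence", "arousal")
  if (!all(need %in% names(images))) {
    abort(paste0("`images` must have columns: ", paste(need, collapse = ", ")))
  }
  images$category <- factor(images$category,
                            levels = c("positive", "neutral", "negative"))
  n_per <- table(images$category)
  if (any(n_per < 2)) {
    abort(paste0("need >= 2 rated images per category; short: ",
                 paste(names(n_per)[n_per < 2], collapse = ", ")))
  }
  for (dim in c("valence", "arousal")) {
    bad <- !is.na(images[[dim]]) &
      (images[[dim]] < 1 | images[[dim]] > 9)
    if (any(bad)) abort(sprintf("%s ratings outside the 1-9 scale", dim))
    miss <- tapply(is.na(images[[dim]]), images$category, all)
    if (any(miss)) {
      abort(sprintf("category %s has no %s ratings",
                    names(miss)[miss][1], dim))
    }
  }

  rate_one <- function(var) {
    y <- images[[var]]
    if (diff(range(y, na.rm = TRUE)) == 0) {
      # exactly constant ratings: no effect by definition; lm residuals
      # are floating-point dust here and would yield a garbage F ratio
      pairs <- c("positive - neutral", "positive - negative",
                 "neutral - negative")
      return(list(
        anova = tibble(dimension = var, f = 0, df1 = 2,
                       df2 = nrow(images) - 3, p = 1),
        contrasts = tibble(dimension = var, contrast = pairs, estimate = 0,
                           se = 0, df = nrow(images) - 3, t = 0,
                           p_corrected = 1, ci_lo = 0, ci_hi = 0)
      ))
    }
    fit <- lm(as.formula(paste(var, "~ category")), data = images)
    av <- anova(fit)
    f <- av$`F value`[1]
    p <- av$`Pr(>F)`[1]
    if (is.nan(f)) { f <- 0; p <- 1 }  # zero between- and within-variance
    ct <- pooled_pairwise_contrasts(fit) %>%
      mutate(t = if_else(is.nan(.data$t), 0, .data$t),
             p_corrected = if_else(is.nan(.data$p_corrected), 1,
                                   .data$p_corrected))
    list(
      anova = tibble(dimension = var, f = f,
                     df1 = av$Df[1], df2 = av$Df[2], p = p),
      contrasts = mutate(ct, dimension = var, .before = 1)
    )
  }
  val <- rate_one("valence")
  aro <- rate_one("arousal")

  feat_cols <- setdiff(names(images)[vapply(images, is.numeric, TRUE)],
                       c("valence", "arousal"))
  low_level <- NULL
  pass <- NA
  if (length(feat_cols)) {
    low_level <- purrr::map_dfr(feat_cols, function(v) {
      av <- anova(lm(as.formula(paste(v, "~ category")), data = images))
      tibble(feature = v, f = av$`F value`[1], df1 = av$Df[1],
             df2 = av$Df[2], p = av$`Pr(>F)`[1])
    }) %>%
      mutate(p_corrected = pmin(1, .data$p * length(feat_cols)))
    pass <- all(low_level$p_corrected > 0.05)
  }

  structure(
    list(
      anova = bind_rows(val$anova, aro$anova),
      contrasts = bind_rows(val$contrasts, aro$contrasts),
      low_level = low_level,
      low_level_pass = pass
    ),
    class = "gazebias_stimcheck"
  )
}

# All three pairwise category contrasts from a one-way lm, tested against
# the pooled error term (df = N - k), Bonferroni factor fixed at 3.
pooled_pairwise_contrasts <- function(fit) {
  em <- emmeans::emmeans(fit, "category")
  ct <- summary(emmeans::contrast(em, method = "pairwise"),
                adjust = "bonferroni", infer = TRUE)
  tibble(
    contrast = as.character(ct$contrast),
    estimate = ct$estimate,
    se = ct$SE,
    df = ct$df,
    t = ct$t.ratio,
    p_corrected = ct$p.value,
    ci_lo = ct$lower.CL,
    ci_hi = ct$upper.CL
  )
}

#' @export
print.gazebias_stimcheck <- function(x, ...) {
  cat("Stimulus-set validation\n\n")
  cat("Category dissociation (one-way F):\n")
  print(as.data.frame(x$anova), row.names = FALSE, digits = 4)
  cat("\nPairwise contrasts (Bonferroni x3, pooled error df):\n")
  print(as.data.frame(x$contrasts), row.names = FALSE, digits = 4)
  if (!is.null(x$low_level)) {
    cat("\nLow-level feature matching:\n")
    print(as.data.frame(x$low_level), row.names = FALSE, digits = 4)
    cat(sprintf("\nMatched on low-level features (all corrected p > 0.05): %s\n",
                x$low_level_pass))
  }
  invisible(x)
}

#' Synthetic normative stimulus table
#'
#' Generates a labelled-synthetic stand-in for a 96-image normative rating
#' table: 16 positive, 16 negative and 64 neutral items with valence and
#' arousal drawn around the category means of a typical validated affective
#' picture subset (valence 7.58 / 4.97 / 2.61 and arousal 5.24 / 4.31 / 4.85
#' for positive / neutral / negative, common SD 1), clamped to the 1-9
#' scale, plus category-free low-level features (luminosity, contrast,
#' complexity, rgb_balance).
#'
#' @param seed Optional integer seed.
#' @param rating_sd Common within-category rating SD (default 1).
#' @return A 96-row tibble with `image_id`, `category`, `valence`, `arousal`
#'   and four low-level feature columns.
#' @export
synthetic_image_set <- function(seed = NULL, rating_sd = 1) {
  with_local_seed(seed, {
    category <- rep(c("positive", "negative", "neutral"), c(16, 16, 64))
    val_mu <- c(positive = 7.58, neutral = 4.97, negative = 2.61)
    aro_mu <- c(positive = 5.24, neutral = 4.31, negative = 4.85)
    n <- length(category)
    tibble(
      image_id = sprintf("img%03d", seq_len(n)),
      category = category,
      valence = pmin(9, pmax(1, rnorm(n, val_mu[category], rating_sd))),
      arousal = pmin(9, pmax(1, rnorm(n, aro_mu[category], rating_sd))),
      luminosity = rnorm(n, 120, 15),
      contrast = rnorm(n, 50, 8),
      complexity = rnorm(n, 0.6, 0.1),
      rgb_balance = rnorm(n, 0, 0.05)
    )
  })
}
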