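#' Per-trial emotional bias scores
#'
#' For emotional (positive-neutral, negative-neutral) trials, the bias
#' score is the proportion of dwell time spent on the emotional image out
#' of the total dwell on both images; values above 0.5 indicate an
#' attentional bias toward the emotional image. Neutral-neutral trials are
#' excluded (they carry no emotional/neutral labelling), and trials with
#' zero total dwell have an undefined score and are dropped with a warning.
#'
#' @param trial_dwell A dwell table from [compute_trial_dwell()] (typically
#'   the `kept` table of [qc_exclude()]), with `condition`,
#'   `dwell_emotional_ms` and `dwell_neutral_ms` columns.
#' @return A tibble with `subject_id`, `trial_id`, `condition`, `bias`
#'   in [0, 1] and `dwell_total_ms`, one row per defined emotional trial.
#' @examples
#' td <- tibble::tibble(subject_id = "S001", trial_id = 1L,
#'                      condition = "positive-neutral",
#'                      dwell_emotional_ms = 6000, dwell_neutral_ms = 2000)
#' bias_scores(td)$bias  # 0.75
#' @export
bias_scores <- function(trial_dwell) {
  td <- as_tibble(trial_dwell) %>%
    filter(.data$condition %in% c("positive-neutral", "negative-neutral"))
  total <- td$dwell_emotional_ms + td$dwell_neutral_ms
  undefined <- is.na(total) | total <= 0
  if (any(undefined)) {
    warn(sprintf("%d trial(s) with zero total dwell dropped from bias scoring",
                 sum(undefined)))
  }
  td %>%
    mutate(dwell_total_ms = total,
           bias = .data$dwell_emotional_ms / total) %>%
    filter(!undefined) %>%
    select("subject_id", "trial_id", "condition", "bias", "dwell_total_ms")
}

#' ERQ reappraisal, suppression and preference scores
#'
#' Scores the Emotion Regulation Questionnaire per participant: the
#' reappraisal score is the mean of the six reappraisal items, the
#' suppression score the mean of the four suppression items, and the
#' preference score their difference (reappraisal minus suppression).
#' Positive preference values indicate habitual preference for
#' reappraisal, negative for suppression, zero equal endorsement.
#' Participants with any missing or out-of-range item are flagged and
#' their scores set to NA.
#'
#' @param participants A data frame with `subject_id` and item columns
#'   `erq_r1`..`erq_r6`, `erq_s1`..`erq_s4` (Likert 1-7).
#' @return A tibble with `subject_id`, `reappraisal`, `suppression`,
#'   `preference` and `erq_complete`.
#' @export
erq_scores <- function(participants) {
  p <- as_tibble(participants)
  r_items <- paste0("erq_r", 1:6)
  s_items <- paste0("erq_s", 1:4)
  missing_cols <- setdiff(c(r_items, s_items), names(p))
  if (length(missing_cols)) {
    abort(paste0("missing ERQ item columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  rm_mat <- as.matrix(p[r_items])
  sm_mat <- as.matrix(p[s_items])
  all_items <- cbind(rm_mat, sm_mat)
  ok <- apply(all_items, 1, function(v) {
    all(!is.na(v)) && all(v >= 1 & v <= 7)
  })
  if (any(!ok)) {
    warn(sprintf("%d participant(s) with missing/out-of-range ERQ items flagged",
                 sum(!ok)))
  }
  tibble(
    subject_id = p$subject_id,
    reappraisal = if_else(ok, rowMeans(rm_mat), NA_real_),
    suppression = if_else(ok, rowMeans(sm_mat), NA_real_),
    erq_complete = ok
  ) %>%
    mutate(preference = .data$reappraisal - .data$suppression) %>%
    select("subject_id", "reappraisal", "suppression", "preference",
           "erq_complete")
}

#' Compare two independent Pearson correlations (Fisher r-to-z)
#'
#' Tests whether two correlations from independent samples differ, via the
#' variance-stabilizing transform: \eqn{z = (\mathrm{atanh}\, r_1 -
#' \mathrm{atanh}\, r_2) / \sqrt{1/(n_1-3) + 1/(n_2-3)}}, with a
#' two-tailed p-value from the standard normal.
#'
#' @param r1,r2 Sample correlations, strictly inside (-1, 1).
#' @param n1,n2 Sample sizes, each at least 4.
#' @return A tibble with `r1`, `n1`, `r2`, `n2`, `z_statistic`,
#'   `p_two_tailed`.
#' @examples
#' fisher_r_to_z_test(-0.476, 44, 0, 28)  # z = -2.04, p = 0.041
#' @export
fisher_r_to_z_test <- function(r1, n1, r2, n2) {
  if (n1 <= 3 || n2 <= 3) abort("both sample sizes must exceed 3")
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    abort("correlations must be strictly inside (-1, 1)")
  }
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble(r1 = r1, n1 = n1, r2 = r2, n2 = n2,
         z_statistic = z, p_two_tailed = 2 * pnorm(-abs(z)))
}

#' Pearson correlation with a t-based two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3), each with nonzero
#'   variance; pairs with missing values are dropped.
#' @return A tibble with `r`, `n`, `t`, `df`, `p_two_tailed`. The p-value
#'   comes from \eqn{t = r\sqrt{n-2}/\sqrt{1-r^2}} on n - 2 df; a perfect
#'   correlation reports p = 0 (below the machine floor).
#' @export
pearson_with_p <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance in `x` or `y`")
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(tibble(r = r, n = n, t = sign(r) * Inf, df = n - 2,
                  p_two_tailed = 0))
  }
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  tibble(r = r, n = n, t = t, df = n - 2,
         p_two_tailed = 2 * pt(-abs(t), n - 2))
}

#' Levels of a variable at mean plus multiples of its SD
#'
#' Helper for reporting simple slopes "at +/-1 SD" of a moderator: returns
#' `mean + k * sd` for each multiplier `k`.
#'
#' @param mean,sd Center and spread (sd >= 0).
#' @param multipliers Numeric vector of SD multiples (e.g. `c(-1, 0, 1)`).
#' @return A tibble with `multiplier` and `level`.
#' @export
sd_levels <- function(mean, sd, multipliers = c(-1, 0, 1)) {
  if (sd < 0) abort("`sd` must be >= 0")
  tibble(multiplier = multipliers, level = mean + multipliers * sd)
}

#' Power of a repeated-measures within-between interaction test
#'
#' Statistical power for the group-by-measurement interaction in a
#' g-group, m-measurement repeated-measures design, under the Cohen
#' effect-size convention: \eqn{f^2 = \eta^2 / (1 - \eta^2)}, noncentrality
#' \eqn{\lambda = f^2 N}, and an F test with
#' \eqn{df_1 = (g-1)(m-1)}, \eqn{df_2 = (N-g)(m-1)}. Power is the
#' probability that a noncentral F with these df and \eqn{\lambda} exceeds
#' the central-F critical value at `alpha`. A sphericity-style
#' convention that scales \eqn{\lambda} by the number of measurements is
#' available via `lambda_convention = "n_times_m"`.
#'
#' @param eta_squared Effect size \eqn{\eta^2}, in (0, 1).
#' @param n_total Total sample size N (must exceed `n_groups`).
#' @param n_groups,n_measurements Design counts g and m (each >= 2).
#' @param alpha Test size (default 0.05).
#' @param lambda_convention `"cohen"` (default, \eqn{\lambda = f^2 N}) or
#'   `"n_times_m"` (\eqn{\lambda = f^2 N m}).
#' @return The power as a single number in (alpha, 1).
#' @examples
#' rm_interaction_power(0.12, 72, 2, 2)  # 0.87
#' @export
rm_interaction_power <- function(eta_squared, n_total, n_groups,
                                 n_measurements, alpha = 0.05,
                                 lambda_convention = c("cohen", "n_times_m")) {
  lambda_convention <- match.arg(lambda_convention)
  if (eta_squared <= 0 || eta_squared >= 1) {
    abort("`eta_squared` must be strictly between 0 and 1")
  }
  if (n_groups < 2 || n_measurements < 2 || n_total <= n_groups) {
    abort("invalid design counts: need n_groups, n_measurements >= 2 and n_total > n_groups")
  }
  f2 <- eta_squared / (1 - eta_squared)
  df1 <- (n_groups - 1) * (n_measurements - 1)
  df2 <- (n_total - n_groups) * (n_measurements - 1)
  lambda <- switch(lambda_convention,
                   cohen = f2 * n_total,
                   n_times_m = f2 * n_total * n_measurements)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = lambda, lower.tail = FALSE)
}
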