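#' Trait-sampler configuration for synthetic cohorts
#'
#' Controls the marginal distributions of the participant traits the
#' analysis conditions on: age, Beck Depression Inventory (BDI-II) sum
#' scores per group, and the 10 Emotion Regulation Questionnaire (ERQ)
#' items (6 reappraisal + 4 suppression, 1-7 Likert). ERQ items are built
#' from a latent bivariate normal per subject (reappraisal level,
#' suppression level) with a configurable within-group correlation, so the
#' control-specific negative reappraisal-suppression association and the
#' group difference in ERQ preference can both be planted.
#'
#' Defaults mirror the study population: ages 35-75; control BDI 0-8
#' (mean 1.8, SD 1.9); MDD BDI 10-47 (mean 27.3, SD 9.3); control latent
#' correlation -0.476 with a mean reappraisal preference near +2.2; MDD
#' correlation 0 with no preference.
#'
#' @param age_range Length-2 numeric, inclusive age bounds in years.
#' @param bdi_control,bdi_mdd Lists with `range`, `mean`, `sd` for the
#'   group-conditional truncated-normal BDI sampler (rounded to integers).
#' @param erq_control,erq_mdd Lists with latent `reapp_mean`, `supp_mean`,
#'   `reapp_sd`, `supp_sd`, `cor` for the per-group ERQ latent sampler.
#' @param erq_item_sd SD of the per-item noise added to the latent level
#'   before rounding/clamping to the 1-7 scale.
#' @return A named list of class `gazebias_trait_config`.
#' @export
trait_config <- function(age_range = c(35, 75),
                         bdi_control = list(range = c(0, 8),
                                            mean = 1.8, sd = 1.9),
                         bdi_mdd = list(range = c(10, 47),
                                        mean = 27.3, sd = 9.3),
                         erq_control = list(reapp_mean = 4.8, supp_mean = 2.6,
                                            reapp_sd = 1, supp_sd = 1,
                                            cor = -0.476),
                         erq_mdd = list(reapp_mean = 4.0, supp_mean = 4.0,
                                        reapp_sd = 1, supp_sd = 1,
                                        cor = 0),
                         erq_item_sd = 0.6) {
  if (age_range[1] > age_range[2]) {
    abort(sprintf("invalid `age_range`: min %s > max %s",
                  age_range[1], age_range[2]))
  }
  for (nm in c("bdi_control", "bdi_mdd")) {
    b <- get(nm)
    if (b$range[1] > b$range[2]) {
      abort(sprintf("invalid `%s$range`: min %s > max %s",
                    nm, b$range[1], b$range[2]))
    }
  }
  for (nm in c("erq_control", "erq_mdd")) {
    e <- get(nm)
    if (abs(e$cor) > 1) abort(sprintf("invalid `%s$cor`: |r| > 1", nm))
  }
  structure(
    list(age_range = age_range, bdi_control = bdi_control, bdi_mdd = bdi_mdd,
         erq_control = erq_control, erq_mdd = erq_mdd,
         erq_item_sd = erq_item_sd),
    class = "gazebias_trait_config"
  )
}

#' Generate a synthetic participant cohort
#'
#' Draws control and MDD participant profiles with ages, group-conditional
#' BDI sums and 10 ERQ item responses under a [trait_config()]. Given the
#' same seed and config the cohort is reproduced exactly.
#'
#' @param n_control,n_mdd Non-negative participant counts per group.
#' @param config A [trait_config()].
#' @param seed Optional integer seed.
#' @return A tibble with one row per participant: `subject_id`, `group`
#'   (`control`/`mdd`), `age`, `bdi_sum`, and ERQ items `erq_r1`..`erq_r6`
#'   (reappraisal) and `erq_s1`..`erq_s4` (suppression), all in 1..7.
#' @examples
#' cohort <- generate_cohort(44, 28, seed = 1)
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(n_control, n_mdd, config = trait_config(),
                            seed = NULL) {
  if (n_control < 0 || n_mdd < 0) abort("participant counts must be >= 0")
  n <- n_control + n_mdd
  with_local_seed(seed, {
    group <- rep(c("control", "mdd"), c(n_control, n_mdd))
    out <- tibble(
      subject_id = sprintf("S%03d", seq_len(n)),
      group = group,
      age = round(runif(n, config$age_range[1], config$age_range[2]), 1)
    )
    bdi <- numeric(n)
    erq <- matrix(NA_real_, n, 10)
    for (g in c("control", "mdd")) {
      idx <- which(group == g)
      if (!length(idx)) next
      bc <- config[[if (g == "control") "bdi_control" else "bdi_mdd"]]
      ec <- config[[if (g == "control") "erq_control" else "erq_mdd"]]
      bdi[idx] <- round(rtruncnorm(length(idx), bc$mean, bc$sd,
                                   bc$range[1] - 0.5, bc$range[2] + 0.499))
      bdi[idx] <- pmin(bc$range[2], pmax(bc$range[1], bdi[idx]))
      erq[idx, ] <- draw_erq_items(length(idx), ec, config$erq_item_sd)
    }
    out$bdi_sum <- as.integer(bdi)
    colnames(erq) <- c(paste0("erq_r", 1:6), paste0("erq_s", 1:4))
    dplyr::bind_cols(out, as_tibble(erq))
  })
}

# Latent bivariate-normal (reappraisal, suppression) levels -> 10 Likert
# items via per-item noise, rounding, and clamping to 1..7.
draw_erq_items <- function(n, ec, item_sd) {
  z1 <- rnorm(n)
  z2 <- ec$cor * z1 + sqrt(1 - ec$cor^2) * rnorm(n)
  reapp <- ec$reapp_mean + ec$reapp_sd * z1
  supp <- ec$supp_mean + ec$supp_sd * z2
  items <- cbind(
    matrix(rep(reapp, 6), n, 6) + matrix(rnorm(n * 6, 0, item_sd), n, 6),
    matrix(rep(supp, 4), n, 4) + matrix(rnorm(n * 4, 0, item_sd), n, 4)
  )
  matrix(pmin(7, pmax(1, round(items))), n, 10)
}

#' Standardize cohort traits for the generative model
#'
#' Adds z-scored age, BDI and ERQ preference columns (`z_age`, `z_bdi`,
#' `z_pref`), standardized across the whole cohort, plus the raw
#' `erq_preference` score. These enter the gaze generator's linear
#' predictor, mirroring the analysis-side standardization.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @return The cohort with `erq_preference`, `z_age`, `z_bdi`, `z_pref`
#'   columns appended; with a single participant, z-scores are 0.
#' @export
standardize_traits <- function(cohort) {
  scores <- erq_scores(cohort)
  cohort <- left_join(cohort, select(scores, "subject_id", erq_preference = "preference"),
                      by = "subject_id")
  zf <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    (x - mean(x)) / s
  }
  mutate(cohort,
         z_age = zf(.data$age),
         z_bdi = zf(.data$bdi_sum),
         z_pref = zf(.data$erq_preference))
}
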