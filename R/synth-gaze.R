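#' Generative coefficients for the semi-Markov gaze process
#'
#' The synthetic gaze process alternates between the two image areas of
#' interest (AOIs) in gamma-distributed dwell episodes; at each episode
#' boundary the emotional AOI is chosen with probability
#' `plogis(eta)`, where `eta` sums a baseline, the trial-condition offset,
#' and (standardized) age, ERQ-preference and BDI terms. Because episode
#' durations are independent of the chosen side, the long-run emotional
#' dwell share equals `plogis(eta)` exactly, which makes every planted
#' effect recoverable in closed form.
#'
#' Default planted effects mirror the qualitative result pattern the
#' pipeline is designed to detect: an overall emotional bias that is
#' stronger for positive than negative pairs, an age-by-preference
#' moderation of opposite sign in the two emotional conditions, and a
#' negativity bias scaling with depressive symptoms.
#'
#' @param b0 Baseline logit of the emotional-side (or, for
#'   neutral-neutral trials, left-side) dwell share.
#' @param b_pos,b_neg Condition offsets for positive-neutral and
#'   negative-neutral trials.
#' @param b_age_pos,b_age_neg Slopes of standardized age per condition.
#' @param b_agexpref_pos,b_agexpref_neg Age x ERQ-preference moderation
#'   per condition (the key planted three-way structure).
#' @param b_bdi_neg Standardized-BDI effect on negative-side dwell.
#' @param subject_sd SD of a subject-level random intercept on the logit
#'   scale (0 disables it).
#' @param episode_shape,episode_mean_ms Gamma shape and mean (ms) of
#'   within-AOI dwell episodes.
#' @param offscreen_rate Probability, at each episode boundary, of an
#'   off-AOI gap episode at the central fixation region.
#' @param latency_mean_ms,latency_sd_ms Truncated-normal parameters of the
#'   first-saccade latency (defaults 310/250 ms, the cohort-level scale at
#'   which the quality-control thresholds operate).
#' @return A named list of class `gazebias_coefficients`.
#' @export
gaze_coefficients <- function(b0 = 0,
                              b_pos = 0.3, b_neg = 0.1,
                              b_age_pos = 0, b_age_neg = 0,
                              b_agexpref_pos = 0.15, b_agexpref_neg = -0.12,
                              b_bdi_neg = 0.2,
                              subject_sd = 0.2,
                              episode_shape = 2, episode_mean_ms = 600,
                              offscreen_rate = 0.1,
                              latency_mean_ms = 310, latency_sd_ms = 250) {
  if (episode_mean_ms <= 0) abort("`episode_mean_ms` must be > 0")
  if (episode_shape <= 0) abort("`episode_shape` must be > 0")
  check_prob(offscreen_rate, "offscreen_rate", allow_one = FALSE)
  if (subject_sd < 0) abort("`subject_sd` must be >= 0")
  structure(
    list(b0 = b0, b_pos = b_pos, b_neg = b_neg,
         b_age_pos = b_age_pos, b_age_neg = b_age_neg,
         b_agexpref_pos = b_agexpref_pos, b_agexpref_neg = b_agexpref_neg,
         b_bdi_neg = b_bdi_neg, subject_sd = subject_sd,
         episode_shape = episode_shape, episode_mean_ms = episode_mean_ms,
         offscreen_rate = offscreen_rate,
         latency_mean_ms = latency_mean_ms, latency_sd_ms = latency_sd_ms),
    class = "gazebias_coefficients"
  )
}

# Linear predictor of the emotional-side choice for one subject x trial.
# z_* are cohort-standardized traits; eta_offset carries the subject
# random intercept. Neutral-neutral trials reduce to b0 (+ offset), with
# "emotional" read as "left" so the two sides stay exchangeable at b0 = 0.
gaze_eta <- function(condition, coeffs, z_age = 0, z_pref = 0, z_bdi = 0,
                     eta_offset = 0) {
  base <- coeffs$b0 + eta_offset
  switch(condition,
    "positive-neutral" = base + coeffs$b_pos + coeffs$b_age_pos * z_age +
      coeffs$b_agexpref_pos * z_age * z_pref,
    "negative-neutral" = base + coeffs$b_neg + coeffs$b_age_neg * z_age +
      coeffs$b_agexpref_neg * z_age * z_pref + coeffs$b_bdi_neg * z_bdi,
    "neutral-neutral" = base,
    abort(sprintf("unknown condition label: '%s'", condition))
  )
}

# Core per-trial simulator; returns plain vectors for speed. The public
# simulate_trial_gaze() wraps this into a tibble.
sim_trial_core <- function(eta, emotional_side, coeffs, geometry,
                           duration_ms, hz) {
  if (hz <= 0) abort("sampling rate must be > 0")
  n <- floor(duration_ms * hz / 1000)
  t_ms <- (seq_len(n) - 1) * (1000 / hz)
  period <- 1000 / hz

  latency <- rtruncnorm(1, coeffs$latency_mean_ms, coeffs$latency_sd_ms,
                        lower = period, upper = duration_ms)
  # Episode schedule from first AOI entry to trial end. States:
  # 0 = off-AOI (center), 1 = emotional side, 2 = other side.
  starts <- latency
  states <- integer(0)
  t_cur <- latency
  scale <- coeffs$episode_mean_ms / coeffs$episode_shape
  p_emo <- stats::plogis(eta)
  repeat {
    off <- runif(1) < coeffs$offscreen_rate
    state <- if (off) 0L else if (runif(1) < p_emo) 1L else 2L
    dur <- if (off) rgamma(1, coeffs$episode_shape, scale = scale / 2)
           else rgamma(1, coeffs$episode_shape, scale = scale)
    states <- c(states, state)
    t_cur <- t_cur + dur
    if (t_cur >= duration_ms) break
    starts <- c(starts, t_cur)
  }

  ep <- findInterval(t_ms, starts)        # 0 = pre-latency center period
  state <- c(0L, states)[ep + 1L]

  emo_is_left <- !identical(emotional_side, "right")  # none/left -> left
  side <- ifelse(state == 0L, "center",
                 ifelse((state == 1L) == emo_is_left, "left", "right"))

  lr <- geometry$left_rect
  rr <- geometry$right_rect
  cx <- (lr[3] + rr[1]) / 2
  cy <- (lr[2] + lr[4]) / 2
  # One fixation point per episode, small per-sample jitter inside the AOI.
  n_ep <- length(starts)
  fx <- runif(n_ep + 1)
  fy <- runif(n_ep + 1)
  ex <- fx[ep + 1L]
  ey <- fy[ep + 1L]
  x <- numeric(n)
  y <- numeric(n)
  left <- side == "left"
  right <- side == "right"
  ctr <- side == "center"
  pad <- 12
  x[left] <- lr[1] + pad + ex[left] * (lr[3] - lr[1] - 2 * pad)
  y[left] <- lr[2] + pad + ey[left] * (lr[4] - lr[2] - 2 * pad)
  x[right] <- rr[1] + pad + ex[right] * (rr[3] - rr[1] - 2 * pad)
  y[right] <- rr[2] + pad + ey[right] * (rr[4] - rr[2] - 2 * pad)
  # Center-cross region sits strictly between the two AOIs.
  half_gap <- max(1, (rr[1] - lr[3]) / 2 - 4)
  x[ctr] <- cx + (ex[ctr] - 0.5) * 2 * half_gap
  y[ctr] <- cy + (ey[ctr] - 0.5) * 40
  jit <- 3
  x <- x + runif(n, -jit, jit)
  y <- y + runif(n, -jit, jit)
  # keep jittered AOI samples inside their rectangle (half-open bounds)
  x[left] <- pmin(lr[3] - 0.1, pmax(lr[1], x[left]))
  y[left] <- pmin(lr[4] - 0.1, pmax(lr[2], y[left]))
  x[right] <- pmin(rr[3] - 0.1, pmax(rr[1], x[right]))
  y[right] <- pmin(rr[4] - 0.1, pmax(rr[2], y[right]))

  list(t_ms = t_ms, x_px = round(x, 1), y_px = round(y, 1),
       valid = rep(TRUE, n))
}

#' Simulate one trial's raw gaze stream
#'
#' Generates a 60 Hz gaze sample sequence for one participant viewing one
#' image pair. Samples begin on the central fixation cross; after a drawn
#' first-saccade latency, gaze alternates between the two AOIs in
#' gamma-distributed episodes, choosing the emotional AOI at each episode
#' boundary with probability `plogis(eta)` (see [gaze_coefficients()]).
#' Off-AOI gap episodes return gaze to the central cross region.
#'
#' @param profile A one-row data frame with at least `subject_id`;
#'   optionally `z_age`, `z_bdi`, `z_pref` (see [standardize_traits()]) and
#'   `eta_offset` (subject random intercept). Missing ones default to 0.
#' @param trial A one-row data frame with `trial_id`, `condition`,
#'   `emotional_side`.
#' @param coeffs A [gaze_coefficients()] object.
#' @param seed Optional integer seed.
#' @param geometry An [aoi_geometry()].
#' @param duration_ms Trial duration (default 10,000 ms).
#' @param hz Sampling rate (default 60; must be positive).
#' @return A tibble of gaze samples with columns `subject_id`, `trial_id`,
#'   `t_ms`, `x_px`, `y_px`, `valid`.
#' @examples
#' prof <- tibble::tibble(subject_id = "S001")
#' tr <- tibble::tibble(trial_id = 1L, condition = "positive-neutral",
#'                      emotional_side = "left")
#' g <- simulate_trial_gaze(prof, tr, gaze_coefficients(), seed = 1)
#' nrow(g)  # 600 samples = 10 s at 60 Hz
#' @export
simulate_trial_gaze <- function(profile, trial, coeffs = gaze_coefficients(),
                                seed = NULL, geometry = aoi_geometry(),
                                duration_ms = 10000, hz = 60) {
  getz <- function(nm) if (nm %in% names(profile)) profile[[nm]][1] else 0
  eta <- gaze_eta(trial$condition[1], coeffs,
                  z_age = getz("z_age"), z_pref = getz("z_pref"),
                  z_bdi = getz("z_bdi"), eta_offset = getz("eta_offset"))
  with_local_seed(seed, {
    s <- sim_trial_core(eta, trial$emotional_side[1], coeffs, geometry,
                        duration_ms, hz)
    tibble(subject_id = profile$subject_id[1], trial_id = trial$trial_id[1],
           t_ms = s$t_ms, x_px = s$x_px, y_px = s$y_px, valid = s$valid)
  })
}

#' Simulate a full cohort's gaze study
#'
#' Chains the cohort trait sampler, per-participant randomized trial lists
#' and the per-trial gaze simulator into the complete synthetic study: for
#' every participant a fresh 48-trial list is built from the image set and
#' each trial's 10 s gaze stream is generated under the planted
#' coefficients, with traits standardized across the cohort and a
#' subject-level random intercept drawn from `coeffs$subject_sd`.
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param coeffs A [gaze_coefficients()].
#' @param images A stimulus table for [build_trial_lists()] (default
#'   [synthetic_image_set()]).
#' @param seed Optional integer seed covering list building and gaze noise.
#' @param geometry,duration_ms,hz Passed to the trial simulator.
#' @return A list with tibbles `samples` (all gaze samples), `trials`
#'   (per-participant trial lists with `subject_id`) and `participants`
#'   (the cohort with standardized traits and `eta_offset`).
#' @export
simulate_cohort_gaze <- function(cohort, coeffs = gaze_coefficients(),
                                 images = NULL, seed = NULL,
                                 geometry = aoi_geometry(),
                                 duration_ms = 10000, hz = 60) {
  with_local_seed(seed, {
    if (is.null(images)) images <- synthetic_image_set()
    cohort <- standardize_traits(cohort)
    cohort$eta_offset <- rnorm(nrow(cohort), 0, coeffs$subject_sd)

    trials <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      mutate(build_trial_lists(images),
             subject_id = cohort$subject_id[i], .before = 1)
    })

    parts <- split(trials, trials$subject_id)
    samples <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
      p <- cohort[i, ]
      tr <- parts[[p$subject_id]]
      per_trial <- lapply(seq_len(nrow(tr)), function(j) {
        eta <- gaze_eta(tr$condition[j], coeffs, z_age = p$z_age,
                        z_pref = p$z_pref, z_bdi = p$z_bdi,
                        eta_offset = p$eta_offset)
        sim_trial_core(eta, tr$emotional_side[j], coeffs, geometry,
                       duration_ms, hz)
      })
      ns <- vapply(per_trial, function(s) length(s$t_ms), 1L)
      tibble(
        subject_id = p$subject_id,
        trial_id = rep(tr$trial_id, ns),
        t_ms = unlist(lapply(per_trial, `[[`, "t_ms")),
        x_px = unlist(lapply(per_trial, `[[`, "x_px")),
        y_px = unlist(lapply(per_trial, `[[`, "y_px")),
        valid = rep(TRUE, sum(ns))
      )
    })
    list(samples = samples, trials = trials, participants = cohort)
  })
}

#' Acquisition-artifact specification
#'
#' Rates of the tracking failure modes the quality-control stage is
#' designed to catch: per-sample dropout (invalid samples), trials whose
#' first recorded sample already sits inside an AOI, trials with an
#' inflated first-saccade latency, and truncated trials with a low sample
#' count.
#'
#' @param dropout_rate Per-sample probability of an invalid sample.
#' @param p_start_in_aoi Per-trial probability the first sample is moved
#'   inside a (random) AOI.
#' @param p_slow_latency Per-trial probability of an inflated latency;
#'   `slow_latency_ms` is the forced first-AOI-entry time.
#' @param p_short_trial Per-trial probability of truncation to
#'   `short_fraction` of its samples.
#' @param slow_latency_ms,short_fraction Artifact magnitudes.
#' @param rng_seed Integer seed making the injection reproducible.
#' @return A named list of class `gazebias_artifact_spec`.
#' @export
artifact_spec <- function(dropout_rate = 0, p_start_in_aoi = 0,
                          p_slow_latency = 0, p_short_trial = 0,
                          slow_latency_ms = 3000, short_fraction = 0.4,
                          rng_seed = NULL) {
  check_prob(dropout_rate, "dropout_rate")
  check_prob(p_start_in_aoi, "p_start_in_aoi")
  check_prob(p_slow_latency, "p_slow_latency")
  check_prob(p_short_trial, "p_short_trial")
  structure(
    list(dropout_rate = dropout_rate, p_start_in_aoi = p_start_in_aoi,
         p_slow_latency = p_slow_latency, p_short_trial = p_short_trial,
         slow_latency_ms = slow_latency_ms, short_fraction = short_fraction,
         rng_seed = rng_seed),
    class = "gazebias_artifact_spec"
  )
}

#' Inject tracking artifacts into a gaze sample table
#'
#' Degrades clean gaze streams with the failure modes in [artifact_spec()]
#' and returns a ground-truth manifest of what was injected where, so
#' quality-control exclusions can be tested against known corruption.
#' All rates zero is an exact no-op.
#'
#' @param samples A gaze sample tibble (`subject_id`, `trial_id`, `t_ms`,
#'   `x_px`, `y_px`, `valid`), time-ordered within trial.
#' @param spec An [artifact_spec()].
#' @param geometry The [aoi_geometry()] used to place start-in-AOI samples.
#' @return A list with `samples` (degraded table) and `manifest` (tibble
#'   `subject_id`, `trial_id`, `artifact` with one row per injected
#'   trial-level artifact).
#' @export
inject_artifacts <- function(samples, spec, geometry = aoi_geometry()) {
  stopifnot(inherits(spec, "gazebias_artifact_spec"))
  manifest <- tibble(subject_id = character(), trial_id = integer(),
                     artifact = character())
  if (spec$dropout_rate == 0 && spec$p_start_in_aoi == 0 &&
      spec$p_slow_latency == 0 && spec$p_short_trial == 0) {
    return(list(samples = samples, manifest = manifest))
  }
  with_local_seed(spec$rng_seed, {
    samples <- arrange(samples, .data$subject_id, .data$trial_id, .data$t_ms)
    keys <- distinct(samples, .data$subject_id, .data$trial_id)
    nt <- nrow(keys)
    keys$start_in_aoi <- runif(nt) < spec$p_start_in_aoi
    keys$slow_latency <- runif(nt) < spec$p_slow_latency
    keys$short_trial <- runif(nt) < spec$p_short_trial

    if (spec$dropout_rate > 0) {
      samples$valid <- samples$valid & (runif(nrow(samples)) >= spec$dropout_rate)
    }

    samples <- left_join(samples, keys, by = c("subject_id", "trial_id"))
    grp <- samples %>% group_by(.data$subject_id, .data$trial_id)

    lr <- geometry$left_rect
    rr <- geometry$right_rect
    cx <- (lr[3] + rr[1]) / 2
    cy <- (lr[2] + lr[4]) / 2

    samples <- grp %>%
      mutate(.row = row_number(), .n = dplyr::n()) %>%
      ungroup() %>%
      mutate(
        # truncate short trials
        .keep_row = !.data$short_trial |
          .data$.row <= ceiling(spec$short_fraction * .data$.n),
        # force a slow first AOI entry by parking early samples at center
        .center = .data$slow_latency & .data$t_ms < spec$slow_latency_ms,
        x_px = if_else(.data$.center, cx + runif(dplyr::n(), -20, 20), .data$x_px),
        y_px = if_else(.data$.center, cy + runif(dplyr::n(), -15, 15), .data$y_px),
        valid = .data$valid | .data$.center  # parked samples stay recorded
      )
    # relocate the first sample of start-in-aoi trials into an AOI interior
    first_rows <- samples$.row == 1 & samples$start_in_aoi
    n1 <- sum(first_rows)
    if (n1) {
      use_left <- runif(n1) < 0.5
      u <- runif(n1); v <- runif(n1)
      samples$x_px[first_rows] <- ifelse(
        use_left, lr[1] + 10 + u * (lr[3] - lr[1] - 20),
        rr[1] + 10 + u * (rr[3] - rr[1] - 20))
      samples$y_px[first_rows] <- lr[2] + 10 + v * (lr[4] - lr[2] - 20)
      samples$valid[first_rows] <- TRUE
    }

    manifest <- keys %>%
      tidyr::pivot_longer(c("start_in_aoi", "slow_latency", "short_trial"),
                          names_to = "artifact", values_to = ".on") %>%
      filter(.data$.on) %>%
      select("subject_id", "trial_id", "artifact")

    samples <- samples %>%
      filter(.data$.keep_row) %>%
      select("subject_id", "trial_id", "t_ms", "x_px", "y_px", "valid")
    list(samples = samples, manifest = manifest)
  })
}
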