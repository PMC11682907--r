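#' Area-of-interest geometry
#'
#' The two image rectangles against which gaze coordinates are classified,
#' on a 1280 x 1024 screen. Each image occupies 576 x 346 px; by default
#' the rectangles are horizontally centered in their screen half and
#' vertically centered at y = 512, leaving a central strip for the
#' fixation cross. Rectangles are half-open: a point belongs to a
#' rectangle when `x0 <= x < x1` and `y0 <= y < y1`, which gives edge
#' samples a deterministic assignment.
#'
#' @param left_rect,right_rect Numeric length-4 vectors `(x0, y0, x1, y1)`.
#' @param screen_px Screen size `(width, height)`.
#' @return A list of class `gazebias_aoi_geometry`.
#' @export
aoi_geometry <- function(left_rect = c(32, 339, 608, 685),
                         right_rect = c(672, 339, 1248, 685),
                         screen_px = c(1280, 1024)) {
  chk <- function(r, nm) {
    if (length(r) != 4 || r[1] >= r[3] || r[2] >= r[4]) {
      abort(sprintf("`%s` must be (x0, y0, x1, y1) with x0 < x1, y0 < y1", nm))
    }
    if (r[1] < 0 || r[2] < 0 || r[3] > screen_px[1] || r[4] > screen_px[2]) {
      abort(sprintf("`%s` extends beyond the %g x %g screen",
                    nm, screen_px[1], screen_px[2]))
    }
  }
  chk(left_rect, "left_rect")
  chk(right_rect, "right_rect")
  overlap <- left_rect[1] < right_rect[3] && right_rect[1] < left_rect[3] &&
    left_rect[2] < right_rect[4] && right_rect[2] < left_rect[4]
  if (overlap) abort("AOI rectangles must be disjoint")
  structure(list(left_rect = left_rect, right_rect = right_rect,
                 screen_px = screen_px),
            class = "gazebias_aoi_geometry")
}

#' Quality-control thresholds for dwell extraction
#'
#' @param gap_ms Bin-split threshold: successive same-AOI samples separated
#'   by `gap_ms` or more start a new bin. 33 ms is the standard 60 Hz value
#'   (two or more missed sample periods); 66 and 133 ms are the degraded
#'   timing-precision dialects.
#' @param min_bin_ms Minimum bin duration (last minus first timestamp) for
#'   a bin to count toward dwell time; default 100 ms.
#' @param latency_sd_mult,samples_sd_mult Cohort-level exclusion
#'   multipliers: a trial is dropped when its first-saccade latency exceeds
#'   the cohort mean + `latency_sd_mult` SD, or its sample count falls
#'   below the cohort mean - `samples_sd_mult` SD.
#' @param max_trial_loss_fraction A participant is dropped when more than
#'   this fraction of their trials is excluded (default 1/3).
#' @param count_invalid Whether invalid-but-recorded samples count toward
#'   the per-trial sample total (default FALSE).
#' @return A list of class `gazebias_qc_thresholds`.
#' @export
qc_thresholds <- function(gap_ms = 33, min_bin_ms = 100,
                          latency_sd_mult = 3, samples_sd_mult = 3,
                          max_trial_loss_fraction = 1 / 3,
                          count_invalid = FALSE) {
  if (!gap_ms %in% c(33, 66, 133)) {
    abort("`gap_ms` must be one of 33, 66, 133")
  }
  if (min_bin_ms <= 0) abort("`min_bin_ms` must be > 0")
  structure(
    list(gap_ms = gap_ms, min_bin_ms = min_bin_ms,
         latency_sd_mult = latency_sd_mult,
         samples_sd_mult = samples_sd_mult,
         max_trial_loss_fraction = max_trial_loss_fraction,
         count_invalid = count_invalid),
    class = "gazebias_qc_thresholds"
  )
}

#' Classify gaze samples into areas of interest
#'
#' Adds an `aoi` column (`"left"`, `"right"`, `"none"`) to a gaze sample
#' table. A sample is assigned to an AOI when its coordinates fall inside
#' that rectangle under the half-open convention (low edge inclusive, high
#' edge exclusive); invalid samples are always `"none"`.
#'
#' @param samples A data frame with `x_px`, `y_px` and optionally `valid`.
#' @param geometry An [aoi_geometry()].
#' @return The input tibble with an `aoi` column appended.
#' @export
assign_aoi <- function(samples, geometry = aoi_geometry()) {
  samples <- as_tibble(samples)
  lr <- geometry$left_rect
  rr <- geometry$right_rect
  in_rect <- function(r) {
    samples$x_px >= r[1] & samples$x_px < r[3] &
      samples$y_px >= r[2] & samples$y_px < r[4]
  }
  aoi <- if_else(in_rect(lr), "left", if_else(in_rect(rr), "right", "none"))
  if ("valid" %in% names(samples)) aoi[!samples$valid] <- "none"
  aoi[is.na(aoi)] <- "none"
  mutate(samples, aoi = aoi)
}

#' Group in-AOI samples into gap-tolerant dwell bins
#'
#' Forms maximal runs of successive same-AOI samples: a new bin starts
#' whenever the AOI changes, an off-AOI sample intervenes, or the time
#' since the previous valid sample reaches `gap_ms`. Invalid samples are
#' treated as absent (they widen the gap between their valid neighbours).
#' Bin duration is the last minus the first member timestamp, so a
#' single-sample bin has duration 0.
#'
#' @param samples Gaze samples for one or more trials (`subject_id`,
#'   `trial_id`, `t_ms`, `x_px`, `y_px`, `valid`), time-sorted within
#'   trial; an `aoi` column is computed if absent.
#' @param thresholds A [qc_thresholds()].
#' @param geometry An [aoi_geometry()], used when `aoi` must be computed.
#' @return A tibble of bins: `subject_id`, `trial_id`, `aoi`,
#'   `t_start_ms`, `t_end_ms`, `n_samples`, `duration_ms`.
#' @export
bin_samples <- function(samples, thresholds = qc_thresholds(),
                        geometry = aoi_geometry()) {
  samples <- as_tibble(samples)
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  if (!"subject_id" %in% names(samples)) samples$subject_id <- "S001"
  if (!"aoi" %in% names(samples)) samples <- assign_aoi(samples, geometry)

  unsorted <- samples %>%
    group_by(.data$subject_id, .data$trial_id) %>%
    summarise(bad = is.unsorted(.data$t_ms), .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(unsorted)) {
    abort(sprintf("timestamps not sorted within trial (e.g. subject %s trial %s)",
                  unsorted$subject_id[1], unsorted$trial_id[1]))
  }

  gap <- thresholds$gap_ms
  samples %>%
    filter(.data$valid) %>%
    group_by(.data$subject_id, .data$trial_id) %>%
    mutate(
      .new_bin = row_number() == 1 |
        .data$aoi != lag(.data$aoi) |
        (.data$t_ms - lag(.data$t_ms)) >= gap,
      .bin = cumsum(.data$.new_bin)
    ) %>%
    group_by(.data$subject_id, .data$trial_id, .data$.bin) %>%
    summarise(
      aoi = first(.data$aoi),
      t_start_ms = first(.data$t_ms),
      t_end_ms = last(.data$t_ms),
      n_samples = dplyr::n(),
      .groups = "drop"
    ) %>%
    filter(.data$aoi != "none") %>%
    mutate(duration_ms = .data$t_end_ms - .data$t_start_ms) %>%
    select(-".bin")
}

#' Keep only bins long enough to count toward dwell time
#'
#' Retains bins whose duration (last minus first timestamp) is at least
#' `min_bin_ms`; the boundary is inclusive, so a bin spanning exactly
#' 100 ms survives the default filter. Order is preserved.
#'
#' @param bins A bin tibble from [bin_samples()].
#' @param min_bin_ms Minimum duration in ms (default 100).
#' @return The filtered bin tibble.
#' @export
filter_bins <- function(bins, min_bin_ms = 100) {
  filter(bins, .data$duration_ms >= min_bin_ms)
}

#' Per-trial AOI dwell times, latency and QC quantities
#'
#' Composes AOI assignment, gap-tolerant binning and the minimum-duration
#' filter into one dwell record per trial: summed left/right dwell, the
#' emotional/neutral relabelling via the trial's emotional side, the
#' first-saccade latency (timestamp of the first valid in-AOI sample), the
#' per-trial sample count, and the start-in-AOI flag (first recorded
#' sample already inside an AOI). Trials present in `trials` but absent
#' from `samples` yield all-zero dwell rows.
#'
#' @param samples A gaze sample table covering one or more subjects.
#' @param trials The trial table (`trial_id`, `condition`,
#'   `emotional_side`, and `subject_id` when trial lists are
#'   per-participant).
#' @param geometry An [aoi_geometry()].
#' @param thresholds A [qc_thresholds()].
#' @return A tibble with one row per subject x trial: dwell per side and
#'   per emotion role (ms), `first_saccade_latency_ms` (NA when gaze never
#'   entered an AOI), `n_samples_total`, and `start_in_aoi`.
#' @export
compute_trial_dwell <- function(samples, trials,
                                geometry = aoi_geometry(),
                                thresholds = qc_thresholds()) {
  samples <- as_tibble(samples)
  trials <- as_tibble(trials)
  if (!"valid" %in% names(samples)) samples$valid <- TRUE
  if (!"subject_id" %in% names(samples)) samples$subject_id <- "S001"
  by_subject <- "subject_id" %in% names(trials)
  if (!by_subject) trials$subject_id <- unique(samples$subject_id)[1]

  samples <- assign_aoi(samples, geometry)
  bins <- bin_samples(samples, thresholds, geometry) %>%
    filter_bins(thresholds$min_bin_ms)

  dwell <- bins %>%
    group_by(.data$subject_id, .data$trial_id) %>%
    summarise(
      dwell_left_ms = sum(.data$duration_ms[.data$aoi == "left"]),
      dwell_right_ms = sum(.data$duration_ms[.data$aoi == "right"]),
      .groups = "drop"
    )

  per_trial <- samples %>%
    group_by(.data$subject_id, .data$trial_id) %>%
    summarise(
      n_samples_total = if (thresholds$count_invalid) dplyr::n()
                        else sum(.data$valid),
      first_saccade_latency_ms = {
        t_in <- .data$t_ms[.data$aoi != "none"]
        if (length(t_in)) t_in[1] else NA_real_
      },
      start_in_aoi = .data$aoi[1] != "none",
      .groups = "drop"
    )

  out <- trials %>%
    select(any_of(c("subject_id", "trial_id", "condition",
                    "emotional_side"))) %>%
    left_join(per_trial, by = c("subject_id", "trial_id")) %>%
    left_join(dwell, by = c("subject_id", "trial_id")) %>%
    mutate(
      n_samples_total = dplyr::coalesce(.data$n_samples_total, 0L),
      start_in_aoi = dplyr::coalesce(.data$start_in_aoi, FALSE),
      dwell_left_ms = dplyr::coalesce(.data$dwell_left_ms, 0),
      dwell_right_ms = dplyr::coalesce(.data$dwell_right_ms, 0),
      dwell_emotional_ms = dplyr::case_when(
        .data$emotional_side == "left" ~ .data$dwell_left_ms,
        .data$emotional_side == "right" ~ .data$dwell_right_ms,
        TRUE ~ NA_real_
      ),
      dwell_neutral_ms = dplyr::case_when(
        .data$emotional_side == "left" ~ .data$dwell_right_ms,
        .data$emotional_side == "right" ~ .data$dwell_left_ms,
        TRUE ~ NA_real_
      )
    )
  out
}

#' Cohort-level trial and participant exclusions
#'
#' Applies the two-pass quality-control rule: first, the cohort mean and
#' SD of first-saccade latency and of per-trial sample count are computed
#' over all trials of all participants pooled; second, a trial is excluded
#' when its first recorded sample was already inside an AOI, its latency
#' exceeds the cohort mean + 3 SD (trials that never entered an AOI count
#' here too), or its sample count falls below the cohort mean - 3 SD. A
#' participant is excluded when more than a third of their trials are
#' excluded. A zero-variance cohort statistic excludes nothing on that
#' criterion.
#'
#' @param trial_dwell A dwell table from [compute_trial_dwell()].
#' @param thresholds A [qc_thresholds()].
#' @return A list of class `gazebias_qc` with `kept` (surviving dwell
#'   rows), `excluded_trials` (with logical reason columns `start_in_aoi`,
#'   `slow_latency`, `low_sample_count`), `excluded_subjects`, and `stats`
#'   (cohort means, SDs and the derived cutoffs).
#' @export
qc_exclude <- function(trial_dwell, thresholds = qc_thresholds()) {
  td <- as_tibble(trial_dwell)
  lat <- td$first_saccade_latency_ms
  if (sum(!is.na(lat)) < 2) {
    abort("need >= 2 trials with a defined first-saccade latency")
  }
  lat_mean <- mean(lat, na.rm = TRUE)
  lat_sd <- sd(lat, na.rm = TRUE)
  ns_mean <- mean(td$n_samples_total)
  ns_sd <- sd(td$n_samples_total)
  lat_limit <- if (lat_sd > 0) lat_mean + thresholds$latency_sd_mult * lat_sd
               else Inf
  ns_floor <- if (ns_sd > 0) ns_mean - thresholds$samples_sd_mult * ns_sd
              else -Inf

  flagged <- td %>%
    mutate(
      slow_latency = is.na(.data$first_saccade_latency_ms) |
        .data$first_saccade_latency_ms > lat_limit,
      low_sample_count = .data$n_samples_total < ns_floor,
      excluded = .data$start_in_aoi | .data$slow_latency |
        .data$low_sample_count
    )

  subj <- flagged %>%
    group_by(.data$subject_id) %>%
    summarise(n_trials = dplyr::n(), n_excluded = sum(.data$excluded),
              loss_fraction = .data$n_excluded / .data$n_trials,
              .groups = "drop") %>%
    mutate(subject_excluded =
             .data$loss_fraction > thresholds$max_trial_loss_fraction)

  flagged <- left_join(
    flagged, select(subj, "subject_id", "subject_excluded"),
    by = "subject_id")

  structure(
    list(
      kept = flagged %>%
        filter(!.data$excluded, !.data$subject_excluded) %>%
        select(-"excluded", -"subject_excluded"),
      excluded_trials = flagged %>%
        filter(.data$excluded) %>%
        select(-"excluded", -"subject_excluded"),
      excluded_subjects = filter(subj, .data$subject_excluded),
      subject_summary = subj,
      stats = tibble(
        latency_mean_ms = lat_mean, latency_sd_ms = lat_sd,
        latency_limit_ms = lat_limit,
        n_samples_mean = ns_mean, n_samples_sd = ns_sd,
        n_samples_floor = ns_floor
      )
    ),
    class = "gazebias_qc"
  )
}

#' @export
print.gazebias_qc <- function(x, ...) {
  cat("Gaze quality control\n")
  cat(sprintf("  trials kept:      %d\n", nrow(x$kept)))
  cat(sprintf("  trials excluded:  %d\n", nrow(x$excluded_trials)))
  cat(sprintf("  subjects dropped: %d\n", nrow(x$excluded_subjects)))
  cat(sprintf("  latency cutoff:   %.0f ms (cohort mean %.0f, SD %.0f)\n",
              x$stats$latency_limit_ms, x$stats$latency_mean_ms,
              x$stats$latency_sd_ms))
  cat(sprintf("  sample floor:     %.0f (cohort mean %.0f, SD %.0f)\n",
              x$stats$n_samples_floor, x$stats$n_samples_mean,
              x$stats$n_samples_sd))
  invisible(x)
}
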