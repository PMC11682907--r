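test_that("AOI assignment follows the half-open rectangle convention", {
  geo <- aoi_geometry()
  lr <- geo$left_rect
  rr <- geo$right_rect
  pts <- tibble::tibble(
    x_px = c((lr[3] + rr[1]) / 2, mean(lr[c(1, 3)]), rr[1], lr[3], rr[3]),
    y_px = c(512, mean(lr[c(2, 4)]), 512, 512, 512),
    valid = TRUE
  )
  out <- assign_aoi(pts, geo)
  expect_equal(out$aoi, c("none",   # fixation cross between the images
                          "left",   # centroid of the left rectangle
                          "right",  # low-x edge of the right rect: inclusive
                          "none",   # high-x edge of the left rect: exclusive
                          "none"))  # high-x edge of the right rect: exclusive

  # invalid samples are never in an AOI
  inv <- assign_aoi(tibble::tibble(x_px = mean(lr[c(1, 3)]),
                                   y_px = mean(lr[c(2, 4)]), valid = FALSE),
                    geo)
  expect_equal(inv$aoi, "none")

  # brute-force agreement on random points
  set.seed(31)
  rnd <- tibble::tibble(x_px = runif(500, 0, 1280),
                        y_px = runif(500, 0, 1024),
                        valid = runif(500) > 0.1)
  got <- assign_aoi(rnd, geo)$aoi
  want <- mapply(oracle_assign_aoi, rnd$x_px, rnd$y_px, rnd$valid,
                 MoreArgs = list(geometry = geo))
  expect_equal(got, unname(want))
})

test_that("binning splits on gaps, AOI changes and off-AOI samples", {
  # hand trace: left samples at 0/17/33/100 ms with the 33 ms rule
  s <- make_trial_samples(c(0, 17, 33, 100), rep("left", 4))
  bins <- bin_samples(s, qc_thresholds(gap_ms = 33))
  expect_equal(nrow(bins), 2)
  expect_equal(bins$t_start_ms, c(0, 100))
  expect_equal(bins$t_end_ms, c(33, 100))
  expect_equal(bins$n_samples, c(3L, 1L))
  expect_equal(bins$duration_ms, c(33, 0))

  # alternating sides: every bin is a singleton
  alt <- make_trial_samples((0:19) * 1000 / 60,
                            rep(c("left", "right"), 10))
  expect_true(all(bin_samples(alt, qc_thresholds())$n_samples == 1L))

  # one unbroken 60 Hz run spans (600 - 1) sample periods
  run <- make_trial_samples((0:599) * 1000 / 60, rep("left", 600))
  b <- bin_samples(run, qc_thresholds())
  expect_equal(nrow(b), 1)
  expect_equal(b$duration_ms, 599 * 1000 / 60, tolerance = 1e-9)

  # unsorted timestamps are a contract violation
  bad <- make_trial_samples(c(0, 40, 20), rep("left", 3))
  expect_error(bin_samples(bad, qc_thresholds()), "not sorted")
})

test_that("binning agrees with the sample-walking oracle on random streams", {
  set.seed(77)
  geo <- aoi_geometry()
  for (i in 1:25) {
    s <- random_trial_samples(n = 200, trial_id = i)
    s$valid[sample(nrow(s), 8)] <- FALSE
    got <- bin_samples(s, qc_thresholds(), geo)
    aoi <- assign_aoi(s, geo)$aoi
    want <- oracle_bin(s$t_ms, aoi, s$valid, 33)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$aoi, want$aoi)
    expect_equal(got$t_start_ms, want$t_start_ms)
    expect_equal(got$t_end_ms, want$t_end_ms)
    expect_equal(got$n_samples, want$n_samples)
    # partition: every valid in-AOI sample lands in exactly one bin
    expect_equal(sum(got$n_samples), sum(s$valid & aoi != "none"))
  }
})

test_that("the 100 ms duration filter is boundary-inclusive", {
  bins <- tibble::tibble(subject_id = "S001", trial_id = 1L,
                         aoi = "left",
                         t_start_ms = c(0, 0, 200),
                         t_end_ms = c(33, 100, 350),
                         n_samples = c(3L, 7L, 10L)) |>
    dplyr::mutate(duration_ms = t_end_ms - t_start_ms)
  kept <- filter_bins(bins, 100)
  expect_equal(kept$duration_ms, c(100, 150))
  expect_equal(nrow(filter_bins(bins[0, ], 100)), 0)
})

test_that("raising the gap dialect can only merge bins", {
  set.seed(78)
  for (i in 1:10) {
    s <- random_trial_samples(n = 250, trial_id = i)
    counts <- sapply(c(33, 66, 133), function(g) {
      nrow(bin_samples(s, qc_thresholds(gap_ms = g)))
    })
    expect_true(all(diff(counts) <= 0))
    totals <- sapply(c(33, 66, 133), function(g) {
      sum(bin_samples(s, qc_thresholds(gap_ms = g))$duration_ms)
    })
    expect_true(all(diff(totals) >= -1e-9))
  }
})

test_that("trial dwell composes the rules and relabels by emotional side", {
  # a single surviving left bin 500..7300 ms on a positive-left trial
  s <- make_trial_samples(c(0, seq(500, 7300, by = 1000 / 60)),
                          c("center", rep("left", length(seq(500, 7300,
                                                             by = 1000 / 60)))))
  trial <- tibble::tibble(subject_id = "S001", trial_id = 1L,
                          condition = "positive-neutral",
                          emotional_side = "left")
  td <- compute_trial_dwell(s, trial)
  expect_equal(td$dwell_emotional_ms, 6800)
  expect_equal(td$dwell_neutral_ms, 0)
  expect_equal(td$first_saccade_latency_ms, 500)
  expect_false(td$start_in_aoi)

  # all samples off-AOI: zero dwell, undefined latency
  off <- make_trial_samples((0:99) * 1000 / 60, rep("center", 100))
  td2 <- compute_trial_dwell(off, trial)
  expect_equal(td2$dwell_left_ms + td2$dwell_right_ms, 0)
  expect_true(is.na(td2$first_saccade_latency_ms))

  # a trial with no samples at all still yields a zero row
  trials2 <- dplyr::bind_rows(trial,
                              dplyr::mutate(trial, trial_id = 2L))
  td3 <- compute_trial_dwell(s, trials2)
  expect_equal(nrow(td3), 2)
  expect_equal(td3$n_samples_total[td3$trial_id == 2L], 0L)
  expect_equal(td3$dwell_left_ms[td3$trial_id == 2L], 0)
})

test_that("sample-count dwell upper-bounds binned dwell and respects duration", {
  set.seed(79)
  geo <- aoi_geometry()
  for (i in 1:15) {
    s <- random_trial_samples(n = 400, trial_id = i)
    trial <- tibble::tibble(subject_id = "S001", trial_id = i,
                            condition = "negative-neutral",
                            emotional_side = "right")
    td <- compute_trial_dwell(s, trial)
    total <- td$dwell_left_ms + td$dwell_right_ms
    aoi <- assign_aoi(s, geo)$aoi
    brute <- sum(s$valid & aoi != "none") * 1000 / 60
    expect_lte(total, brute + 1e-9)
    expect_lte(total, max(s$t_ms))

    # dropping samples never increases dwell
    s2 <- s[-sample(nrow(s), 50), ]
    td_sub <- compute_trial_dwell(s2, trial)
    expect_lte(td_sub$dwell_left_ms + td_sub$dwell_right_ms, total + 1e-9)
  }
})

test_that("cohort QC excludes by latency, sample count and trial-loss fraction", {
  # latency pool constructed to have mean 310 and SD 250 exactly
  set.seed(80)
  n <- 400
  lat <- as.numeric(scale(rnorm(n))) * 250 + 310
  td <- tibble::tibble(
    subject_id = rep(sprintf("P%02d", 1:10), each = 40),
    trial_id = rep(1:40, times = 10),
    condition = "positive-neutral",
    emotional_side = "left",
    n_samples_total = 600L,
    first_saccade_latency_ms = lat,
    start_in_aoi = FALSE,
    dwell_left_ms = 5000, dwell_right_ms = 2000,
    dwell_emotional_ms = 5000, dwell_neutral_ms = 2000
  )
  td$first_saccade_latency_ms[1] <- 1200  # beyond mean + 3 SD (~1060)
  td$first_saccade_latency_ms[2] <- 900   # inside the limit
  qc <- qc_exclude(td)
  # the two planted values shift the pooled stats only slightly
  expect_gt(qc$stats$latency_limit_ms, 1000)
  expect_lt(qc$stats$latency_limit_ms, 1150)
  expect_gt(1200, qc$stats$latency_limit_ms)
  expect_lt(900, qc$stats$latency_limit_ms)
  expect_true(1 %in% qc$excluded_trials$trial_id[
    qc$excluded_trials$subject_id == "P01"])
  flagged_2 <- qc$excluded_trials$subject_id == "P01" &
    qc$excluded_trials$trial_id == 2
  expect_false(any(flagged_2))

  # a subject whose every trial starts in an AOI loses > 33% and is dropped
  td2 <- td
  td2$start_in_aoi[td2$subject_id == "P05"] <- TRUE
  qc2 <- qc_exclude(td2)
  expect_true("P05" %in% qc2$excluded_subjects$subject_id)
  expect_false("P05" %in% qc2$kept$subject_id)

  # artifact-free: no start-in-AOI exclusions
  expect_equal(sum(qc$excluded_trials$start_in_aoi), 0)

  # degenerate cohort variance excludes nothing on that criterion
  td3 <- td
  td3$first_saccade_latency_ms <- 310
  qc3 <- qc_exclude(td3)
  expect_equal(nrow(qc3$excluded_trials), 0)

  expect_error(qc_exclude(td[1, ]), "defined first-saccade latency")
})
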