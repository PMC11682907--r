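# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, direct formulas) so they cannot share bugs
# with the vectorised implementations they check.

# Loop-based point-in-rectangle check, half-open on the high edges.
oracle_in_rect <- function(x, y, r) {
  x >= r[1] && x < r[3] && y >= r[2] && y < r[4]
}

oracle_assign_aoi <- function(x, y, valid, geometry) {
  if (!valid) return("none")
  if (oracle_in_rect(x, y, geometry$left_rect)) return("left")
  if (oracle_in_rect(x, y, geometry$right_rect)) return("right")
  "none"
}

# One-sample-at-a-time binner: walk the valid samples in time order,
# closing the open bin on an AOI change, an off-AOI sample, or a gap of
# gap_ms or more. Returns a data frame of bins (pre-filter).
oracle_bin <- function(t_ms, aoi, valid, gap_ms) {
  bins <- list()
  cur <- NULL
  for (i in seq_along(t_ms)) {
    if (!valid[i]) next
    a <- aoi[i]
    if (a == "none") { if (!is.null(cur)) { bins <- c(bins, list(cur)); cur <- NULL }; next }
    if (!is.null(cur) &&
        (cur$aoi != a || (t_ms[i] - cur$t_end) >= gap_ms)) {
      bins <- c(bins, list(cur)); cur <- NULL
    }
    if (is.null(cur)) {
      cur <- list(aoi = a, t_start = t_ms[i], t_end = t_ms[i], n = 1L)
    } else {
      cur$t_end <- t_ms[i]; cur$n <- cur$n + 1L
    }
  }
  if (!is.null(cur)) bins <- c(bins, list(cur))
  if (!length(bins)) {
    return(data.frame(aoi = character(), t_start_ms = numeric(),
                      t_end_ms = numeric(), n_samples = integer(),
                      duration_ms = numeric()))
  }
  data.frame(
    aoi = vapply(bins, `[[`, "", "aoi"),
    t_start_ms = vapply(bins, `[[`, 0, "t_start"),
    t_end_ms = vapply(bins, `[[`, 0, "t_end"),
    n_samples = vapply(bins, function(b) as.integer(b$n), 1L),
    duration_ms = vapply(bins, function(b) b$t_end - b$t_start, 0)
  )
}

# Build a one-trial sample table from timestamps and screen positions
# named by region ("left", "right", "center").
make_trial_samples <- function(t_ms, region, valid = TRUE,
                               subject_id = "S001", trial_id = 1L,
                               geometry = aoi_geometry()) {
  lr <- geometry$left_rect
  rr <- geometry$right_rect
  pos <- list(
    left = c(mean(lr[c(1, 3)]), mean(lr[c(2, 4)])),
    right = c(mean(rr[c(1, 3)]), mean(rr[c(2, 4)])),
    center = c((lr[3] + rr[1]) / 2, mean(lr[c(2, 4)]))
  )
  xy <- t(vapply(region, function(r) pos[[r]], numeric(2)))
  tibble::tibble(
    subject_id = subject_id, trial_id = trial_id, t_ms = t_ms,
    x_px = xy[, 1], y_px = xy[, 2],
    valid = rep_len(valid, length(t_ms))
  )
}

# Random AOI-region stream for property tests: regular 60 Hz timestamps
# with random dropped samples and random left/right/center regions.
random_trial_samples <- function(n = 300, trial_id = 1L,
                                 subject_id = "S001") {
  keep <- runif(n) > 0.1
  t_ms <- ((seq_len(n) - 1) * 1000 / 60)[keep]
  region <- sample(c("left", "right", "center"), sum(keep),
                   replace = TRUE, prob = c(0.4, 0.4, 0.2))
  make_trial_samples(t_ms, region, subject_id = subject_id,
                     trial_id = trial_id)
}

# Pair of vectors with an exact sample Pearson correlation r.
vectors_with_r <- function(r, n) {
  x <- rnorm(n)
  y0 <- rnorm(n)
  x <- as.numeric(scale(x))
  e <- stats::residuals(stats::lm(y0 ~ x))
  e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}

# Direct pooled-error two-group t for a one-way design: the hand formula
# t = (m1 - m2) / sqrt(MSE * (1/n1 + 1/n2)) with df = N - k.
oracle_pooled_t <- function(values, groups, g1, g2) {
  k <- length(unique(groups))
  ms <- tapply(values, groups, mean)
  sse <- sum((values - ms[groups])^2)
  df <- length(values) - k
  mse <- sse / df
  n <- table(groups)
  est <- ms[[g1]] - ms[[g2]]
  list(estimate = est,
       t = est / sqrt(mse * (1 / n[[g1]] + 1 / n[[g2]])),
       df = df)
}
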