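# Tab-separated I/O with provenance headers. TSV (not CSV) avoids locale
# decimal-comma ambiguity; all times are milliseconds in files.

PIPELINE_COLUMNS <- list(
  samples = c("subject_id", "trial_id", "t_ms", "x_px", "y_px", "valid"),
  trials = c("subject_id", "trial_id", "condition", "left_image",
             "right_image", "emotional_side"),
  participants = c("subject_id", "group", "age", "bdi_sum",
                   paste0("erq_r", 1:6), paste0("erq_s", 1:4)),
  manifest = c("subject_id", "trial_id", "artifact"),
  trial_dwell = c("subject_id", "trial_id", "condition", "emotional_side",
                  "n_samples_total", "first_saccade_latency_ms",
                  "start_in_aoi", "dwell_left_ms", "dwell_right_ms",
                  "dwell_emotional_ms", "dwell_neutral_ms"),
  bias = c("subject_id", "trial_id", "condition", "bias", "dwell_total_ms"),
  scores = c("subject_id", "reappraisal", "suppression", "preference",
             "erq_complete")
)

# Cheap polynomial rolling hash of a string; provenance fingerprint only.
content_hash <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 1000000007
  sprintf("%08x", h)
}

#' Write a pipeline table as TSV with a provenance header
#'
#' Writes `#`-prefixed provenance comment lines (package version, seed,
#' config hash) followed by a tab-separated table. Paired readers skip the
#' comment lines.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param seed Seed recorded in the header (may be NULL).
#' @param config_hash Optional config hash string.
#' @return `path`, invisibly.
#' @export
write_pipeline_tsv <- function(x, path, seed = NULL, config_hash = NULL) {
  ver <- as.character(utils::packageVersion("gazebias"))
  hdr <- c(sprintf("# gazebias %s", ver),
           sprintf("# seed: %s", seed %||% "NA"),
           if (!is.null(config_hash)) sprintf("# config: %s", config_hash))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline TSV, validating its columns
#'
#' @param path Input path.
#' @param kind One of `"samples"`, `"trials"`, `"participants"`,
#'   `"manifest"`, `"trial_dwell"`, `"bias"`, `"scores"`, or NULL to skip
#'   column validation.
#' @return A tibble.
#' @export
read_pipeline_tsv <- function(path, kind = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  if (!is.null(kind)) {
    expected <- PIPELINE_COLUMNS[[kind]]
    if (is.null(expected)) abort(sprintf("unknown table kind '%s'", kind))
    miss <- setdiff(expected, names(x))
    if (length(miss)) {
      abort(sprintf(
        "%s: malformed %s table; missing column(s) %s (expected header: %s)",
        path, kind, paste(miss, collapse = ", "),
        paste(expected, collapse = "\t")))
    }
  }
  x
}

#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline: cohort sizes, the
#' generative coefficients and artifact rates of the simulator, AOI
#' geometry, QC thresholds, model options, the output directory and the
#' seed for every source of randomness. `pipeline_config()` builds it from
#' defaults; `read_pipeline_config()` loads a YAML file whose keys override
#' the defaults (nested keys `coefficients:`, `artifacts:`, `thresholds:`
#' map to the corresponding constructor arguments).
#'
#' @param n_control,n_mdd Cohort sizes (defaults 44 and 28).
#' @param seed Integer seed.
#' @param out_dir Output directory for pipeline artifacts.
#' @param coefficients A [gaze_coefficients()].
#' @param artifacts An [artifact_spec()].
#' @param geometry An [aoi_geometry()].
#' @param thresholds A [qc_thresholds()].
#' @param traits A [trait_config()].
#' @param dv `"dwell"` or `"bias"` for the moderation models.
#' @param bdi_ranges Named list of raw-scale BDI averaging ranges for the
#'   depression follow-up contrast.
#' @return A list of class `gazebias_config`.
#' @export
pipeline_config <- function(n_control = 44, n_mdd = 28, seed = 1,
                            out_dir = "gazebias-output",
                            coefficients = gaze_coefficients(),
                            artifacts = artifact_spec(),
                            geometry = aoi_geometry(),
                            thresholds = qc_thresholds(),
                            traits = trait_config(),
                            dv = "dwell",
                            bdi_ranges = list(control = c(0, 8),
                                              mdd = c(10, 47))) {
  structure(
    list(n_control = n_control, n_mdd = n_mdd, seed = seed,
         out_dir = out_dir, coefficients = coefficients,
         artifacts = artifacts, geometry = geometry,
         thresholds = thresholds, traits = traits, dv = dv,
         bdi_ranges = bdi_ranges),
    class = "gazebias_config"
  )
}

#' @rdname pipeline_config
#' @param path Path to a YAML config file.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (nm in c("n_control", "n_mdd", "seed", "out_dir", "dv")) {
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  }
  if (!is.null(y$coefficients)) {
    args$coefficients <- do.call(gaze_coefficients, y$coefficients)
  }
  if (!is.null(y$artifacts)) {
    args$artifacts <- do.call(artifact_spec, y$artifacts)
  }
  if (!is.null(y$thresholds)) {
    args$thresholds <- do.call(qc_thresholds, y$thresholds)
  }
  if (!is.null(y$geometry)) args$geometry <- do.call(aoi_geometry, y$geometry)
  if (!is.null(y$traits)) args$traits <- do.call(trait_config, y$traits)
  if (!is.null(y$bdi_ranges)) args$bdi_ranges <- y$bdi_ranges
  do.call(pipeline_config, args)
}

config_hash <- function(config) {
  content_hash(paste(deparse(config[setdiff(names(config), "out_dir")]),
              collapse = ""))
}

#' Run the full analysis pipeline
#'
#' Chains the stages simulate -> preprocess -> score -> analyze -> report
#' under one configuration and seed. Each stage writes its tables (TSV
#' with provenance headers) into `config$out_dir`; re-running with the
#' same config reproduces them byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @param stages Character vector of stages to run; `"all"` (default)
#'   runs the full chain.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the stage outputs: `cohort`, `trials`,
#'   `samples`, `manifest`, `dwell`, `qc`, `bias`, `scores`, `suite`,
#'   `followups`.
#' @export
run_pipeline <- function(config = pipeline_config(), stages = "all",
                         quiet = FALSE) {
  stopifnot(inherits(config, "gazebias_config"))
  all_stages <- c("simulate", "preprocess", "score", "analyze", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) {
    abort(paste0("unknown stage(s): ", paste(bad, collapse = ", "),
                 "; valid: ", paste(all_stages, collapse = ", ")))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  seed <- config$seed
  say <- function(...) if (!quiet) message(sprintf(...))
  wtsv <- function(x, name) {
    write_pipeline_tsv(x, file.path(config$out_dir, paste0(name, ".tsv")),
                       seed = seed, config_hash = hash)
  }
  rtsv <- function(name, kind) {
    read_pipeline_tsv(file.path(config$out_dir, paste0(name, ".tsv")), kind)
  }
  out <- list()

  if ("simulate" %in% stages) {
    say("simulate: %d control + %d mdd participants (seed %s)",
        config$n_control, config$n_mdd, seed)
    cohort <- generate_cohort(config$n_control, config$n_mdd,
                              config$traits, seed = seed)
    sim <- simulate_cohort_gaze(cohort, config$coefficients,
                                seed = seed + 1L,
                                geometry = config$geometry)
    spec <- config$artifacts
    spec$rng_seed <- spec$rng_seed %||% (seed + 2L)
    art <- inject_artifacts(sim$samples, spec, config$geometry)
    out$cohort <- sim$participants
    out$trials <- sim$trials
    out$samples <- art$samples
    out$manifest <- art$manifest
    wtsv(select(out$cohort, all_of(PIPELINE_COLUMNS$participants)),
         "participants")
    wtsv(select(out$trials, all_of(PIPELINE_COLUMNS$trials)), "trials")
    wtsv(out$samples, "samples")
    wtsv(out$manifest, "artifact_manifest")
    say("simulate: wrote %d samples over %d trials",
        nrow(out$samples), nrow(out$trials))
  }

  if ("preprocess" %in% stages) {
    samples <- out$samples %||% rtsv("samples", "samples")
    trials <- out$trials %||% rtsv("trials", "trials")
    dwell <- compute_trial_dwell(samples, trials, config$geometry,
                                 config$thresholds)
    qc <- qc_exclude(dwell, config$thresholds)
    out$dwell <- dwell
    out$qc <- qc
    wtsv(select(dwell, all_of(PIPELINE_COLUMNS$trial_dwell)), "trial_dwell")
    wtsv(select(qc$kept, all_of(PIPELINE_COLUMNS$trial_dwell)), "dwell_kept")
    wtsv(qc$stats, "qc_stats")
    say("preprocess: %d/%d trials kept, %d subject(s) excluded",
        nrow(qc$kept), nrow(dwell), nrow(qc$excluded_subjects))
  }

  if ("score" %in% stages) {
    kept <- out$qc$kept %||% rtsv("dwell_kept", "trial_dwell")
    participants <- out$cohort %||% rtsv("participants", "participants")
    out$bias <- suppressWarnings(bias_scores(kept))
    out$scores <- erq_scores(participants)
    wtsv(out$bias, "bias")
    wtsv(out$scores, "erq_scores")
    say("score: %d bias trials, %d scored participants",
        nrow(out$bias), nrow(out$scores))
  }

  if ("analyze" %in% stages) {
    kept <- out$qc$kept %||% rtsv("dwell_kept", "trial_dwell")
    participants <- out$cohort %||% rtsv("participants", "participants")
    suite <- run_model_suite(kept, participants, dv = config$dv)
    followups <- list()
    followups$bdi_contrasts <- bind_rows(lapply(
      names(config$bdi_ranges), function(g) {
        emmeans_over_range(suite$m2, "condition", "bdi",
                           config$bdi_ranges[[g]],
                           label = sprintf("condition contrast, %s BDI range", g))
      }))
    if (!is.null(suite$m3_control)) {
      followups$age_slopes_control <-
        age_slopes_at_levels(suite$m3_control)
    }
    scores <- out$scores %||% erq_scores(participants)
    corr <- participants %>%
      left_join(scores, by = "subject_id") %>%
      group_by(.data$group) %>%
      summarise(test = list(pearson_with_p(.data$reappraisal,
                                           .data$suppression)),
                .groups = "drop") %>%
      tidyr::unnest("test")
    if (all(c("control", "mdd") %in% corr$group)) {
      ctl <- filter(corr, .data$group == "control")
      mdd <- filter(corr, .data$group == "mdd")
      followups$erq_correlation_comparison <-
        fisher_r_to_z_test(ctl$r, ctl$n, mdd$r, mdd$n)
    }
    followups$erq_correlations <- corr
    out$suite <- suite
    out$followups <- followups
  }

  if ("report" %in% stages) {
    if (is.null(out$suite)) abort("report stage requires the analyze stage")
    report <- suite_report(out$suite, out$followups)
    wtsv(report, "model_report")
    txt <- file.path(config$out_dir, "summary.txt")
    lines <- utils::capture.output({
      cat(sprintf("gazebias pipeline summary (seed %s, config %s)\n\n",
                  seed, hash))
      print(out$suite)
      cat("\nFollow-ups\n==========\n")
      for (nm in names(out$followups)) {
        cat("\n--", nm, "--\n")
        print(as.data.frame(out$followups[[nm]]), row.names = FALSE,
              digits = 4)
      }
    })
    writeLines(lines, txt)
    say("report: wrote %s and model_report.tsv", txt)
  }

  invisible(out)
}

# Flatten a suite + follow-ups into one term-per-row report table,
# p-values rounded to 3 decimals for display parity with the text output.
suite_report <- function(suite, followups = list()) {
  rows <- purrr::map_dfr(
    c("m1", "m1b", "m2", "m3_control", "m3_mdd", "m4"),
    function(nm) {
      f <- suite[[nm]]
      if (is.null(f)) return(NULL)
      bind_rows(
        mutate(f$anova_lines, model = nm, kind = "anova",
               estimate = NA_real_, se = NA_real_,
               ci_lo = NA_real_, ci_hi = NA_real_, t = NA_real_),
        mutate(f$fixed_effects, model = nm, kind = "coef",
               f = NA_real_, df1 = NA_real_, df2 = NA_real_)
      )
    })
  extra <- purrr::map_dfr(names(followups), function(nm) {
    x <- followups[[nm]]
    if (!is.data.frame(x)) return(NULL)
    x <- mutate(x, model = nm, kind = "followup")
    x
  })
  out <- bind_rows(rows, extra)
  if ("p" %in% names(out)) out$p <- round(out$p, 3)
  out
}
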