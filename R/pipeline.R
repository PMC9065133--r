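#' End-to-end run configuration
#'
#' Bundles everything one run needs: which salt-condition presets to
#' simulate, how many fields per condition, the field geometry, the
#' detection and filtering parameters, an output directory and the root
#' seed. Every default equals the printed acquisition value where one
#' exists (0.78 um aperture, 14.5 contrast, denoise 5, 0.48 um ball,
#' 200 arb. unit Cy3 cutoff, 5 Hz, 900 frames, 16 sites).
#'
#' @param presets Character vector of [condition_preset()] names.
#' @param n_fields Fields of view per condition.
#' @param sim_overrides Named list of [sim_config()] overrides applied to
#'   every preset (e.g. `list(n_frames = 300)` for a shorter movie).
#' @param field A [field_config()].
#' @param detection A [detection_params()].
#' @param filters A [filter_params()].
#' @param out_dir Output directory (created on run) or `NULL` to skip
#'   writing files.
#' @param seed Integer root seed.
#' @return A `run_config` list.
#' @export
run_config <- function(presets = salt_series(),
                       n_fields = 3L,
                       sim_overrides = list(),
                       field = field_config(),
                       detection = detection_params(),
                       filters = filter_params(),
                       out_dir = NULL,
                       seed = 1L) {
  stopifnot(inherits(field, "field_config"),
            inherits(detection, "detection_params"),
            inherits(filters, "filter_params"))
  structure(
    list(presets = presets, n_fields = as.integer(n_fields),
         sim_overrides = sim_overrides, field = field,
         detection = detection, filters = filters,
         out_dir = out_dir, seed = as.integer(seed)),
    class = "run_config"
  )
}

config_digest <- function(config) {
  # small stable digest of the config echo, recorded in the run log
  txt <- yaml::as.yaml(config_echo(config))
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 251 + 1)) %% 1e9
}

config_echo <- function(config) {
  list(
    presets = as.list(config$presets),
    n_fields = config$n_fields,
    sim_overrides = config$sim_overrides,
    field = unclass(config$field),
    detection = unclass(config$detection),
    filters = unclass(config$filters),
    seed = config$seed
  )
}

#' Run the full simulate - process - count - summarize pipeline
#'
#' For each condition preset, simulates `n_fields` two-channel fields,
#' processes the Cy3 snapshots (denoise, rolling-ball background
#' subtraction, bright-spot detection on the temporal mean), extracts a
#' Surf649 trace at every detected intasome, applies the exclusion chain
#' and counts photobleaching steps, then aggregates per-condition
#' box-whisker statistics. With an `out_dir` set, writes `traces.csv`
#' (long format: one row per spot-frame), `counts.csv`, `summary.json`,
#' a `config.yaml` echo and `run.log`; re-running with an identical
#' config reproduces every output bit for bit.
#'
#' @param config A [run_config()].
#' @return A `bleach_run` list: `counts` (per-spot tibble), `summary`
#'   (a [summarize_conditions()] tibble; conditions whose cohort came out
#'   empty are reported in `empty_conditions` instead), `traces`,
#'   `detections`, `log` (character), `config`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- sprintf("run seed %d, config digest %d",
                       config$seed, config_digest(config))
  all_traces <- list()
  all_detections <- list()
  for (ci in seq_along(config$presets)) {
    preset <- config$presets[ci]
    sim <- do.call(condition_preset, c(list(name = preset),
                                       config$sim_overrides))
    for (fi in seq_len(config$n_fields)) {
      fseed <- substream_seed(config$seed, ci * 100000L + fi)
      fld <- simulate_field(sim, config$field, seed = fseed)
      cy3_dn <- denoise(fld$cy3, config$detection$denoise_strength)
      surf_dn <- denoise(fld$surf649, config$detection$denoise_strength)
      # rolling-ball flattening feeds detection only; photometry uses its
      # own local annulus background on the denoised frames, which keeps
      # spot flux linear in the underlying fluorophore count
      cy3_flat <- subtract_background(
        stack_mean(cy3_dn),
        config$detection$rolling_ball_radius_um, cy3_dn$pixel_size_um)
      spots <- detect_spots(cy3_flat, config$detection,
                            pixel_size_um = cy3_dn$pixel_size_um)
      log_lines <- c(log_lines, sprintf(
        "%s field %d: %d true spots, %d detected", preset, fi,
        nrow(fld$truth), nrow(spots)))
      if (nrow(spots) == 0L) next
      traces <- extract_traces(surf_dn, cy3_dn, spots, config$detection)
      traces$condition <- sim$condition
      traces$spot_id <- sprintf("%s_f%d_s%d", preset, fi, traces$spot_id)
      all_traces[[length(all_traces) + 1L]] <- traces
      spots$field <- fi
      spots$condition <- sim$condition
      all_detections[[length(all_detections) + 1L]] <- spots
    }
  }
  traces <- dplyr::bind_rows(all_traces)
  detections <- dplyr::bind_rows(all_detections)

  counts <- if (nrow(traces) > 0L) {
    count_steps(traces, config$filters)
  } else {
    tibble(spot_id = character(), condition = character(),
           k_steps = integer(), step_size_estimate = numeric(),
           sigma_hat = numeric(),
           exclusion_reason = factor(levels = c(
             "none", "edge_clipped", "bright_cy3", "unstable",
             "zero_steps")),
           included = logical())
  }

  summaries <- list()
  empty_conditions <- character()
  for (cond in unique(counts$condition)) {
    sub <- counts[counts$condition == cond, , drop = FALSE]
    s <- tryCatch(summarize_conditions(sub),
                  bleachsteps_empty_cohort = function(e) NULL)
    if (is.null(s)) {
      empty_conditions <- c(empty_conditions, cond)
      log_lines <- c(log_lines, sprintf("%s: empty cohort", cond))
    } else {
      summaries[[length(summaries) + 1L]] <- s
    }
  }
  # every condition configured but yielding no traces at all is empty too
  configured <- vapply(config$presets, function(p) {
    condition_preset(p)$condition
  }, character(1))
  missing <- setdiff(configured, unique(counts$condition))
  empty_conditions <- c(empty_conditions, missing)
  summary <- if (length(summaries) > 0L) {
    dplyr::bind_rows(summaries)
  } else NULL

  for (r in levels(counts$exclusion_reason)) {
    log_lines <- c(log_lines, sprintf(
      "excluded %s: %d", r, sum(counts$exclusion_reason == r &
                                  r != "none")))
  }
  log_lines <- c(log_lines, sprintf(
    "included %d of %d traces", sum(counts$included), nrow(counts)))

  result <- structure(
    list(counts = counts, summary = summary,
         empty_conditions = empty_conditions,
         traces = traces, detections = detections,
         log = log_lines, config = config),
    class = "bleach_run"
  )
  if (!is.null(config$out_dir)) write_run(result, config$out_dir)
  result
}

#' @export
print.bleach_run <- function(x, ...) {
  cat("<bleach_run>\n")
  cat(sprintf("  %d traces, %d included\n",
              nrow(x$counts), sum(x$counts$included)))
  if (!is.null(x$summary)) {
    s <- x$summary
    for (i in seq_len(nrow(s))) {
      cat(sprintf("  %s: n = %d, mean %.2f, median %.1f steps\n",
                  s$condition[i], s$n_included[i], s$mean[i], s$median[i]))
    }
  }
  if (length(x$empty_conditions) > 0) {
    cat("  empty cohorts:", paste(x$empty_conditions, collapse = ", "), "\n")
  }
  invisible(x)
}

write_run <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  config <- result$config
  yaml::write_yaml(config_echo(config), file.path(out_dir, "config.yaml"))
  writeLines(result$log, file.path(out_dir, "run.log"))
  if (nrow(result$traces) > 0L) {
    long <- tidyr::unnest(
      dplyr::mutate(
        result$traces[, c("spot_id", "condition", "cy3_intensity",
                          "intensity", "time_s")],
        frame = purrr::map(.data$intensity, ~ seq_along(.x) - 1L)
      ),
      c("frame", "time_s", "intensity")
    )
    long <- long[, c("spot_id", "condition", "frame", "time_s",
                     "intensity", "cy3_intensity")]
    names(long)[names(long) == "intensity"] <- "surf649_intensity"
    utils::write.csv(long, file.path(out_dir, "traces.csv"),
                     row.names = FALSE)
  } else {
    writeLines("spot_id,condition,frame,time_s,surf649_intensity,cy3_intensity",
               file.path(out_dir, "traces.csv"))
  }
  counts_out <- result$counts[, c("spot_id", "condition", "k_steps",
                                  "exclusion_reason",
                                  "step_size_estimate")]
  utils::write.csv(counts_out, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  summary_list <- list(
    conditions = if (is.null(result$summary)) list() else
      lapply(seq_len(nrow(result$summary)), function(i) {
        row <- result$summary[i, ]
        list(condition = row$condition, n_included = row$n_included,
             n_excluded = list(edge_clipped = row$n_edge_clipped,
                               bright_cy3 = row$n_bright_cy3,
                               unstable = row$n_unstable,
                               zero_steps = row$n_zero_steps),
             mean = row$mean, median = row$median,
             q25 = row$q25, q75 = row$q75, p10 = row$p10, p90 = row$p90,
             max_count = row$max_count,
             outliers = row$outliers[[1]])
      }),
    empty_conditions = as.list(result$empty_conditions)
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
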