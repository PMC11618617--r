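#' Pointwise mean and standard error of cohort trajectories
#'
#' The trajectory summary behind mean-deviation-over-time figures: at every
#' grid point, the cohort mean deviation and its standard error
#' (`sd / sqrt(n)`) per axis and speed condition.
#'
#' @param traces Cohort tibble of aligned preprocessed traces.
#' @param axes Channels to summarise.
#' @return A `trajectory_summary` tibble: `speed`, `axis`, `time`, `mean`,
#'   `sem`, `n`.
#' @export
trajectory_summary <- function(traces, axes = c("pitch", "yaw", "roll")) {
  axes <- intersect(axes, names(traces))
  if (length(axes) == 0) abort_inference("No angle channels found in traces")
  if (!"speed" %in% names(traces)) traces$speed <- "all"
  if ("excluded" %in% names(traces)) {
    traces <- dplyr::filter(traces, !.data$excluded)
  }
  out <- purrr::map_dfr(split(traces, traces$speed), function(layer) {
    purrr::map_dfr(axes, function(axis) {
      mat <- cohort_matrix(layer, axis)
      n <- ncol(mat$values)
      if (n < 2) {
        abort_inference("Trajectory summary needs at least 2 traces")
      }
      mu <- rowMeans(mat$values)
      sem <- sqrt(rowSums((mat$values - mu)^2) / (n - 1)) / sqrt(n)
      tibble(speed = layer$speed[1], axis = axis, time = mat$time,
             mean = mu, sem = sem, n = n)
    })
  })
  structure(out, class = c("trajectory_summary", class(out)))
}

#' Format the conformity summary as a fixed-width text table
#'
#' One row per axis and speed with the one-sample t-test against zero, the
#' mean correlation to the normative (leave-one-out median) motion, and its
#' SD. Significant tests (p below `alpha`) are starred.
#'
#' @param summary A [summarize_conformity()] result.
#' @param alpha Significance threshold for starring.
#' @return A character vector of report lines.
#' @export
format_conformity_report <- function(summary, alpha = 0.05) {
  header <- sprintf("%-6s %-6s %10s %12s %8s %6s", "Axis", "Speed",
                    "t(df)", "p", "Mean r", "SD")
  lines <- purrr::pmap_chr(summary, function(axis, speed, n, mean_r, sd_r,
                                             t, df, p) {
    sprintf("%-6s %-6s %10s %12s %8.2f %6.2f",
            axis, speed, sprintf("%.2f(%d)", t, df),
            paste0(format.pval(p, digits = 3, eps = 1e-4),
                   ifelse(!is.na(p) && p < alpha, " *", "")),
            mean_r, sd_r)
  })
  c("Conformity to normative head motion (one-sample t vs 0)",
    header, lines)
}

#' Format the conformity-rating association table as text
#'
#' @param table A [conformity_association_table()] result.
#' @return A character vector of report lines; significant cells are
#'   starred.
#' @export
format_association_report <- function(table) {
  alpha <- attr(table, "alpha") %||% 0.05
  wide <- table |>
    dplyr::mutate(cell = ifelse(
      .data$insufficient_n, "(n<3)",
      sprintf("%5.2f%s", .data$r,
              ifelse(!is.na(.data$significant) & .data$significant,
                     "*", " "))
    )) |>
    dplyr::select("dv", "speed", "axis", "cell") |>
    tidyr::pivot_wider(names_from = "axis", values_from = "cell")
  header <- sprintf("%-10s %-6s %8s %8s %8s", "Measure", "Speed",
                    "pitch", "yaw", "roll")
  lines <- purrr::pmap_chr(wide, function(dv, speed, pitch, yaw, roll) {
    sprintf("%-10s %-6s %8s %8s %8s", dv, speed, pitch, yaw, roll)
  })
  c(sprintf(
    "Correlation between conformity and ratings (* = p < %g)", alpha
  ), header, lines)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      abort_config(sprintf("Config file not found: '%s'", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort_config("Config must be a list or a YAML path")
  io <- config$io
  if (is.null(io$lap_duration)) {
    abort_config("Config is missing io: lap_duration")
  }
  if (is.null(io$rate)) abort_config("Config is missing io: rate")
  if (is.null(config$synthetic) && is.null(io$data_dir)) {
    abort_config("Config must declare either io: data_dir or a synthetic: block")
  }
  config
}

build_synthetic_input <- function(config) {
  syn <- config$synthetic
  track_args <- utils::modifyList(
    list(lap_duration = config$io$lap_duration, rate = config$io$rate),
    syn$track %||% list()
  )
  track <- do.call(track_config, track_args)
  experiments <- syn$experiments %||% c(1, 2)
  sizes <- syn$n_participants %||% list()
  cohorts <- purrr::imap(experiments, function(exp, i) {
    generate_cohort(cohort_config(
      experiment = exp,
      n_participants = sizes[[as.character(exp)]] %||%
        (if (exp == 1) 52 else 36),
      seed = substream_seed(syn$seed %||% 1L, 0L, 100L + i),
      track = track,
      head_population = syn$head_population %||% list()
    ))
  })
  if (length(cohorts) == 1) {
    c(cohorts[[1]][c("traces", "records", "vehicle")],
      list(ground_truth = cohorts[[1]]$ground_truth))
  } else {
    c(do.call(combine_cohorts, cohorts),
      list(ground_truth = purrr::map(cohorts, "ground_truth")))
  }
}

read_cohort_input <- function(config) {
  dir <- config$io$data_dir
  records <- read_trial_records(file.path(dir, "trial_records.csv"),
                                lap_duration = config$io$lap_duration)
  vehicle <- dplyr::bind_rows(purrr::map(c("slow", "fast"), function(sp) {
    read_vehicle_trace(file.path(dir, sprintf("vehicle_%s.csv", sp)),
                       speed = sp)
  }))
  head_files <- list.files(dir, pattern = "^head_.*\\.csv$",
                           full.names = TRUE)
  if (length(head_files) == 0) {
    abort_data(sprintf("No head_<participant>_<speed>.csv files in '%s'", dir))
  }
  traces <- purrr::map_dfr(head_files, function(f) {
    parts <- strsplit(sub("\\.csv$", "", basename(f)), "_")[[1]]
    speed <- parts[length(parts)]
    pid <- paste(parts[-c(1, length(parts))], collapse = "_")
    read_head_motion_log(f, participant_id = pid) |>
      tibble::add_column(speed = speed)
  })
  list(traces = traces, records = records, vehicle = vehicle,
       ground_truth = NULL)
}

#' Write a cohort dataset as the package's CSV family
#'
#' Lays a dataset (typically a [generate_cohort()] result) out on disk in
#' the layout [run_pipeline()] reads back: `trial_records.csv`,
#' `vehicle_slow.csv` / `vehicle_fast.csv`, one `head_<participant>_<speed>.csv`
#' per trace, and -- for synthetic cohorts -- a `ground_truth.csv` sidecar of
#' planted per-participant parameters that no analysis stage reads.
#'
#' @param cohort A `synthetic_cohort` or compatible list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_records(cohort$records, file.path(dir, "trial_records.csv"))
  for (sp in unique(cohort$vehicle$speed)) {
    write_vehicle_trace(
      cohort$vehicle[cohort$vehicle$speed == sp,
                     c("time", "vehicle_yaw")],
      file.path(dir, sprintf("vehicle_%s.csv", sp))
    )
  }
  groups <- dplyr::distinct(cohort$traces[c("participant_id", "speed")])
  purrr::pwalk(groups, function(participant_id, speed) {
    tr <- cohort$traces[cohort$traces$participant_id == participant_id &
                          cohort$traces$speed == speed,
                        c("time", "pitch", "yaw", "roll")]
    write_head_motion_log(
      tr, file.path(dir, sprintf("head_%s_%s.csv", participant_id, speed))
    )
  })
  if (!is.null(cohort$ground_truth$participants)) {
    readr::write_csv(cohort$ground_truth$participants,
                     file.path(dir, "ground_truth.csv"), progress = FALSE)
  }
  invisible(dir)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes ingest, preprocessing (centre/unwrap + uniform resampling),
#' velocity summaries and axis comparisons, conformity scoring and
#' summaries, lag estimation, the self-report statistics, and report
#' writing. The result bundle is a pure function of (input data, config,
#' seed): rerunning with the same config produces byte-identical CSV
#' outputs.
#'
#' @param config A config list or path to a YAML file with sections `io`
#'   (`lap_duration`, `rate`, optionally `data_dir`), `synthetic`
#'   (optional: `seed`, `experiments`, `n_participants`, `track`,
#'   `head_population`), `analysis` (optional: `max_lag_ms`, `step_ms`),
#'   and `report` (optional: `figures`).
#' @param output_dir Directory for the CSV artifacts, text report, run log,
#'   and figures.
#' @return Invisibly, a list with every stage's tables.
#' @export
run_pipeline <- function(config, output_dir) {
  config <- read_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  log_stage <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    inform(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "headconform_pipeline_error", parent = e)
    })
  }

  input <- stage("ingest", {
    if (!is.null(config$synthetic)) {
      build_synthetic_input(config)
    } else {
      read_cohort_input(config)
    }
  })
  log_stage("ingest: %d head trace(s), %d trial record(s)",
            nrow(dplyr::distinct(input$traces[c("participant_id", "speed")])),
            nrow(input$records))

  rate <- config$io$rate
  lap <- config$io$lap_duration
  prep <- stage("preprocess", {
    head <- input$traces |> center_and_unwrap() |>
      resample_uniform(rate = rate, duration = lap)
    vehicle <- input$vehicle |> center_and_unwrap() |>
      resample_uniform(rate = rate, duration = lap)
    list(head = head, vehicle = vehicle)
  })
  n_excl <- prep$head |>
    dplyr::filter(.data$excluded) |>
    dplyr::distinct(.data$participant_id, .data$speed) |>
    nrow()
  log_stage("preprocess: grid %d points; %d trace(s) flagged for exclusion",
            round(rate * lap), n_excl)

  velocity <- stage("velocity", mean_absolute_velocity(prep$head))
  axis_tests <- stage("velocity", compare_axes(velocity))
  log_stage("velocity: %d summaries", nrow(velocity))

  scores <- stage("conformity",
                  suppressMessages(conformity_scores(prep$head)))
  conf_summary <- stage("conformity",
                        suppressMessages(summarize_conformity(scores)))
  log_stage("conformity: %d scores (%d degenerate)",
            nrow(scores), sum(scores$degenerate))

  analysis <- config$analysis %||% list()
  lags <- stage("lag", suppressMessages(estimate_cohort_lags(
    prep$head, prep$vehicle,
    max_lag_ms = analysis$max_lag_ms %||% 2000,
    step_ms = analysis$step_ms
  )))
  lag_profile <- stage("lag", cohort_lag_profile(lags))
  log_stage("lag: n = %d, median = %.1f ms", lag_profile$n,
            lag_profile$median_ms)

  stats_out <- stage("stats", {
    anovas <- list()
    recs <- input$records
    if ("experiment" %in% names(recs)) {
      for (exp in sort(unique(recs$experiment))) {
        sub <- recs[recs$experiment == exp, ]
        within <- if (exp == 1) c("posture", "alignment", "speed") else
          c("direction", "speed")
        for (dv in c("vection_magnitude", "sickness", "presence")) {
          anovas[[sprintf("exp%s_%s", exp, dv)]] <-
            rm_anova(sub, dv, within = within)
        }
      }
    }
    assoc <- conformity_association_table(scores, recs)
    list(anovas = anovas, association = assoc,
         rating_cors = rating_correlations(recs))
  })
  log_stage("stats: %d ANOVA table(s), %d association rows",
            length(stats_out$anovas), nrow(stats_out$association))

  traj <- stage("report", trajectory_summary(prep$head))
  stage("report", {
    wr <- function(x, name) {
      readr::write_csv(x, file.path(output_dir, name), progress = FALSE)
    }
    wr(velocity, "velocity_summaries.csv")
    wr(axis_tests, "axis_comparisons.csv")
    wr(scores, "conformity_scores.csv")
    wr(tibble::as_tibble(conf_summary), "conformity_summary.csv")
    wr(lags, "lag_estimates.csv")
    wr(lag_profile$bins, "lag_histogram.csv")
    wr(tibble(n = lag_profile$n, median_ms = lag_profile$median_ms,
              q1_ms = lag_profile$q1_ms, q3_ms = lag_profile$q3_ms,
              iqr_ms = lag_profile$iqr_ms), "lag_profile.csv")
    wr(tibble::as_tibble(stats_out$association), "association_table.csv")
    wr(stats_out$rating_cors, "rating_correlations.csv")
    wr(tibble::as_tibble(traj), "trajectory_summary.csv")
    for (name in names(stats_out$anovas)) {
      wr(tidy(stats_out$anovas[[name]]), sprintf("anova_%s.csv", name))
    }
    report <- c(
      format_conformity_report(conf_summary), "",
      format_association_report(stats_out$association), "",
      sprintf("Cohort lag: median %.1f ms (IQR %.1f ms, n = %d); negative = head leads vehicle",
              lag_profile$median_ms, lag_profile$iqr_ms, lag_profile$n)
    )
    writeLines(report, file.path(output_dir, "report.txt"))
    if (isTRUE((config$report %||% list())$figures)) {
      ggplot2::ggsave(file.path(output_dir, "trajectory_summary.pdf"),
                      plot_trajectory_summary(traj), width = 9, height = 6)
      ggplot2::ggsave(file.path(output_dir, "conformity_scores.pdf"),
                      plot_conformity_scores(scores), width = 7, height = 5)
    }
    writeLines(c(
      sprintf("seed: %s", (config$synthetic %||% list())$seed %||% "n/a"),
      sprintf("headconform version: %s",
              as.character(utils::packageVersion("headconform"))),
      log_lines
    ), file.path(output_dir, "run_log.txt"))
  })

  invisible(list(
    input = input, preprocessed = prep, velocity = velocity,
    axis_tests = axis_tests, scores = scores,
    conformity_summary = conf_summary, lags = lags,
    lag_profile = lag_profile, stats = stats_out,
    trajectory = traj
  ))
}
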