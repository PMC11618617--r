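ANGLE_COLUMNS <- c("pitch", "yaw", "roll", "vehicle_yaw")
TRACE_ID_COLUMNS <- c("participant_id", "trial_id", "lap_id", "speed")

angle_cols <- function(trace) intersect(ANGLE_COLUMNS, names(trace))

trace_groups <- function(trace) intersect(TRACE_ID_COLUMNS, names(trace))

# Apply `fn` per (participant, trial, lap, speed) group when id columns are
# present, so cohort-shaped tibbles work as naturally as single traces.
map_traces <- function(trace, fn) {
  ids <- trace_groups(trace)
  if (length(ids) == 0) return(fn(trace))
  trace |>
    dplyr::group_by(dplyr::across(dplyr::all_of(ids))) |>
    dplyr::group_modify(function(g, key) fn(g)) |>
    dplyr::ungroup()
}

unwrap_degrees <- function(x) {
  if (length(x) < 2) return(x)
  d <- diff(x)
  d <- d - 360 * round(d / 360)
  x[1] + cumsum(c(0, d))
}

#' Centre a trace on its lap-start orientation and unwrap angle jumps
#'
#' Converts raw recorded angles into signed deviations from the reference
#' orientation: the participant's default, forward-facing viewpoint at the
#' beginning of the lap. Each channel is first unwrapped (successive
#' differences mapped into (-180, 180], so a 359 -> 1 degree jump reads as
#' +2 degrees, preserving continuity) and then shifted so the first sample is
#' zero. If genuine cumulative rotation exceeds half a turn, continuity wins
#' over the (-180, 180] range.
#'
#' @param trace A trace tibble with a `time` column and one or more angle
#'   channels (`pitch`, `yaw`, `roll`, `vehicle_yaw`); may hold several
#'   traces distinguished by id columns.
#' @return The trace with every angle channel expressed as deviation from
#'   its first sample.
#' @export
#' @examples
#' center_and_unwrap(tibble::tibble(time = 0:2 / 90, yaw = c(350, 351, 352)))
center_and_unwrap <- function(trace) {
  if (nrow(trace) == 0) abort_data("Trace is empty")
  map_traces(trace, function(g) {
    for (col in angle_cols(g)) {
      u <- unwrap_degrees(g[[col]])
      g[[col]] <- u - u[1]
    }
    g
  })
}

#' Resample a trace onto the uniform analysis grid
#'
#' Places each channel on the uniform grid of `round(rate * duration)` points
#' (5400 for a 60-s lap at 90 Hz) by linear interpolation, starting at the
#' trace's first timestamp. Recorder jitter and dropped frames shorter than
#' `max_gap` are interpolated across; a longer gap cannot be bridged without
#' risking a fabricated head turn, so such traces are kept but flagged in the
#' logical `excluded` column and dropped (with a logged count) by the
#' analysis stages.
#'
#' @inheritParams center_and_unwrap
#' @param rate Target sampling rate in Hz.
#' @param duration Target duration in seconds; the trace must cover at least
#'   95 percent of it.
#' @param max_gap Largest timestamp gap (seconds) that may be interpolated;
#'   default 0.1 s (9 frames at 90 Hz).
#' @return The resampled trace with an `excluded` column.
#' @export
resample_uniform <- function(trace, rate = 90, duration = 60,
                             max_gap = 0.1) {
  if (nrow(trace) == 0) abort_data("Trace is empty")
  n_grid <- round(rate * duration)
  map_traces(trace, function(g) {
    t <- g$time
    span <- t[length(t)] - t[1]
    if (span < 0.95 * duration) {
      abort_data(sprintf(
        "Trace covers %.2f s, less than 95%% of the requested %g s", span,
        duration
      ))
    }
    grid <- t[1] + (seq_len(n_grid) - 1) / rate
    out <- tibble(time = grid - t[1])
    for (col in angle_cols(g)) {
      out[[col]] <- approx(t, g[[col]], xout = grid, rule = 2)$y
    }
    out$excluded <- max(diff(t)) > max_gap + 1e-12
    out
  })
}

check_uniform_grid <- function(t, context) {
  if (length(t) < 2) {
    abort_inference(sprintf("%s needs at least 2 samples", context))
  }
  dt <- diff(t)
  if (max(abs(dt - median(dt))) > 1e-6) {
    abort_data(sprintf(
      "%s requires a uniform time grid; run resample_uniform() first", context
    ))
  }
  1 / median(dt)
}

#' Mean absolute angular velocity per axis
#'
#' The lap-level motion summary: for each channel, the mean of the absolute
#' successive differences times the sampling rate, in degrees per second.
#' First differences are used without smoothing, which would bias the
#' summary downward. Zero means the channel never moved.
#'
#' @inheritParams center_and_unwrap
#' @return A tibble with one row per trace and axis: id columns, `axis`, and
#'   `mean_abs_velocity` (deg/s).
#' @export
mean_absolute_velocity <- function(trace) {
  if (nrow(trace) == 0) abort_data("Trace is empty")
  map_traces(trace, function(g) {
    rate <- check_uniform_grid(g$time, "mean_absolute_velocity()")
    purrr::map_dfr(angle_cols(g), function(col) {
      tibble(axis = sub("vehicle_yaw", "yaw", col),
             mean_abs_velocity = mean(abs(diff(g[[col]]))) * rate)
    })
  })
}

#' Paired axis comparisons of velocity summaries
#'
#' Tests, per speed condition, whether yaw velocity exceeds pitch and roll
#' velocity with paired t-tests across participants. When every paired
#' difference is zero the comparison returns t = 0, p = 1; a nonzero
#' constant difference has zero variance and is flagged `degenerate` rather
#' than reported as an infinite t.
#'
#' @param summaries Output of [mean_absolute_velocity()] over a cohort:
#'   columns `participant_id`, `axis`, `mean_abs_velocity`, and optionally
#'   `speed`.
#' @return A tibble with one row per speed and comparison: `mean_diff`, `t`,
#'   `df`, `p`, `degenerate`.
#' @export
compare_axes <- function(summaries) {
  if (!"speed" %in% names(summaries)) summaries$speed <- "all"
  wide <- tidyr::pivot_wider(
    summaries[c("participant_id", "speed", "axis", "mean_abs_velocity")],
    names_from = "axis", values_from = "mean_abs_velocity"
  )
  missing_axis <- setdiff(c("yaw", "pitch", "roll"), names(wide))
  if (length(missing_axis) > 0) {
    abort_inference(sprintf(
      "Every participant must contribute all three axes; missing: %s",
      paste(missing_axis, collapse = ", ")
    ))
  }
  purrr::map_dfr(split(wide, wide$speed), function(w) {
    purrr::map_dfr(c(pitch = "pitch", roll = "roll"), function(other) {
      d <- w$yaw - w[[other]]
      if (length(d) < 2) {
        abort_inference("Paired axis comparison needs at least 2 participants")
      }
      if (sd(d) == 0) {
        if (all(d == 0)) {
          tibble(speed = w$speed[1],
                 comparison = paste0("yaw_vs_", other),
                 mean_diff = 0, t = 0, df = length(d) - 1, p = 1,
                 degenerate = FALSE)
        } else {
          tibble(speed = w$speed[1],
                 comparison = paste0("yaw_vs_", other),
                 mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
                 p = NA_real_, degenerate = TRUE)
        }
      } else {
        tt <- t.test(w$yaw, w[[other]], paired = TRUE)
        tibble(speed = w$speed[1],
               comparison = paste0("yaw_vs_", other),
               mean_diff = mean(d), t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               degenerate = FALSE)
      }
    })
  })
}
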