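#' Describe the column layout of a head-motion CSV export
#'
#' Head-motion logs arrive as per-trial CSV files written by an OpenVR-style
#' recorder: one row per sample, a timestamp column, and one column per
#' rotation axis. Recorders differ in column naming and units, so reads go
#' through a dialect object that maps file columns onto the package's
#' canonical names (`time`, `pitch`, `yaw`, `roll`; seconds and degrees).
#'
#' Sign conventions assumed throughout the package: positive yaw is a
#' rightward head turn, positive pitch is upward, positive roll is a
#' rightward ear-to-shoulder tilt. Vehicle yaw uses the same convention.
#'
#' @param time,pitch,yaw,roll Column names in the file.
#' @param angle_unit `"degrees"` (default) or `"radians"`; radians are
#'   converted to degrees on read.
#' @param time_unit `"seconds"` (default) or `"milliseconds"`.
#' @return A `head_motion_dialect` list.
#' @export
#' @examples
#' head_motion_dialect(time = "Timestamp", yaw = "Head.Yaw",
#'                     pitch = "Head.Pitch", roll = "Head.Roll")
head_motion_dialect <- function(time = "time", pitch = "pitch", yaw = "yaw",
                                roll = "roll",
                                angle_unit = c("degrees", "radians"),
                                time_unit = c("seconds", "milliseconds")) {
  structure(
    list(columns = c(time = time, pitch = pitch, yaw = yaw, roll = roll),
         angle_unit = match.arg(angle_unit),
         time_unit = match.arg(time_unit)),
    class = "head_motion_dialect"
  )
}

#' @rdname head_motion_dialect
#' @param vehicle_yaw Column holding the vehicle heading/yaw channel.
#' @export
vehicle_dialect <- function(time = "time", vehicle_yaw = "vehicle_yaw",
                            angle_unit = c("degrees", "radians"),
                            time_unit = c("seconds", "milliseconds")) {
  structure(
    list(columns = c(time = time, vehicle_yaw = vehicle_yaw),
         angle_unit = match.arg(angle_unit),
         time_unit = match.arg(time_unit)),
    class = "head_motion_dialect"
  )
}

# Read a CSV strictly: all cells as character, then numeric conversion with
# row/column blame. Silent coercion at the boundary is the failure mode this
# guards against.
read_numeric_columns <- function(path, columns) {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: '%s'", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "File '%s' is missing required column(s): %s",
      path, paste0("'", missing, "'", collapse = ", ")
    ))
  }
  out <- purrr::imap(columns, function(col, canonical) {
    values <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(parsed) & !is.na(values) & values != "")
    if (length(bad) > 0) {
      abort_data(sprintf(
        "Non-numeric value '%s' in column '%s' at data row %d of '%s'",
        values[bad[1]], col, bad[1], path
      ))
    }
    parsed
  })
  tibble::as_tibble(out)
}

check_time_monotonic <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad) > 0) {
    abort_data(sprintf(
      "Timestamps must be strictly increasing; violation at data row %d of '%s'",
      bad[1] + 1L, path
    ))
  }
  invisible(t)
}

apply_units <- function(tbl, dialect) {
  if (dialect$time_unit == "milliseconds") {
    tbl$time <- tbl$time / 1000
  }
  if (dialect$angle_unit == "radians") {
    angle_cols <- setdiff(names(tbl), "time")
    tbl[angle_cols] <- lapply(tbl[angle_cols], function(x) x * 180 / pi)
  }
  tbl
}

#' Read a per-trial head-motion telemetry log
#'
#' Returns the raw (uncentred) angles in degrees with a strictly increasing
#' time column in seconds. Centring on the lap-start orientation and angle
#' unwrapping are preprocessing decisions and live in [center_and_unwrap()];
#' nothing is imputed or smoothed at read time.
#'
#' @param path Path to the CSV file.
#' @param dialect A [head_motion_dialect()] mapping file columns to channels.
#' @param participant_id,trial_id Optional labels attached as columns.
#' @return A tibble with columns `time`, `pitch`, `yaw`, `roll` (and the
#'   optional id columns), one row per sample.
#' @export
read_head_motion_log <- function(path, dialect = head_motion_dialect(),
                                 participant_id = NULL, trial_id = NULL) {
  tbl <- read_numeric_columns(path, dialect$columns)
  tbl <- apply_units(tbl, dialect)
  check_time_monotonic(tbl$time, path)
  check_angles_finite(tbl, path)
  add_id_columns(tbl, participant_id, trial_id)
}

#' Read a per-lap vehicle yaw trace
#'
#' @inheritParams read_head_motion_log
#' @param dialect A [vehicle_dialect()].
#' @param lap_id,speed Optional labels attached as columns; `speed` is the
#'   playback condition (`"slow"` or `"fast"`).
#' @return A tibble with columns `time` and `vehicle_yaw`.
#' @export
read_vehicle_trace <- function(path, dialect = vehicle_dialect(),
                               lap_id = NULL, speed = NULL) {
  tbl <- read_numeric_columns(path, dialect$columns)
  tbl <- apply_units(tbl, dialect)
  check_time_monotonic(tbl$time, path)
  check_angles_finite(tbl, path)
  if (!is.null(lap_id)) tbl$lap_id <- lap_id
  if (!is.null(speed)) tbl$speed <- speed
  tbl
}

check_angles_finite <- function(tbl, path) {
  for (col in setdiff(names(tbl), "time")) {
    bad <- which(!is.finite(tbl[[col]]))
    if (length(bad) > 0) {
      abort_data(sprintf(
        "Non-finite angle in column '%s' at data row %d of '%s'",
        col, bad[1], path
      ))
    }
  }
  invisible(tbl)
}

add_id_columns <- function(tbl, participant_id, trial_id) {
  if (!is.null(trial_id)) {
    tbl <- tibble::add_column(tbl, trial_id = trial_id, .before = 1)
  }
  if (!is.null(participant_id)) {
    tbl <- tibble::add_column(tbl, participant_id = participant_id,
                              .before = 1)
  }
  tbl
}

#' Write traces and trial tables back to CSV
#'
#' Inverse of the corresponding readers; `write` then `read` is the identity
#' to numerical tolerance. Missing ratings fields (conditional vection onset
#' and duration) are written as empty cells.
#'
#' @param x A tibble as produced by the matching reader.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_head_motion_log <- function(x, path) {
  readr::write_csv(x, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_head_motion_log
#' @export
write_vehicle_trace <- write_head_motion_log

#' @rdname write_head_motion_log
#' @export
write_trial_records <- write_head_motion_log

trial_rating_columns <- c("vection_magnitude", "sickness", "presence")

#' Read and validate a trial-record table
#'
#' One row per trial: participant, condition factors (posture, alignment,
#' direction, speed -- including the stationary baseline), and the five
#' self-report measures. Ratings are 1-20 integers; vection onset and
#' duration (seconds) are recorded only when vection magnitude is at least 2,
#' because a magnitude of 1 means no vection was felt at all.
#'
#' @param path Path to the CSV file.
#' @param lap_duration Lap length in seconds (default 60); onset + duration
#'   may not exceed it.
#' @return A validated tibble of trial records.
#' @export
read_trial_records <- function(path, lap_duration = 60) {
  if (!file.exists(path)) {
    abort_data(sprintf("File not found: '%s'", path))
  }
  tbl <- readr::read_csv(
    path,
    col_types = readr::cols(
      .default = readr::col_character(),
      vection_magnitude = readr::col_double(),
      vection_onset = readr::col_double(),
      vection_duration = readr::col_double(),
      sickness = readr::col_double(),
      presence = readr::col_double()
    ),
    progress = FALSE
  )
  validate_trial_records(tbl, lap_duration = lap_duration)
}

#' Validate a trial-record tibble against the study's recording rules
#'
#' Enforces: every rating in \[1, 20\]; vection onset/duration present if and
#' only if vection magnitude >= 2; onset + duration within the lap; speed one
#' of `stationary`, `slow`, `fast`. Validation never coerces: the first
#' violation raises a `headconform_validation_error` naming the row.
#'
#' @param records A tibble of trial records.
#' @inheritParams read_trial_records
#' @return `records`, invisibly classed as validated (returned visibly).
#' @export
validate_trial_records <- function(records, lap_duration = 60) {
  required <- c("participant_id", "speed", trial_rating_columns)
  missing <- setdiff(required, names(records))
  if (length(missing) > 0) {
    abort_format(sprintf(
      "Trial records are missing required column(s): %s",
      paste0("'", missing, "'", collapse = ", ")
    ))
  }
  if (!"vection_onset" %in% names(records)) records$vection_onset <- NA_real_
  if (!"vection_duration" %in% names(records)) {
    records$vection_duration <- NA_real_
  }

  bad_speed <- which(!records$speed %in% c("stationary", "slow", "fast"))
  if (length(bad_speed) > 0) {
    abort_validation(sprintf(
      "Row %d: speed '%s' is not one of 'stationary', 'slow', 'fast'",
      bad_speed[1], records$speed[bad_speed[1]]
    ))
  }

  for (col in trial_rating_columns) {
    v <- records[[col]]
    bad <- which(is.na(v) | v < 1 | v > 20)
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Row %d: %s = %s is outside the 1-20 rating scale",
        bad[1], col,
        ifelse(is.na(v[bad[1]]), "NA", format(v[bad[1]]))
      ))
    }
  }

  has_onset <- !is.na(records$vection_onset)
  has_duration <- !is.na(records$vection_duration)
  felt <- records$vection_magnitude >= 2

  bad <- which(has_onset != has_duration)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Row %d: vection onset and duration must be recorded together", bad[1]
    ))
  }
  bad <- which(has_onset & !felt)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      paste0("Row %d: vection onset/duration recorded although magnitude is 1",
             " (1 indicates no vection)"), bad[1]
    ))
  }
  bad <- which(felt & !has_onset)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Row %d: vection magnitude >= 2 requires onset and duration", bad[1]
    ))
  }
  bad <- which(has_onset &
                 (records$vection_onset < 0 | records$vection_duration < 0))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Row %d: vection onset and duration must be non-negative", bad[1]
    ))
  }
  bad <- which(has_onset &
                 records$vection_onset + records$vection_duration >
                   lap_duration + 1e-9)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Row %d: vection onset (%g s) + duration (%g s) exceeds the %g-s lap",
      bad[1], records$vection_onset[bad[1]],
      records$vection_duration[bad[1]], lap_duration
    ))
  }
  tibble::as_tibble(records)
}
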