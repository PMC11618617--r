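#' Estimate the head-to-vehicle lag by cross-correlation
#'
#' Finds the signed delay that maximises the Pearson correlation between a
#' head yaw trace and the vehicle yaw trace. A lag of `d` means the head
#' trace looks like the vehicle trace delayed by `d`: negative lags mean the
#' head *leads* the vehicle, i.e. the participant turned toward an upcoming
#' curve before the car did (anticipatory steering-like behaviour).
#'
#' Correlations are computed on the overlapping region of the two shifted
#' series (truncation, not padding, which would bias r toward zero
#' asymmetrically). Ties in peak correlation are broken toward the smallest
#' absolute lag, which is conservative against over-claiming anticipation.
#' Lags whose overlap has zero variance in either series are skipped with a
#' log entry.
#'
#' @param head A single preprocessed head trace tibble (uniform grid) with a
#'   `yaw` column (or the channel named by `head_channel`).
#' @param vehicle The vehicle trace on the identical grid (`vehicle_yaw`
#'   column, or `vehicle_channel`).
#' @param max_lag_ms Largest absolute lag searched, in milliseconds.
#' @param step_ms Search step in milliseconds; must be an integer multiple
#'   of the sample period. Default: one sample (about 11.1 ms at 90 Hz).
#' @param head_channel,vehicle_channel Column names of the two signals.
#' @return A one-row tibble: `lag_ms` (negative = head leads), `peak_r`,
#'   `n_overlap`, `max_lag_ms`, `step_ms`.
#' @export
estimate_lag <- function(head, vehicle, max_lag_ms = 2000, step_ms = NULL,
                         head_channel = "yaw",
                         vehicle_channel = "vehicle_yaw") {
  x <- head[[head_channel]]
  y <- vehicle[[vehicle_channel]]
  if (is.null(y) && vehicle_channel == "vehicle_yaw") y <- vehicle[["yaw"]]
  if (is.null(x) || is.null(y)) {
    abort_inference("Requested signal channels not found in the traces")
  }
  if (length(x) != length(y)) {
    abort_inference("Head and vehicle traces are not on the same grid")
  }
  rate <- check_uniform_grid(head$time, "estimate_lag()")
  period_ms <- 1000 / rate
  if (is.null(step_ms)) step_ms <- period_ms
  step_samples <- step_ms / period_ms
  if (abs(step_samples - round(step_samples)) > 1e-6) {
    abort_config(sprintf(
      "step_ms (%g) must be an integer multiple of the sample period (%g ms)",
      step_ms, period_ms
    ))
  }
  step_samples <- round(step_samples)
  max_samples <- floor(max_lag_ms / period_ms)
  if (max_samples >= length(x) / 2) {
    abort_config("max_lag_ms must be below half the trace duration")
  }
  lags <- seq(-max_samples, max_samples, by = step_samples)

  n <- length(x)
  rs <- vapply(lags, function(k) {
    # lag k: head(t) ~ vehicle(t - k); overlap indices
    if (k >= 0) {
      xs <- x[(1 + k):n]
      ys <- y[1:(n - k)]
    } else {
      xs <- x[1:(n + k)]
      ys <- y[(1 - k):n]
    }
    if (sd(xs) == 0 || sd(ys) == 0) return(NA_real_)
    cor(xs, ys)
  }, numeric(1))

  n_skipped <- sum(is.na(rs))
  if (n_skipped > 0) {
    inform(sprintf("Skipped %d lag(s) with zero-variance overlap", n_skipped))
  }
  if (all(is.na(rs))) {
    abort_inference("No lag had a non-degenerate overlap")
  }
  peak <- max(rs, na.rm = TRUE)
  candidates <- lags[!is.na(rs) & rs >= peak - 1e-12]
  best <- candidates[which.min(abs(candidates))]
  tibble(
    lag_ms = best * period_ms,
    peak_r = peak,
    n_overlap = length(x) - abs(best),
    max_lag_ms = max_lag_ms,
    step_ms = step_samples * period_ms
  )
}

#' Per-participant lag estimates for a cohort
#'
#' Runs [estimate_lag()] for every participant and speed condition against
#' the matching vehicle trace.
#'
#' @param traces Cohort tibble of preprocessed head traces
#'   (`participant_id`, optionally `speed`, `time`, `yaw`).
#' @param vehicle_traces Vehicle traces with a `speed` column matching the
#'   head traces' speed conditions (centred like the head traces).
#' @inheritParams estimate_lag
#' @return A tibble of per-participant [estimate_lag()] rows.
#' @export
estimate_cohort_lags <- function(traces, vehicle_traces, max_lag_ms = 2000,
                                 step_ms = NULL) {
  if (!"speed" %in% names(traces)) traces$speed <- "all"
  if (!"speed" %in% names(vehicle_traces)) vehicle_traces$speed <- "all"
  if ("excluded" %in% names(traces)) {
    traces <- dplyr::filter(traces, !.data$excluded)
  }
  groups <- dplyr::distinct(traces[c("participant_id", "speed")])
  purrr::pmap_dfr(groups, function(participant_id, speed) {
    h <- traces[traces$participant_id == participant_id &
                  traces$speed == speed, ]
    v <- vehicle_traces[vehicle_traces$speed == speed, ]
    if (nrow(v) == 0) {
      abort_inference(sprintf("No vehicle trace for speed '%s'", speed))
    }
    est <- estimate_lag(h, v, max_lag_ms = max_lag_ms, step_ms = step_ms)
    tibble::add_column(est, participant_id = participant_id, speed = speed,
                       .before = 1)
  })
}

#' Cohort summary of lag estimates
#'
#' Median and interquartile range of the per-participant lags, plus
#' histogram-ready bin counts, supporting a single cohort-level statement
#' such as "head turns lead the vehicle by about 750 ms".
#'
#' @param estimates Tibble of [estimate_lag()] rows.
#' @param bin_width_ms Histogram bin width in milliseconds.
#' @return A `lag_profile` list: `n`, `median_ms`, `iqr_ms`, `q1_ms`,
#'   `q3_ms`, and a `bins` tibble.
#' @export
cohort_lag_profile <- function(estimates, bin_width_ms = 100) {
  if (nrow(estimates) == 0) abort_inference("No lag estimates supplied")
  lags <- estimates$lag_ms
  breaks <- seq(
    floor(min(lags) / bin_width_ms) * bin_width_ms,
    ceiling(max(lags) / bin_width_ms) * bin_width_ms + bin_width_ms,
    by = bin_width_ms
  )
  counts <- table(cut(lags, breaks = breaks, right = FALSE))
  structure(list(
    n = length(lags),
    median_ms = median(lags),
    q1_ms = unname(quantile(lags, 0.25)),
    q3_ms = unname(quantile(lags, 0.75)),
    iqr_ms = unname(diff(quantile(lags, c(0.25, 0.75)))),
    bins = tibble(
      lower_ms = head(breaks, -1),
      upper_ms = tail(breaks, -1),
      count = as.integer(counts)
    )
  ), class = "lag_profile")
}

#' @export
print.lag_profile <- function(x, ...) {
  cat(sprintf(
    "Cohort lag profile: n = %d, median = %g ms (IQR %g ms; negative = head leads)\n",
    x$n, x$median_ms, x$iqr_ms
  ))
  invisible(x)
}
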