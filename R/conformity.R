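#' Leave-one-out median head trajectory
#'
#' The normative reference against which one participant is scored: at every
#' time point, the median deviation across every *other* participant's trace.
#' The median (not the mean) is used so that a single outlying head does not
#' drag the reference; with an even count the mean of the two central values
#' is taken.
#'
#' @param traces A cohort tibble of aligned, preprocessed traces: columns
#'   `participant_id`, `time`, and the angle channels. All traces must share
#'   an identical time grid.
#' @param target The participant to exclude.
#' @param axis One of `"pitch"`, `"yaw"`, `"roll"`.
#' @return A tibble with `time` and `reference` (degrees).
#' @export
loo_median_trajectory <- function(traces, target, axis) {
  mat <- cohort_matrix(traces, axis)
  if (ncol(mat$values) < 3) {
    abort_inference(
      "Leave-one-out median needs at least 3 participants (with 2, the reference would be a single other trace)"
    )
  }
  if (!target %in% colnames(mat$values)) {
    abort_inference(sprintf("Participant '%s' not present in the cohort",
                            target))
  }
  others <- mat$values[, colnames(mat$values) != target, drop = FALSE]
  tibble(time = mat$time, reference = apply(others, 1, median))
}

# Reshape a cohort tibble to a time-by-participant matrix, insisting on one
# shared grid. A direct fill is used rather than a pivot: cohort matrices are
# rebuilt per axis and speed inside Monte-Carlo loops.
cohort_matrix <- function(traces, axis) {
  if (!axis %in% names(traces)) {
    abort_inference(sprintf("Axis column '%s' not found in traces", axis))
  }
  counts <- table(traces$participant_id)
  if (length(unique(counts)) != 1) {
    abort_data("Traces are not on an identical time grid; resample first")
  }
  ord <- order(match(traces$participant_id,
                     unique(traces$participant_id)), traces$time)
  ids <- unique(traces$participant_id)
  n_t <- unname(counts[1])
  times <- matrix(traces$time[ord], nrow = n_t)
  if (max(abs(times - times[, 1])) > 1e-9) {
    abort_data("Traces are not on an identical time grid; resample first")
  }
  values <- matrix(traces[[axis]][ord], nrow = n_t,
                   dimnames = list(NULL, ids))
  list(time = times[, 1], values = values)
}

#' Score one trace against a reference trajectory
#'
#' The conformity score is the Pearson correlation between a participant's
#' deviation series and the reference trajectory over all grid points.
#' Pearson correlation is location- and positive-scale-invariant, so
#' centring conventions cannot change the score. A constant trace or
#' reference (a motionless participant) has no defined correlation and is
#' flagged `degenerate` instead of being scored.
#'
#' @param trace A single preprocessed trace tibble.
#' @param reference Output of [loo_median_trajectory()] (or any tibble with
#'   `time` and `reference`, or a bare numeric vector on the same grid).
#' @param axis Angle channel of `trace` to score.
#' @return A one-row tibble: `axis`, `r`, `n_points`, `degenerate`.
#' @export
conformity_score <- function(trace, reference, axis) {
  x <- trace[[axis]]
  y <- if (is.numeric(reference)) reference else reference$reference
  if (length(x) != length(y)) {
    abort_inference("Trace and reference are not on the same grid")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(axis = axis, r = NA_real_, n_points = length(x),
                  degenerate = TRUE))
  }
  tibble(axis = axis, r = cor(x, y), n_points = length(x),
         degenerate = FALSE)
}

# Vectorised leave-one-out medians for a full cohort. Each time point's row
# is sorted once (a single global order() call); removing the element of
# rank k from a sorted row leaves order statistics that are a simple index
# shift, so all N leave-one-out medians come from one sort per time point.
loo_median_matrix <- function(values) {
  n <- ncol(values)
  n_t <- nrow(values)
  o <- order(row(values), values)          # stable: ties rank by column
  sorted <- matrix(values[o], nrow = n_t, byrow = TRUE)
  rank_flat <- integer(length(o))
  rank_flat[o] <- rep.int(seq_len(n), n_t)
  ranks <- matrix(rank_flat, nrow = n_t)
  m <- n - 1
  ri <- row(ranks)
  pick <- function(j) {
    idx <- j + (ranks <= j)  # j-th smallest of the row minus rank-k element
    matrix(sorted[cbind(as.vector(ri), as.vector(idx))], nrow = n_t)
  }
  if (m %% 2 == 1) {
    pick((m + 1) / 2)
  } else {
    (pick(m / 2) + pick(m / 2 + 1)) / 2
  }
}

colwise_pearson <- function(x, y) {
  xc <- sweep(x, 2, colMeans(x))
  yc <- sweep(y, 2, colMeans(y))
  sx <- colSums(xc^2)
  sy <- colSums(yc^2)
  r <- rep(NA_real_, ncol(x))
  ok <- sx > 0 & sy > 0
  r[ok] <- colSums(xc * yc)[ok] / sqrt(sx[ok] * sy[ok])
  list(r = r, degenerate = !ok)
}

#' Conformity scores for a whole cohort
#'
#' For every participant, axis, and speed condition, the Pearson correlation
#' between the participant's trace and the leave-one-out median trajectory
#' of the rest of the cohort. Traces flagged `excluded` by
#' [resample_uniform()] are dropped with a logged count. If several laps per
#' participant and condition are present (distinguished by `trial_id`), the
#' per-lap scores are averaged on the Fisher-z scale and back-transformed.
#'
#' @param traces Cohort tibble of aligned preprocessed traces with
#'   `participant_id`, `time`, angle channels, and optionally `speed`,
#'   `trial_id`, `excluded`.
#' @param axes Channels to score.
#' @return A tibble: `participant_id`, `speed`, `axis`, `r`, `n_points`,
#'   `degenerate`.
#' @export
conformity_scores <- function(traces, axes = c("pitch", "yaw", "roll")) {
  axes <- intersect(axes, names(traces))
  if (length(axes) == 0) abort_inference("No angle channels found in traces")
  if ("excluded" %in% names(traces)) {
    n_excluded <- traces |>
      dplyr::filter(.data$excluded) |>
      dplyr::distinct(dplyr::across(dplyr::any_of(
        c("participant_id", "speed", "trial_id")
      ))) |>
      nrow()
    if (n_excluded > 0) {
      inform(sprintf(
        "Excluding %d trace(s) flagged by gap handling from conformity scoring",
        n_excluded
      ))
    }
    traces <- dplyr::filter(traces, !.data$excluded)
  }
  if (!"speed" %in% names(traces)) traces$speed <- "all"
  has_laps <- "trial_id" %in% names(traces)
  layers <- if (has_laps) {
    split(traces, interaction(traces$speed, traces$trial_id, drop = TRUE))
  } else {
    split(traces, traces$speed)
  }
  per_lap <- purrr::map_dfr(layers, function(layer) {
    purrr::map_dfr(axes, function(axis) {
      mat <- cohort_matrix(layer, axis)
      if (ncol(mat$values) < 3) {
        abort_inference("Conformity scoring needs at least 3 participants")
      }
      ref <- loo_median_matrix(mat$values)
      pr <- colwise_pearson(mat$values, ref)
      tibble(participant_id = colnames(mat$values),
             speed = layer$speed[1], axis = axis,
             r = pr$r, n_points = nrow(mat$values),
             degenerate = pr$degenerate)
    })
  })
  scores <- per_lap |>
    dplyr::group_by(.data$participant_id, .data$speed, .data$axis) |>
    dplyr::summarise(
      r = fisher_mean(.data$r[!.data$degenerate]),
      n_points = .data$n_points[1],
      degenerate = all(.data$degenerate),
      .groups = "drop"
    )
  dplyr::arrange(scores, .data$speed, .data$axis, .data$participant_id)
}

fisher_mean <- function(r) {
  if (length(r) == 0) return(NA_real_)
  if (length(r) == 1) return(r)
  clamped <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tanh(mean(atanh(clamped)))
}

#' Summarise conformity scores per axis and speed
#'
#' Mean and SD of the scores plus a two-tailed one-sample t-test against
#' zero: is the cohort's head motion, on average, positively correlated with
#' the normative (leave-one-out median) trajectory? Degenerate scores are
#' excluded with a logged count.
#'
#' @param scores Output of [conformity_scores()].
#' @return A `conformity_summary` tibble: `axis`, `speed`, `n`, `mean_r`,
#'   `sd_r`, `t`, `df`, `p`.
#' @export
summarize_conformity <- function(scores) {
  usable <- dplyr::filter(scores, !.data$degenerate)
  n_dropped <- nrow(scores) - nrow(usable)
  if (n_dropped > 0) {
    inform(sprintf("Excluding %d degenerate score(s) from summaries",
                   n_dropped))
  }
  if (nrow(usable) == 0) {
    abort_inference("All conformity scores are degenerate; nothing to summarise")
  }
  out <- usable |>
    dplyr::group_by(.data$axis, .data$speed) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_r = mean(.data$r),
      sd_r = sd(.data$r),
      t = one_sample_t(.data$r)$t,
      df = one_sample_t(.data$r)$df,
      p = one_sample_t(.data$r)$p,
      .groups = "drop"
    )
  structure(out, class = c("conformity_summary", class(out)))
}

one_sample_t <- function(x) {
  if (length(x) < 2) {
    abort_inference("One-sample t-test needs at least 2 scores")
  }
  if (sd(x) == 0) {
    if (all(x == 0)) return(list(t = 0, df = length(x) - 1, p = 1))
    return(list(t = NA_real_, df = length(x) - 1, p = NA_real_))
  }
  tt <- t.test(x, mu = 0)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}
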