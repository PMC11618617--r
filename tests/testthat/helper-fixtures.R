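# Programmatic fixtures; nothing is stored on disk.

make_trace <- function(n = 50, rate = 90, seed = 1, jitter = 0) {
  set.seed(seed)
  t <- (seq_len(n) - 1) / rate
  if (jitter > 0) {
    t <- t + runif(n, -jitter, jitter) / rate
    t <- sort(t)
    t <- t - t[1]
  }
  tibble::tibble(
    time = t,
    pitch = cumsum(rnorm(n, 0, 0.5)),
    yaw = cumsum(rnorm(n, 0, 0.8)),
    roll = cumsum(rnorm(n, 0, 0.3))
  )
}

make_cohort_traces <- function(n_participants = 5, n = 40, rate = 90,
                               seed = 1) {
  purrr::map_dfr(seq_len(n_participants), function(i) {
    tr <- make_trace(n = n, rate = rate, seed = seed * 1000 + i)
    tibble::add_column(tr, participant_id = sprintf("P%02d", i), .before = 1)
  })
}

make_trial_table <- function() {
  tibble::tibble(
    participant_id = rep(c("P01", "P02"), each = 3),
    speed = rep(c("stationary", "slow", "fast"), 2),
    posture = "upright",
    alignment = "aligned",
    direction = "forward",
    vection_magnitude = c(1, 8, 12, 2, 6, 9),
    vection_onset = c(NA, 10, 5, 20, 8, 12),
    vection_duration = c(NA, 30, 40, 10, 20, 25),
    sickness = c(1, 3, 5, 2, 4, 6),
    presence = c(5, 12, 15, 6, 10, 13)
  )
}

# A balanced random within-subject dataset for ANOVA oracle checks.
make_anova_data <- function(n_subj, levels_per_factor, seed) {
  set.seed(seed)
  factors <- purrr::imap(levels_per_factor, function(k, i) {
    paste0("f", i, "_", seq_len(k))
  })
  names(factors) <- paste0("w", seq_along(levels_per_factor))
  grid <- tidyr::expand_grid(
    participant_id = sprintf("S%02d", seq_len(n_subj)),
    !!!factors
  )
  grid$score <- round(rnorm(nrow(grid), 10, 3))
  grid
}
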