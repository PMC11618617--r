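make_aligned_cohort <- function(values) {
  # values: named list participant -> numeric vector on a shared grid
  purrr::imap_dfr(values, function(v, id) {
    tibble::tibble(participant_id = id, time = (seq_along(v) - 1) / 10,
                   yaw = v)
  })
}

test_that("the leave-one-out median excludes the target and uses the even-count convention", {
  cohort <- make_aligned_cohort(list(A = c(1, 5), B = c(2, 5), C = c(9, 5)))
  ref <- loo_median_trajectory(cohort, "C", "yaw")
  expect_equal(ref$reference[1], 1.5)  # median of {1, 2}

  # perturbing only the target leaves its own reference unchanged
  cohort2 <- make_aligned_cohort(list(A = c(1, 5), B = c(2, 5),
                                      C = c(100, -3)))
  ref2 <- loo_median_trajectory(cohort2, "C", "yaw")
  expect_equal(ref2$reference, ref$reference)

  expect_error(
    loo_median_trajectory(make_aligned_cohort(list(A = 1:3, B = 2:4)),
                          "A", "yaw"),
    class = "headconform_inference_error"
  )
  misaligned <- make_aligned_cohort(list(A = 1:4, B = 2:5, C = 3:6))
  misaligned$time[2] <- 0.42
  expect_error(loo_median_trajectory(misaligned, "A", "yaw"),
               class = "headconform_data_error")
})

test_that("leave-one-out medians match the sort-and-pick oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(3:9, 1)
    mat <- matrix(rnorm(30 * n), nrow = 30)
    colnames(mat) <- sprintf("P%02d", seq_len(n))
    cohort <- purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(participant_id = colnames(mat)[i],
                     time = (0:29) / 10, yaw = mat[, i])
    })
    target <- sample(n, 1)
    ref <- loo_median_trajectory(cohort, colnames(mat)[target], "yaw")
    expect_equal(ref$reference, oracle_loo_median(mat, target),
                 tolerance = 1e-9)
  }
})

test_that("conformity scores are Pearson correlations with degenerate guards", {
  tr <- tibble::tibble(time = (0:9) / 10, yaw = sin(1:10))
  expect_equal(conformity_score(tr, tr$yaw, "yaw")$r, 1)
  expect_equal(conformity_score(tr, -tr$yaw, "yaw")$r, -1)

  x <- c(1, 3, 2, 5, 4)
  y <- c(2, 1, 4, 3, 5)
  sc <- conformity_score(tibble::tibble(time = (0:4) / 10, yaw = x), y,
                         "yaw")
  expect_equal(sc$r, oracle_pearson(x, y), tolerance = 1e-9)

  flat <- tibble::tibble(time = (0:4) / 10, yaw = rep(1, 5))
  expect_true(conformity_score(flat, y, "yaw")$degenerate)
})

test_that("the fast cohort path equals naive per-participant scoring", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(3:10, 1)
    len <- sample(10:60, 1)
    cohort <- purrr::map_dfr(seq_len(n), function(i) {
      tibble::tibble(participant_id = sprintf("P%02d", i),
                     time = (seq_len(len) - 1) / 30,
                     yaw = rnorm(len))
    })
    fast <- suppressMessages(conformity_scores(cohort, axes = "yaw"))
    naive <- purrr::map_dbl(sprintf("P%02d", seq_len(n)), function(id) {
      ref <- loo_median_trajectory(cohort, id, "yaw")
      conformity_score(cohort[cohort$participant_id == id, ], ref, "yaw")$r
    })
    expect_equal(fast$r[order(fast$participant_id)], naive,
                 tolerance = 1e-9)
  }
})

test_that("conformity is invariant to positive affine transforms of a trace", {
  set.seed(8)
  cohort <- make_cohort_traces(n_participants = 6, n = 50)
  base <- suppressMessages(conformity_scores(cohort, axes = "yaw"))
  warped <- cohort
  warped$yaw[warped$participant_id == "P03"] <-
    2.7 * warped$yaw[warped$participant_id == "P03"] + 15
  after <- suppressMessages(conformity_scores(warped, axes = "yaw"))
  expect_equal(after$r[after$participant_id == "P03"],
               base$r[base$participant_id == "P03"], tolerance = 1e-9)
})

test_that("summaries report the one-sample t against zero", {
  scores <- tibble::tibble(
    participant_id = sprintf("P%d", 1:3), speed = "fast", axis = "yaw",
    r = c(0.2, 0.4, 0.6), n_points = 100, degenerate = FALSE
  )
  out <- summarize_conformity(scores)
  expect_equal(out$mean_r, 0.4)
  expect_equal(out$t, 0.4 / (0.2 / sqrt(3)), tolerance = 1e-9)
  expect_equal(out$df, 2)

  null_scores <- dplyr::mutate(scores, r = 0)
  out0 <- summarize_conformity(null_scores)
  expect_equal(out0$t, 0)
  expect_equal(out0$p, 1)

  scores$degenerate[1] <- TRUE
  expect_message(summarize_conformity(scores), "degenerate")
  all_bad <- dplyr::mutate(scores, degenerate = TRUE)
  expect_error(suppressMessages(summarize_conformity(all_bad)),
               class = "headconform_inference_error")
})

test_that("multiple laps per condition average on the Fisher-z scale", {
  two_laps <- purrr::map_dfr(c("L1", "L2"), function(lap) {
    cohort <- make_cohort_traces(n_participants = 4, n = 40,
                                 seed = match(lap, c("L1", "L2")))
    tibble::add_column(cohort, trial_id = lap, speed = "fast")
  })
  combined <- suppressMessages(conformity_scores(two_laps, axes = "yaw"))
  per_lap <- purrr::map(c("L1", "L2"), function(lap) {
    suppressMessages(conformity_scores(
      two_laps[two_laps$trial_id == lap, -which(names(two_laps) == "trial_id")],
      axes = "yaw"
    ))
  })
  manual <- tanh((atanh(per_lap[[1]]$r) + atanh(per_lap[[2]]$r)) / 2)
  expect_equal(combined$r[order(combined$participant_id)],
               manual[order(per_lap[[1]]$participant_id)],
               tolerance = 1e-9)
})

test_that("a coupling-free cohort has near-zero mean conformity", {
  track <- track_config(n_turns = 4, lap_duration = 20, rate = 30)
  veh <- generate_vehicle_trace(track, "fast")
  means <- vapply(1:100, function(rep) {
    traces <- purrr::map_dfr(1:30, function(i) {
      m <- head_model(gain = 0, noise_sd = 0.5, drift_sd = 2)
      tibble::add_column(simulate_head_trace(veh, m,
                                             seed = 300 + rep * 53 + i),
                         participant_id = sprintf("P%02d", i), .before = 1)
    })
    sc <- suppressMessages(conformity_scores(center_and_unwrap(traces),
                                             axes = "yaw"))
    mean(sc$r)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.05)
})

test_that("expected conformity rises with the planted gain", {
  track <- track_config(n_turns = 4, lap_duration = 20, rate = 30)
  veh <- generate_vehicle_trace(track, "fast")
  gains <- c(0.04, 0.08, 0.16, 0.32)
  mean_r <- vapply(seq_along(gains), function(gi) {
    rs <- vapply(1:50, function(rep) {
      traces <- purrr::map_dfr(1:5, function(i) {
        m <- head_model(gain = gains[gi], noise_sd = 0.5, drift_sd = 2)
        tibble::add_column(
          simulate_head_trace(veh, m, seed = 40 + rep * 29 + i * 7 + gi),
          participant_id = sprintf("P%02d", i), .before = 1
        )
      })
      sc <- suppressMessages(conformity_scores(center_and_unwrap(traces),
                                               axes = "yaw"))
      mean(sc$r)
    }, numeric(1))
    mean(rs)
  }, numeric(1))
  expect_true(all(diff(mean_r) > 0))
})
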