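test_that("vehicle traces honour the track geometry", {
  flat <- track_config(n_turns = 4, turn_amplitude = 0, lap_duration = 10,
                       rate = 30)
  expect_true(all(generate_vehicle_trace(flat, "fast")$vehicle_yaw == 0))

  expect_error(track_config(n_turns = 0, turn_amplitude = 10),
               class = "headconform_config_error")

  # half-speed playback: slow(t) = fast(t / 2)
  track <- track_config(n_turns = 6, lap_duration = 60, rate = 90)
  fast <- generate_vehicle_trace(track, "fast")
  slow <- generate_vehicle_trace(track, "slow")
  i10 <- which.min(abs(fast$time - 10))
  i20 <- which.min(abs(slow$time - 20))
  expect_equal(slow$vehicle_yaw[i20], fast$vehicle_yaw[i10],
               tolerance = 1e-9)
  half <- fast$time <= 30 + 1e-9
  expect_equal(slow$vehicle_yaw[seq(1, 5400, by = 2)],
               fast$vehicle_yaw[half][1:2700], tolerance = 1e-9)
})

test_that("the lap has exactly n_turns alternating yaw excursions", {
  track <- track_config(n_turns = 6, lap_duration = 60, rate = 90)
  yaw <- generate_vehicle_trace(track, "fast")$vehicle_yaw
  # zero-crossing style oracle: count sign runs of the yaw profile that
  # reach at least half the nominal amplitude
  runs <- rle(sign(yaw))
  peaks <- 0
  pos <- cumsum(c(0, runs$lengths))
  signs <- integer(0)
  for (j in seq_along(runs$lengths)) {
    seg <- yaw[(pos[j] + 1):pos[j + 1]]
    if (max(abs(seg)) >= track$turn_amplitude / 2 && runs$values[j] != 0) {
      peaks <- peaks + 1
      signs <- c(signs, runs$values[j])
    }
  }
  expect_equal(peaks, 6)
  expect_true(all(diff(signs) != 0))  # strictly alternating left/right
})

test_that("head simulation has the documented limiting behaviour", {
  track <- track_config(n_turns = 4, lap_duration = 20, rate = 45)
  veh <- generate_vehicle_trace(track, "fast")
  clean <- head_model(gain = 1, lead_ms = 0, noise_sd = 0, drift_sd = 0,
                      baseline_sd = 0)
  tr <- simulate_head_trace(veh, clean, seed = 1)
  expect_equal(tr$yaw, veh$vehicle_yaw, tolerance = 1e-9)
  expect_equal(tr$pitch, clean$pitch_gain * veh$vehicle_yaw,
               tolerance = 1e-9)

  none <- head_model(gain = 0, lead_ms = 0, noise_sd = 0, drift_sd = 0)
  tr0 <- simulate_head_trace(veh, none, seed = 1)
  expect_true(all(tr0$yaw == 0) && all(tr0$pitch == 0) &&
                all(tr0$roll == 0))

  a <- simulate_head_trace(veh, head_model(), seed = 42)
  b <- simulate_head_trace(veh, head_model(), seed = 42)
  c <- simulate_head_trace(veh, head_model(), seed = 43)
  expect_identical(a, b)
  expect_gt(max(abs(a$yaw - c$yaw)), 1e-6)

  expect_error(head_model(noise_sd = -1),
               class = "headconform_config_error")
})

test_that("the planted lead shows up as an anticipatory shift", {
  track <- track_config(n_turns = 4, lap_duration = 20, rate = 90)
  veh <- generate_vehicle_trace(track, "fast")
  m <- head_model(gain = 1, lead_ms = 300, noise_sd = 0, drift_sd = 0)
  tr <- simulate_head_trace(veh, m, seed = 1)
  k <- 27  # 300 ms at 90 Hz
  n <- nrow(veh)
  expect_equal(tr$yaw[1:(n - k)], veh$vehicle_yaw[(1 + k):n],
               tolerance = 1e-9)
})

test_that("ratings follow the latent model and the recording rules", {
  sched <- build_cohort_schedule(design_spec(2), 12)
  flat <- rating_model(
    intercepts = c(vection = 10, sickness = 10, presence = 10),
    coefficients = list(
      vection = c(speed_fast = 0, stationary = 0, direction_reverse = 0,
                  direction_lateral = 0),
      sickness = c(speed_fast = 0, stationary = 0, direction_reverse = 0,
                   direction_lateral = 0),
      presence = c(speed_fast = 0, stationary = 0, direction_reverse = 0,
                   direction_lateral = 0)
    ),
    conformity_beta = c(vection = 0, sickness = 0, presence = 0),
    shared_participant_sd = 0,
    participant_sd = c(vection = 0, sickness = 0, presence = 0),
    residual_sd = 0
  )
  out <- simulate_ratings(sched, config = flat, seed = 5)
  expect_true(all(out$vection_magnitude == 10))
  expect_true(all(out$sickness == 10))
  expect_true(all(out$presence == 10))

  out <- simulate_ratings(sched, config = rating_model(), seed = 6)
  expect_silent(validate_trial_records(out))
  none <- out$vection_magnitude == 1
  expect_true(all(is.na(out$vection_onset[none])))
  felt <- !none
  expect_true(all(out$vection_onset[felt] + out$vection_duration[felt] <=
                    60 + 1e-9))

  # a condition without a coefficient is a configuration error
  broken <- rating_model()
  broken$coefficients$vection <-
    broken$coefficients$vection[names(broken$coefficients$vection) !=
                                  "direction_lateral"]
  expect_error(simulate_ratings(sched, config = broken, seed = 1),
               class = "headconform_config_error",
               regexp = "direction_lateral")
})

test_that("planted speed effects dominate cohort means across seeds", {
  sched <- build_cohort_schedule(design_spec(2), 36)
  wins <- vapply(1:200, function(s) {
    out <- simulate_ratings(sched, config = rating_model(), seed = 1000 + s)
    laps <- out[out$speed != "stationary", ]
    mean(laps$vection_magnitude[laps$speed == "fast"]) >
      mean(laps$vection_magnitude[laps$speed == "slow"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("a noise-free homogeneous cohort is perfectly conformal", {
  co <- generate_cohort(cohort_config(
    experiment = 2, n_participants = 4, seed = 3,
    track = track_config(n_turns = 2, lap_duration = 10, rate = 30),
    head_population = list(gain_mean = 0.12, gain_sd = 0,
                           lead_sd_ms = 0, noise_sd_mean = 0,
                           noise_sd_sd = 0, drift_sd = 0, baseline_sd = 0)
  ))
  yaw <- tidyr::pivot_wider(co$traces[co$traces$speed == "fast",
                                      c("participant_id", "time", "yaw")],
                            names_from = participant_id,
                            values_from = yaw)[-1]
  cors <- cor(as.matrix(yaw))
  expect_equal(unname(cors), matrix(1, 4, 4), tolerance = 1e-9)

  scores <- suppressMessages(conformity_scores(
    center_and_unwrap(co$traces)
  ))
  expect_true(all(abs(scores$r[scores$axis == "yaw"] - 1) < 1e-9))
})

test_that("generation is reproducible and extensible without perturbation", {
  cfg <- function(n) cohort_config(
    experiment = 2, n_participants = n, seed = 11,
    track = track_config(n_turns = 2, lap_duration = 6, rate = 20)
  )
  a <- generate_cohort(cfg(5))
  b <- generate_cohort(cfg(5))
  expect_identical(a$traces, b$traces)
  expect_identical(a$records, b$records)

  bigger <- generate_cohort(cfg(8))
  keep <- unique(a$traces$participant_id)
  first5 <- bigger$traces[bigger$traces$participant_id %in% keep, ]
  expect_equal(as.data.frame(first5), as.data.frame(a$traces),
               tolerance = 1e-12)
  rec5 <- bigger$records[bigger$records$participant_id %in% keep, ]
  expect_equal(as.data.frame(rec5), as.data.frame(a$records),
               tolerance = 1e-12)
})

test_that("analyses never touch the ground-truth sidecar", {
  co <- generate_cohort(cohort_config(
    experiment = 2, n_participants = 6, seed = 2,
    track = track_config(n_turns = 2, lap_duration = 6, rate = 20)
  ))
  pre <- center_and_unwrap(co$traces)
  baseline <- suppressMessages(conformity_scores(pre))
  co$ground_truth <- NULL  # analyses must not notice
  again <- suppressMessages(conformity_scores(center_and_unwrap(co$traces)))
  expect_identical(baseline, again)

  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_false(file.exists(file.path(dir, "ground_truth.csv")))
  co2 <- generate_cohort(cohort_config(
    experiment = 2, n_participants = 6, seed = 2,
    track = track_config(n_turns = 2, lap_duration = 6, rate = 20)
  ))
  write_cohort(co2, dir)
  expect_true(file.exists(file.path(dir, "ground_truth.csv")))
})

test_that("conformity scores recover the ranking of planted gains", {
  track <- track_config(rate = 30)
  veh <- generate_vehicle_trace(track, "fast")
  g <- seq(0.05, 0.25, length.out = 20)
  rhos <- vapply(1:200, function(rep) {
    traces <- purrr::map_dfr(seq_along(g), function(i) {
      m <- head_model(gain = g[i], lead_ms = 750, noise_sd = 1.8,
                      drift_sd = 0)
      tibble::add_column(
        simulate_head_trace(veh, m, seed = 7000 + rep * 37 + i),
        participant_id = sprintf("P%02d", i), .before = 1
      )
    })
    sc <- suppressMessages(
      conformity_scores(center_and_unwrap(traces), axes = "yaw")
    )
    idx <- as.integer(sub("P", "", sc$participant_id))
    cor(sc$r, g[idx], method = "spearman")
  }, numeric(1))
  expect_gte(mean(rhos), 0.9)
})
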