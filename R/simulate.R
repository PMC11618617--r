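#' Configuration objects for the synthetic study generator
#'
#' The generator emulates the study the analysis functions expect: 60-s laps
#' sampled at 90 Hz (5400 points), a fixed pre-recorded lap whose slow
#' version is the fast lap replayed at half speed, head yaw tracking the
#' track's turns a few hundred milliseconds early with a few degrees of
#' excursion, and 1-20 ordinal ratings with planted condition effects and a
#' planted coupling between yaw conformity and the ratings.
#'
#' `track_config()` describes the lap: `n_turns` alternating left/right
#' raised-cosine yaw lobes (smooth, with bounded derivative, so velocity
#' summaries are well defined) of amplitude `turn_amplitude` degrees, with
#' per-turn amplitude jitter drawn once from `track_seed` so the lap is one
#' fixed track shared by every participant.
#'
#' @param n_turns Number of turns in the fast lap.
#' @param turn_amplitude Peak vehicle yaw excursion per turn, degrees.
#' @param turn_duration Duration of one turn lobe, seconds; turns are spaced
#'   evenly with straight (zero-yaw) segments filling the remainder. The
#'   default (0.44 of each turn's slot) gives distinct 2.2-s corners on the
#'   default 12-turn lap, the cadence of a fast one-minute segment of a
#'   twisty circuit.
#' @param lap_duration Lap length, seconds.
#' @param rate Sampling rate, Hz; `rate * lap_duration` must be an integer.
#' @param amplitude_jitter Relative spread of per-turn amplitudes.
#' @param track_seed Seed fixing the track layout.
#' @return A `track_config` list.
#' @export
track_config <- function(n_turns = 12, turn_amplitude = 30,
                         turn_duration = 0.44 * lap_duration / max(n_turns, 1),
                         lap_duration = 60, rate = 90,
                         amplitude_jitter = 0.3, track_seed = 19L) {
  n_samples <- rate * lap_duration
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    abort_config("rate * lap_duration must be an integer sample count")
  }
  if (n_turns == 0 && turn_amplitude != 0) {
    abort_config("A track with zero turns cannot have a nonzero turn amplitude")
  }
  if (n_turns > 0 && n_turns * turn_duration > lap_duration + 1e-9) {
    abort_config("Turns do not fit in the lap: n_turns * turn_duration > lap_duration")
  }
  structure(list(n_turns = n_turns, turn_amplitude = turn_amplitude,
                 turn_duration = turn_duration, lap_duration = lap_duration,
                 rate = rate, amplitude_jitter = amplitude_jitter,
                 track_seed = as.integer(track_seed)),
            class = "track_config")
}

# Continuous-time fast-lap yaw profile; the slow lap is this evaluated at
# t / 2 (half-speed playback covers half the track in the same 60 s).
vehicle_yaw_fun <- function(track) {
  n <- track$n_turns
  if (n == 0 || track$turn_amplitude == 0) {
    return(function(t) rep(0, length(t)))
  }
  set.seed(track$track_seed)
  amps <- track$turn_amplitude * (1 + runif(n, -1, 1) *
                                    track$amplitude_jitter)
  signs <- rep_len(c(1, -1), n)
  gap <- (track$lap_duration - n * track$turn_duration) / (n + 1)
  starts <- gap + (seq_len(n) - 1) * (track$turn_duration + gap)
  function(t) {
    y <- numeric(length(t))
    for (k in seq_len(n)) {
      u <- (t - starts[k]) / track$turn_duration
      inside <- u >= 0 & u <= 1
      # raised-cosine lobe: zero value and zero slope at both ends
      y[inside] <- y[inside] +
        signs[k] * amps[k] * (1 - cos(2 * pi * u[inside])) / 2
    }
    y
  }
}

#' Generate a vehicle yaw trace for one lap
#'
#' @param track A [track_config()].
#' @param speed `"fast"` or `"slow"`; the slow lap is the fast lap replayed
#'   at half speed over the same 60-s window (`slow(t) = fast(t / 2)`).
#' @return A tibble with `time`, `vehicle_yaw`, `speed`, `lap_id`.
#' @export
#' @examples
#' v <- generate_vehicle_trace(track_config(n_turns = 6), "fast")
#' range(v$vehicle_yaw)
generate_vehicle_trace <- function(track, speed = c("fast", "slow")) {
  speed <- match.arg(speed)
  f <- vehicle_yaw_fun(track)
  n <- round(track$rate * track$lap_duration)
  t <- (seq_len(n) - 1) / track$rate
  yaw <- if (speed == "fast") f(t) else f(t / 2)
  tibble(time = t, vehicle_yaw = yaw, speed = speed,
         lap_id = paste0("lap_", speed))
}

#' Per-participant head-motion model parameters
#'
#' Head yaw is modelled as a gain-scaled, time-advanced copy of vehicle yaw
#' plus two noise processes:
#' `yaw(t) = gain * vehicle_yaw(t + lead) + tremor(t) + drift(t)`.
#' The tremor is sample-level tracker jitter, AR(1) in position with a
#' default coefficient of 0 (white); tiny in amplitude, it sets the velocity
#' floor of a seated head wearing a headset. The drift is a slow postural wander
#' modelled as integrated AR(1) velocity -- smooth at the sample scale, so
#' it moves the head several degrees over a lap while adding little to mean
#' absolute velocity, exactly the combination seated observers show.
#' Pitch and roll are attenuated copies of the yaw signal component (fixed
#' small gains) with their own independent noise. `lead_ms >= 0` means the
#' head turns *before* the vehicle does.
#'
#' @param gain Conformity gain applied to vehicle yaw (dimensionless).
#' @param lead_ms Anticipatory lead, milliseconds.
#' @param noise_sd Marginal SD of the yaw tremor AR(1), degrees.
#' @param ar_coef Tremor AR(1) coefficient in \[0, 1).
#' @param drift_sd Position SD of the yaw postural wander at lap end,
#'   degrees.
#' @param drift_tau Velocity correlation time of the wander, seconds.
#' @param pitch_gain,roll_gain Attenuation of the yaw signal on the other
#'   axes.
#' @param pitch_noise_sd,roll_noise_sd Tremor SDs of the other axes,
#'   degrees.
#' @param pitch_drift_scale,roll_drift_scale Wander SD of the other axes
#'   relative to `drift_sd`.
#' @param baseline_sd SD of the random constant orientation offset per
#'   channel, degrees (exercises centring; zero by default).
#' @return A `head_model` list.
#' @export
head_model <- function(gain = 0.12, lead_ms = 750, noise_sd = 0.016,
                       ar_coef = 0, drift_sd = 6.3, drift_tau = 0.15,
                       pitch_gain = 0.35, roll_gain = 0.22,
                       pitch_noise_sd = 0.65 * noise_sd,
                       roll_noise_sd = 0.55 * noise_sd,
                       pitch_drift_scale = 0.55, roll_drift_scale = 0.36,
                       baseline_sd = 0) {
  if (noise_sd < 0 || pitch_noise_sd < 0 || roll_noise_sd < 0 ||
        drift_sd < 0 || baseline_sd < 0) {
    abort_config("Noise, drift, and baseline SDs must be non-negative")
  }
  if (gain < 0) abort_config("Conformity gain must be non-negative")
  if (ar_coef < 0 || ar_coef >= 1) {
    abort_config("ar_coef must be in [0, 1)")
  }
  if (drift_tau <= 0) abort_config("drift_tau must be positive")
  structure(as.list(environment()), class = "head_model")
}

ar1_noise <- function(n, sd, coef) {
  if (sd == 0) return(numeric(n))
  innov <- rnorm(n, 0, sd * sqrt(1 - coef^2))
  as.numeric(filter(innov, coef, method = "recursive",
                    init = rnorm(1, 0, sd)))
}

# Smooth postural wander: AR(1) velocity integrated to position, scaled so
# the position SD at lap end is `sd` degrees. Var(pos(T)) ~ sd_v^2 * 2 tau T
# for T >> tau.
drift_wander <- function(n, sd, tau, rate) {
  if (sd == 0) return(numeric(n))
  duration <- n / rate
  sd_v <- sd / sqrt(2 * tau * duration)
  phi <- exp(-1 / (rate * tau))
  v <- ar1_noise(n, sd_v, phi)
  cumsum(v) / rate
}

#' Simulate one participant's head trace for a lap
#'
#' @param vehicle A vehicle trace from [generate_vehicle_trace()].
#' @param params A [head_model()].
#' @param seed Integer seed; the trace is a pure function of
#'   `(vehicle, params, seed)`.
#' @return A head trace tibble (`time`, `pitch`, `yaw`, `roll`) on the
#'   vehicle's grid, in raw (uncentred) degrees.
#' @export
simulate_head_trace <- function(vehicle, params = head_model(), seed = 1L) {
  ch <- simulate_head_channels(vehicle$time, vehicle$vehicle_yaw, params,
                               seed)
  tibble(time = vehicle$time, pitch = ch$pitch, yaw = ch$yaw,
         roll = ch$roll)
}

simulate_head_channels <- function(t, vehicle_yaw, params, seed) {
  if (!inherits(params, "head_model")) {
    abort_config("`params` must be a head_model object")
  }
  set.seed(as.integer(seed))
  n <- length(t)
  rate <- if (n > 1) 1 / median(diff(t)) else 1
  # Sample the vehicle channel at t + lead (boundary values held), so the
  # head shows the turn `lead_ms` before the vehicle does.
  advanced <- approx(t, vehicle_yaw, xout = t + params$lead_ms / 1000,
                     rule = 2)$y
  signal <- params$gain * advanced
  channel <- function(gain_scale, tremor_sd, drift_scale) {
    gain_scale * signal +
      ar1_noise(n, tremor_sd, params$ar_coef) +
      drift_wander(n, params$drift_sd * drift_scale, params$drift_tau,
                   rate) +
      rnorm(1, 0, params$baseline_sd)
  }
  list(
    yaw = channel(1, params$noise_sd, 1),
    pitch = channel(params$pitch_gain, params$pitch_noise_sd,
                    params$pitch_drift_scale),
    roll = channel(params$roll_gain, params$roll_noise_sd,
                   params$roll_drift_scale)
  )
}

#' Rating-generation model for the synthetic cohort
#'
#' Each self-report measure (vection magnitude, sickness, presence) is an
#' integer 1-20 produced by rounding and clamping a Gaussian latent:
#' intercept + condition effects + participant effects + conformity coupling
#' + residual. Vection and presence share a participant-level
#' "responsiveness" component, which is what makes their participant-mean
#' correlation strongly positive; sickness gets an independent participant
#' effect. The conformity coupling adds `beta * z` rating points, where `z`
#' is the participant's yaw-conformity standardised within the cohort and
#' speed condition.
#'
#' Defaults plant the study's qualitative structure: fast laps boost vection,
#' sickness, and presence; reduced visual-cue availability (viewpoint pitched
#' up relative to the virtual road) lowers vection; reverse and lateral
#' driving lower vection (forward > reverse > lateral) and sickness;
#' stationary baselines sit near the bottom of the scales.
#'
#' @param intercepts Named numeric: latent means of the three measures in
#'   the slow, upright, aligned, forward reference condition.
#' @param coefficients Named list of named numeric vectors (one per
#'   measure): effects for `speed_fast`, `stationary`, `posture_reclined`,
#'   `alignment_misaligned`, `cue_unavailable`, `direction_reverse`,
#'   `direction_lateral`, in rating points.
#' @param conformity_beta Named numeric: rating points per SD of yaw
#'   conformity.
#' @param conformity_center,conformity_scale Fixed reference mean and SD
#'   used to standardise conformity before coupling; fixed (rather than
#'   cohort-sample) constants keep each participant's ratings a function of
#'   their own trace alone.
#' @param shared_participant_sd SD of the participant component shared by
#'   vection and presence.
#' @param participant_sd Named numeric: measure-specific participant SDs.
#' @param residual_sd Residual latent SD, rating points.
#' @param onset_mean,onset_sd Vection onset distribution (s), truncated to
#'   \[1, 40\].
#' @param duration_range Vection duration as a uniform fraction of the time
#'   remaining after onset.
#' @return A `rating_model` list.
#' @export
rating_model <- function(
    intercepts = c(vection = 9, sickness = 4, presence = 12),
    coefficients = list(
      vection = c(speed_fast = 1.5, stationary = -7, posture_reclined = 0,
                  alignment_misaligned = 0, cue_unavailable = -0.8,
                  direction_reverse = -1.2, direction_lateral = -2.4),
      sickness = c(speed_fast = 0.8, stationary = -2.5,
                   posture_reclined = -0.3, alignment_misaligned = 0.3,
                   cue_unavailable = 0, direction_reverse = -1,
                   direction_lateral = -1),
      presence = c(speed_fast = 1.2, stationary = -3, posture_reclined = -0.5,
                   alignment_misaligned = -0.2, cue_unavailable = 0,
                   direction_reverse = -0.3, direction_lateral = -0.4)
    ),
    conformity_beta = c(vection = 1.45, sickness = 0.75, presence = 1.1),
    conformity_center = 0.45, conformity_scale = 0.27,
    shared_participant_sd = 2,
    participant_sd = c(vection = 0.8, sickness = 1.5, presence = 0.8),
    residual_sd = 2,
    onset_mean = 12, onset_sd = 5,
    duration_range = c(0.3, 0.95)) {
  structure(as.list(environment()), class = "rating_model")
}

rating_measures <- c("vection", "sickness", "presence")

# Map a schedule row to the coefficient names its condition requires.
condition_terms <- function(schedule) {
  terms <- vector("list", nrow(schedule))
  cue_unavailable <- !is.na(schedule$posture) &
    ((schedule$posture == "upright" & schedule$alignment == "misaligned") |
       (schedule$posture == "reclined" & schedule$alignment == "aligned"))
  for (i in seq_len(nrow(schedule))) {
    tt <- character(0)
    if (schedule$speed[i] == "fast") tt <- c(tt, "speed_fast")
    if (schedule$speed[i] == "stationary") tt <- c(tt, "stationary")
    if (!is.na(schedule$posture[i]) && schedule$posture[i] == "reclined") {
      tt <- c(tt, "posture_reclined")
    }
    if (!is.na(schedule$alignment[i]) &&
          schedule$alignment[i] == "misaligned") {
      tt <- c(tt, "alignment_misaligned")
    }
    if (cue_unavailable[i]) tt <- c(tt, "cue_unavailable")
    if (!is.na(schedule$direction[i]) &&
          schedule$direction[i] == "reverse") {
      tt <- c(tt, "direction_reverse")
    }
    if (!is.na(schedule$direction[i]) &&
          schedule$direction[i] == "lateral") {
      tt <- c(tt, "direction_lateral")
    }
    terms[[i]] <- tt
  }
  terms
}

#' Simulate self-report ratings for a trial schedule
#'
#' @param schedule A cohort schedule tibble from [build_cohort_schedule()]
#'   (columns `participant_id`, `posture`, `alignment`, `direction`,
#'   `speed`).
#' @param conformity Optional per-participant yaw conformity: a tibble with
#'   `participant_id`, `speed`, `r`. Standardised within speed and coupled
#'   into the latents via `conformity_beta`; `NULL` plants no coupling.
#' @param config A [rating_model()].
#' @param seed Integer seed.
#' @param lap_duration Lap length in seconds (bounds onset + duration).
#' @return The schedule with `vection_magnitude`, `vection_onset`,
#'   `vection_duration`, `sickness`, `presence` columns appended; satisfies
#'   [validate_trial_records()].
#' @export
simulate_ratings <- function(schedule, conformity = NULL,
                             config = rating_model(), seed = 1L,
                             lap_duration = 60) {
  if (!inherits(config, "rating_model")) {
    abort_config("`config` must be a rating_model object")
  }
  for (col in c("posture", "alignment", "direction")) {
    if (!col %in% names(schedule)) schedule[[col]] <- NA_character_
  }
  terms <- condition_terms(schedule)
  needed <- unique(unlist(terms))
  for (m in rating_measures) {
    missing <- setdiff(needed, names(config$coefficients[[m]]))
    if (length(missing) > 0) {
      abort_config(sprintf(
        "rating_model is missing %s coefficient(s) for scheduled condition(s): %s",
        m, paste(missing, collapse = ", ")
      ))
    }
  }
  # Per-participant substreams: a participant's effects, residuals, and
  # onset/duration draws depend only on (seed, participant index), so
  # enlarging the cohort never perturbs earlier members.
  participants <- unique(schedule$participant_id)
  row_part <- match(schedule$participant_id, participants)
  shared_vec <- numeric(nrow(schedule))
  own_vec <- matrix(0, nrow(schedule), length(rating_measures),
                    dimnames = list(NULL, rating_measures))
  resid_vec <- matrix(0, nrow(schedule), length(rating_measures),
                      dimnames = list(NULL, rating_measures))
  onset_raw <- numeric(nrow(schedule))
  frac_raw <- numeric(nrow(schedule))
  for (i in seq_along(participants)) {
    rows <- which(row_part == i)
    set.seed(substream_seed(seed, i, 11L))
    shared_vec[rows] <- rnorm(1, 0, config$shared_participant_sd)
    for (m in rating_measures) {
      own_vec[rows, m] <- rnorm(1, 0, config$participant_sd[[m]])
      resid_vec[rows, m] <- rnorm(length(rows), 0, config$residual_sd)
    }
    onset_raw[rows] <- rnorm(length(rows), config$onset_mean,
                             config$onset_sd)
    frac_raw[rows] <- runif(length(rows), config$duration_range[1],
                            config$duration_range[2])
  }

  z <- numeric(nrow(schedule))
  if (!is.null(conformity)) {
    # standardised against fixed reference constants (not the cohort
    # sample), so a participant's ratings depend only on their own trace
    zval <- (conformity$r - config$conformity_center) /
      config$conformity_scale
    key <- paste(schedule$participant_id, schedule$speed)
    lookup <- setNames(zval, paste(conformity$participant_id,
                                   conformity$speed))
    z <- unname(lookup[key])
    z[is.na(z)] <- 0  # stationary trials have no lap conformity
  }

  out <- schedule
  for (m in rating_measures) {
    coefs <- config$coefficients[[m]]
    effect <- vapply(terms, function(tt) sum(coefs[tt]), numeric(1))
    latent <- config$intercepts[[m]] + effect +
      own_vec[, m] +
      (if (m %in% c("vection", "presence")) shared_vec else 0) +
      config$conformity_beta[[m]] * z +
      resid_vec[, m]
    col <- if (m == "vection") "vection_magnitude" else m
    out[[col]] <- pmin(pmax(round(latent), 1), 20)
  }

  felt <- out$vection_magnitude >= 2
  onset <- pmin(pmax(onset_raw, 1), min(40, lap_duration - 1))
  duration <- frac_raw * (lap_duration - onset)
  out$vection_onset <- ifelse(felt, round(onset, 1), NA_real_)
  out$vection_duration <- ifelse(felt, round(duration, 1), NA_real_)
  out
}

substream_seed <- function(master, i, k = 0L) {
  ((as.double(master) %% 65011) * 33029 + i * 977 + k * 131) %% 2147483629 + 1
}

#' Full synthetic-study configuration
#'
#' @param experiment `1` or `2`.
#' @param n_participants Cohort size; defaults to the study sizes (52 for
#'   experiment 1, 36 for experiment 2).
#' @param seed Master seed; every participant gets an independent substream
#'   derived from it by a counter scheme, so enlarging the cohort never
#'   perturbs earlier participants.
#' @param track A [track_config()].
#' @param head_population Named list of population parameters for the
#'   per-participant [head_model()] draws: `gain_mean`, `gain_sd`,
#'   `lead_mean_ms`, `lead_sd_ms`, `noise_sd_mean`, `noise_sd_sd`,
#'   `ar_coef`, `drift_sd`, `pitch_gain`, `roll_gain`, `baseline_sd`.
#' @param ratings A [rating_model()].
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(experiment = 1,
                          n_participants = if (experiment == 1) 52 else 36,
                          seed = 1L,
                          track = track_config(),
                          head_population = list(),
                          ratings = rating_model()) {
  pop <- utils::modifyList(list(
    gain_mean = 0.12, gain_sd = 0.04,
    lead_mean_ms = 750, lead_sd_ms = 100,
    noise_sd_mean = 0.016, noise_sd_sd = 0.005,
    ar_coef = 0, drift_sd = 6.3,
    pitch_gain = 0.35, roll_gain = 0.22,
    baseline_sd = 3
  ), head_population)
  structure(list(experiment = experiment, n_participants = n_participants,
                 seed = as.integer(seed), track = track,
                 head_population = pop, ratings = ratings),
            class = "cohort_config")
}

truncated_normal <- function(n, mean, sd, lower) {
  pmax(rnorm(n, mean, sd), lower)
}

#' Generate a complete synthetic study with known ground truth
#'
#' Composes the schedule, track, head-trace, and rating generators into a
#' full dataset shaped exactly like the CSV family the readers expect, plus
#' a ground-truth record of every planted parameter. The ground truth is for
#' validation and parameter-recovery checks only; no analysis function reads
#' it.
#'
#' Head kinematics are modelled as condition-independent apart from speed:
#' one head trace per participant and speed condition, standing for the
#' upright, world-aligned, forward-facing lap that every participant
#' experiences and that the combined head-motion analysis uses. The
#' generator-side conformity driving the rating coupling is the correlation
#' of each participant's yaw trace with the clean track profile.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `traces` (head traces, raw degrees),
#'   `vehicle` (the two lap traces), `records` (validated trial records),
#'   `schedule`, and `ground_truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort_config("`config` must be a cohort_config object")
  }
  design <- design_spec(config$experiment)
  schedule <- withCallingHandlers(
    build_cohort_schedule(design, config$n_participants),
    headconform_balance_warning = function(w) {
      invokeRestart("muffleWarning")
    }
  )
  schedule$experiment <- config$experiment

  vehicle <- dplyr::bind_rows(
    generate_vehicle_trace(config$track, "slow"),
    generate_vehicle_trace(config$track, "fast")
  )

  pop <- config$head_population
  ids <- unique(schedule$participant_id)
  # Per-participant parameter substreams: participant i's draws depend only
  # on (seed, i), so enlarging the cohort never perturbs earlier members.
  draws <- vapply(seq_along(ids), function(i) {
    set.seed(substream_seed(config$seed, i, 0L))
    c(gain = truncated_normal(1, pop$gain_mean, pop$gain_sd, 0.01),
      lead_ms = truncated_normal(1, pop$lead_mean_ms, pop$lead_sd_ms, 0),
      noise_sd = truncated_normal(1, pop$noise_sd_mean, pop$noise_sd_sd,
                                  0))
  }, numeric(3))
  params <- tibble(
    participant_id = ids,
    gain = draws["gain", ],
    lead_ms = draws["lead_ms", ],
    noise_sd = draws["noise_sd", ]
  )

  # Traces are assembled channel-matrix first (one allocation per speed)
  # rather than participant-by-participant: cohort generation sits inside
  # Monte-Carlo loops.
  speeds <- c("slow", "fast")
  by_speed <- lapply(speeds, function(sp) {
    v <- vehicle[vehicle$speed == sp, ]
    n_t <- nrow(v)
    chan <- list(pitch = matrix(0, n_t, length(ids)),
                 yaw = matrix(0, n_t, length(ids)),
                 roll = matrix(0, n_t, length(ids)))
    for (i in seq_along(ids)) {
      model <- head_model(
        gain = params$gain[i], lead_ms = params$lead_ms[i],
        noise_sd = params$noise_sd[i], ar_coef = pop$ar_coef,
        drift_sd = pop$drift_sd, pitch_gain = pop$pitch_gain,
        roll_gain = pop$roll_gain, baseline_sd = pop$baseline_sd
      )
      ch <- simulate_head_channels(
        v$time, v$vehicle_yaw, model,
        seed = substream_seed(config$seed, i, if (sp == "slow") 1L else 2L)
      )
      chan$pitch[, i] <- ch$pitch
      chan$yaw[, i] <- ch$yaw
      chan$roll[, i] <- ch$roll
    }
    list(speed = sp, time = v$time, vehicle_yaw = v$vehicle_yaw,
         chan = chan)
  })
  traces <- dplyr::bind_rows(lapply(by_speed, function(b) {
    tibble(
      participant_id = rep(ids, each = length(b$time)),
      speed = b$speed,
      time = rep(b$time, length(ids)),
      pitch = as.vector(b$chan$pitch),
      yaw = as.vector(b$chan$yaw),
      roll = as.vector(b$chan$roll)
    )
  }))

  # Generator-side conformity: correlation of each yaw trace with the clean
  # normative head profile -- the track's yaw advanced by the typical
  # anticipatory lead (what the cohort median trace looks like without
  # noise). Location-invariant, so raw traces are fine.
  conf <- dplyr::bind_rows(lapply(by_speed, function(b) {
    normative <- approx(b$time, b$vehicle_yaw,
                        xout = b$time + pop$lead_mean_ms / 1000,
                        rule = 2)$y
    tibble(participant_id = ids, speed = b$speed,
           r = as.vector(cor(b$chan$yaw, normative)))
  })) |>
    dplyr::arrange(.data$participant_id, .data$speed)

  records <- simulate_ratings(
    schedule, conformity = conf, config = config$ratings,
    seed = substream_seed(config$seed, 0L, 3L),
    lap_duration = config$track$lap_duration
  )
  records <- validate_trial_records(records,
                                    lap_duration = config$track$lap_duration)

  structure(list(
    traces = traces,
    vehicle = vehicle,
    records = records,
    schedule = schedule,
    ground_truth = list(participants = params,
                        generator_conformity = conf,
                        rating_model = config$ratings,
                        head_population = pop,
                        track = config$track)
  ), class = "synthetic_cohort")
}

#' Pool the head-motion cohorts of two experiments
#'
#' The upright, world-aligned, forward-facing lap is common to both designs,
#' so their head traces can be analysed as one larger cohort (52 + 36 = 88
#' in the study sizes). Participant ids are prefixed by experiment to stay
#' unique.
#'
#' @param ... `synthetic_cohort` objects (or lists with `traces`, `records`,
#'   `vehicle`).
#' @return A list with pooled `traces`, `records`, and the shared `vehicle`
#'   traces.
#' @export
combine_cohorts <- function(...) {
  cohorts <- list(...)
  tag <- function(x, i, col = "participant_id") {
    x[[col]] <- paste0("E", i, "_", x[[col]])
    x
  }
  list(
    traces = purrr::imap_dfr(cohorts, function(c, i) tag(c$traces, i)),
    records = purrr::imap_dfr(cohorts, function(c, i) tag(c$records, i)),
    vehicle = cohorts[[1]]$vehicle
  )
}
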