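test_that("within-subject ANOVA matches the sum-of-squares oracle", {
  configs <- list(
    list(n = 4, levels = c(2, 2), seed = 1),
    list(n = 6, levels = c(2, 3), seed = 2),
    list(n = 5, levels = c(3, 2), seed = 3),
    list(n = 6, levels = c(2, 2, 2), seed = 4),
    list(n = 4, levels = c(2, 2, 3), seed = 5)
  )
  for (cfg in configs) {
    data <- make_anova_data(cfg$n, cfg$levels, cfg$seed)
    within <- grep("^w", names(data), value = TRUE)
    fit <- rm_anova(data, "score", within = within)
    o <- oracle_rm_anova(as.data.frame(data), "score", within,
                         "participant_id")
    for (i in seq_len(nrow(o))) {
      row <- fit[fit$effect == o$effect[i], ]
      expect_equal(nrow(row), 1)
      expect_equal(row$F, o$F[i], tolerance = 1e-9)
      expect_equal(row$p, o$p[i], tolerance = 1e-9)
      expect_equal(row$eta_p, o$eta_p[i], tolerance = 1e-9)
      expect_equal(row$df_num, o$df_num[i])
      expect_equal(row$df_den, o$df_den[i])
    }
  }
})

test_that("a constant dependent measure yields F = 0 everywhere", {
  data <- make_anova_data(4, c(2, 2), seed = 9)
  data$score <- 7
  fit <- rm_anova(data, "score", within = c("w1", "w2"))
  expect_true(all(fit$F == 0))
  expect_true(all(fit$p == 1))
  expect_true(all(fit$eta_p == 0))
})

test_that("incomplete or inconsistent designs are rejected with names", {
  data <- make_anova_data(4, c(2, 2), seed = 10)
  expect_error(rm_anova(data[-3, ], "score", within = c("w1", "w2")),
               class = "headconform_inference_error", regexp = "S01")
  dup <- rbind(data, data[1, ])
  expect_error(rm_anova(dup, "score", within = c("w1", "w2")),
               class = "headconform_inference_error", regexp = "2 observ")

  data$sex <- rep(c("f", "m"), length.out = nrow(data))  # varies within
  expect_error(rm_anova(data, "score", within = c("w1", "w2"),
                        between = "sex"),
               class = "headconform_inference_error", regexp = "sex")
})

test_that("non-integer ratings are accepted with a warning", {
  data <- make_anova_data(4, c(2, 2), seed = 11)
  data$score <- data$score + 0.5
  expect_warning(rm_anova(data, "score", within = c("w1", "w2")),
                 class = "headconform_noninteger_warning")
})

test_that("between-subjects moderation screens have the right strata", {
  data <- make_anova_data(8, c(2, 2), seed = 12)
  sex <- setNames(rep(c("f", "m"), each = 4), sprintf("S%02d", 1:8))
  data$sex <- sex[data$participant_id]
  fit <- rm_anova(data, "score", within = c("w1", "w2"), between = "sex")
  sex_row <- fit[fit$effect == "sex", ]
  expect_equal(sex_row$df_num, 1)
  expect_equal(sex_row$df_den, 6)  # subjects within groups
  w1_row <- fit[fit$effect == "w1", ]
  expect_equal(w1_row$df_den, 6)
  expect_true(all(fit$eta_p >= 0 & fit$eta_p <= 1))
  expect_true("sex:w1" %in% fit$effect)
})

test_that("stationary baselines are excluded from condition ANOVAs", {
  records <- simulate_ratings(build_cohort_schedule(design_spec(2), 12),
                              config = rating_model(), seed = 3)
  fit <- rm_anova(records, "vection_magnitude",
                  within = c("direction", "speed"))
  speed_row <- fit[fit$effect == "speed", ]
  expect_equal(speed_row$df_num, 1)  # slow vs fast only
  expect_equal(speed_row$df_den, 11)
  expect_equal(fit$df_num[fit$effect == "direction"], 2)
})

test_that("Greenhouse-Geisser correction shrinks df and keeps F", {
  data <- make_anova_data(8, c(3, 2), seed = 13)
  plain <- rm_anova(data, "score", within = c("w1", "w2"))
  gg <- rm_anova(data, "score", within = c("w1", "w2"),
                 correction = "greenhouse-geisser")
  i <- which(plain$effect == "w1")
  expect_equal(gg$F[i], plain$F[i])
  expect_lte(gg$df_num[i], plain$df_num[i])
  expect_gte(gg$df_num[i], plain$df_num[i] / 2)  # eps >= 1/(k-1)
  # corrected p is recomputed from F at the shrunken df
  expect_equal(gg$p[i],
               pf(gg$F[i], gg$df_num[i], gg$df_den[i], lower.tail = FALSE),
               tolerance = 1e-12)
  if (plain$F[i] > 1) expect_gte(gg$p[i], plain$p[i])
  # single-df effects are untouched
  j <- which(plain$effect == "w2")
  expect_equal(gg$df_num[j], plain$df_num[j])
})

test_that("tidy and glance expose the fitted table and its metadata", {
  data <- make_anova_data(4, c(2, 2), seed = 14)
  fit <- rm_anova(data, "score", within = c("w1", "w2"))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "headconform_anova"))
  gl <- glance(fit)
  expect_equal(gl$n_participants, 4)
  expect_equal(gl$dv, "score")
})

test_that("null condition effects give uniform ANOVA p-values", {
  ps <- vapply(1:400, function(s) {
    data <- make_anova_data(6, c(2, 2), seed = 20000 + s)
    fit <- rm_anova(data, "score", within = c("w1", "w2"))
    fit$p[fit$effect == "w1"]
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("pearson_assoc reproduces the textbook formula and its guards", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(pearson_assoc(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_assoc(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(15)
  y <- rnorm(6)
  pa <- pearson_assoc(x, y)
  expect_equal(pa$r, oracle_pearson(x, y), tolerance = 1e-9)
  r <- pa$r
  t_stat <- r * sqrt(4 / (1 - r^2))
  expect_equal(pa$p, 2 * pt(-abs(t_stat), 4), tolerance = 1e-9)

  expect_true(pearson_assoc(rep(1, 5), y[1:5])$degenerate)
  expect_error(pearson_assoc(1:2, 2:3),
               class = "headconform_inference_error")
})

test_that("the association table is the full measure-axis-speed grid", {
  co <- generate_cohort(cohort_config(
    experiment = 2, n_participants = 10, seed = 21,
    track = track_config(n_turns = 3, lap_duration = 12, rate = 30)
  ))
  scores <- suppressMessages(conformity_scores(center_and_unwrap(co$traces)))
  tab <- conformity_association_table(scores, co$records)
  expect_equal(nrow(tab), 18)
  expect_equal(dplyr::n_distinct(tab$dv), 3)
  expect_equal(dplyr::n_distinct(tab$axis), 3)
  expect_equal(dplyr::n_distinct(tab$speed), 2)
  expect_false(any(tab$insufficient_n))
  expect_true(all(tab$n == 10))

  # too few joinable pairs flags rather than errors
  tiny <- scores[scores$participant_id %in% unique(scores$participant_id)[1:2], ]
  tab2 <- conformity_association_table(tiny, co$records)
  expect_true(all(tab2$insufficient_n))
})

test_that("non-reference condition rows are excluded from the association join", {
  co <- generate_cohort(cohort_config(
    experiment = 1, n_participants = 8, seed = 22,
    track = track_config(n_turns = 3, lap_duration = 12, rate = 30)
  ))
  scores <- suppressMessages(conformity_scores(center_and_unwrap(co$traces)))
  tab <- conformity_association_table(scores, co$records)
  # experiment 1 has one upright/aligned lap per speed per participant
  expect_true(all(tab$n == 8))
})

test_that("participant-mean rating correlations carry the planted coupling", {
  sched <- suppressWarnings(build_cohort_schedule(design_spec(2), 40))
  records <- simulate_ratings(sched, config = rating_model(), seed = 30)
  cors <- rating_correlations(records)
  vp <- cors[cors$measure_1 == "vection" & cors$measure_2 == "presence", ]
  expect_gt(vp$r, 0.5)  # shared responsiveness component
  expect_equal(nrow(cors), 3)
  expect_equal(vp$n, 40)
})
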