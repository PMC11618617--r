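#' Repeated-measures factorial ANOVA with partial eta squared
#'
#' Fits the within-subjects (optionally mixed) factorial ANOVA the
#' self-report analyses use: every within-subject effect is tested against
#' its own effect-by-participant error stratum, and effect size is partial
#' eta squared, `SS_effect / (SS_effect + SS_error)`. No sphericity
#' correction is applied by default and p-values are not adjusted for
#' multiple testing, matching the convention of reporting plain df and raw
#' p per effect. Stationary-baseline trials (rows with `speed ==
#' "stationary"`) are excluded: the factorial conditions are the lap trials.
#'
#' @param records Trial-record tibble (one row per participant and
#'   condition).
#' @param dv Name of the dependent measure column.
#' @param within Character vector of within-subject factor columns.
#' @param between Optional character vector of between-subjects factor
#'   columns (e.g. sex, counterbalancing order) for moderation screens.
#' @param participant Name of the participant id column.
#' @param correction `"none"` (default) or `"greenhouse-geisser"`; the
#'   latter applies the Greenhouse-Geisser epsilon to the df and p of
#'   within-subject effects with more than one numerator df.
#' @return A `headconform_anova` tibble: one row per effect with `effect`,
#'   `df_num`, `df_den`, `ss_effect`, `ss_error`, `F`, `p`, `eta_p`.
#' @export
rm_anova <- function(records, dv, within, between = NULL,
                     participant = "participant_id",
                     correction = c("none", "greenhouse-geisser")) {
  correction <- match.arg(correction)
  needed <- c(dv, within, between, participant)
  missing <- setdiff(needed, names(records))
  if (length(missing) > 0) {
    abort_inference(sprintf("Column(s) not found in records: %s",
                            paste(missing, collapse = ", ")))
  }
  data <- as.data.frame(records)
  if ("speed" %in% names(data)) {
    data <- data[data$speed != "stationary", , drop = FALSE]
  }
  data <- data[c(participant, within, between, dv)]
  if (anyNA(data[[dv]])) {
    abort_inference(sprintf("Dependent measure '%s' contains missing values",
                            dv))
  }
  y <- data[[dv]]
  if (any(abs(y - round(y)) > 1e-9)) {
    warn(sprintf("'%s' contains non-integer values; treated as continuous",
                 dv),
         class = "headconform_noninteger_warning")
  }
  for (col in c(participant, within, between)) {
    data[[col]] <- factor(data[[col]])
  }

  # Balanced completeness: each participant must fill every within-cell once.
  cells <- interaction(data[within], drop = FALSE, sep = ":")
  counts <- table(data[[participant]], cells)
  bad <- which(counts != 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort_inference(sprintf(
      "Unbalanced design: participant '%s' has %d observation(s) in cell '%s' (expected 1)",
      rownames(counts)[bad[1, 1]],
      counts[bad[1, 1], bad[1, 2]],
      colnames(counts)[bad[1, 2]]
    ))
  }
  for (b in between) {
    varying <- tapply(data[[b]], data[[participant]],
                      function(v) length(unique(v)))
    if (any(varying > 1)) {
      abort_inference(sprintf(
        "Between-subjects factor '%s' varies within participant '%s'",
        b, names(varying)[which(varying > 1)[1]]
      ))
    }
  }

  fixed <- paste(c(between, within), collapse = " * ")
  error_term <- sprintf("Error(%s/(%s))", participant,
                        paste(within, collapse = " * "))
  form <- stats::as.formula(sprintf("%s ~ %s + %s", dv, fixed, error_term))
  fit <- aov(form, data = data)
  out <- extract_aov_effects(fit)

  if (correction == "greenhouse-geisser") {
    out <- apply_gg_correction(out, data, dv, within, participant)
  }
  structure(out, class = c("headconform_anova", class(out)),
            dv = dv, within = within, between = between,
            n_participants = length(unique(data[[participant]])))
}

extract_aov_effects <- function(fit) {
  strata <- summary(fit)
  rows <- list()
  for (stratum in strata) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    res <- which(terms == "Residuals")
    ss_res <- if (length(res) == 1) tab[res, "Sum Sq"] else NA_real_
    df_res <- if (length(res) == 1) tab[res, "Df"] else NA_real_
    for (i in setdiff(seq_along(terms), res)) {
      ss <- tab[i, "Sum Sq"]
      df <- tab[i, "Df"]
      if (!is.na(ss) && ss < 1e-12) {
        f <- 0; p <- 1; eta <- 0
      } else if (is.na(ss_res) || ss_res < 1e-12 || df_res == 0) {
        f <- NA_real_; p <- NA_real_
        eta <- if (!is.na(ss_res)) ss / (ss + ss_res) else NA_real_
      } else {
        f <- (ss / df) / (ss_res / df_res)
        p <- stats::pf(f, df, df_res, lower.tail = FALSE)
        eta <- ss / (ss + ss_res)
      }
      rows[[length(rows) + 1]] <- tibble(
        effect = terms[i], df_num = df, df_den = df_res,
        ss_effect = ss, ss_error = ss_res, F = f, p = p, eta_p = eta
      )
    }
  }
  dplyr::bind_rows(rows)
}

# Greenhouse-Geisser epsilon per within effect, from the covariance of the
# participant-by-cell score matrix of that effect's contrasts.
apply_gg_correction <- function(out, data, dv, within, participant) {
  for (i in seq_len(nrow(out))) {
    parts <- strsplit(out$effect[i], ":", fixed = TRUE)[[1]]
    if (!all(parts %in% within) || out$df_num[i] < 2) next
    cells <- interaction(data[parts], drop = TRUE, sep = ":")
    m <- tapply(data[[dv]], list(data[[participant]], cells), mean)
    k <- ncol(m)
    cc <- stats::cov(m)
    centred <- cc - outer(rowMeans(cc), rep(1, k)) -
      outer(rep(1, k), colMeans(cc)) + mean(cc)
    eps <- sum(diag(centred))^2 / ((k - 1) * sum(centred^2))
    eps <- min(max(eps, 1 / (k - 1)), 1)
    out$df_num[i] <- out$df_num[i] * eps
    out$df_den[i] <- out$df_den[i] * eps
    out$p[i] <- stats::pf(out$F[i], out$df_num[i], out$df_den[i],
                          lower.tail = FALSE)
  }
  out
}

#' @export
tidy.headconform_anova <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @export
glance.headconform_anova <- function(x, ...) {
  tibble(
    dv = attr(x, "dv"),
    n_participants = attr(x, "n_participants"),
    n_effects = nrow(x),
    within = paste(attr(x, "within"), collapse = ", "),
    between = paste(attr(x, "between") %||% character(0), collapse = ", ")
  )
}

#' Pearson association between two per-participant measures
#'
#' Two-tailed Pearson correlation test. Constant input has no defined
#' correlation and yields a `degenerate` row rather than an error, so table
#' builders can keep their shape.
#'
#' @param x,y Paired numeric vectors; pairs with missing values are dropped.
#' @return A one-row tibble: `r`, `p`, `n`, `df`, `degenerate`.
#' @export
pearson_assoc <- function(x, y) {
  keep <- complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort_inference("Pearson association needs at least 3 complete pairs")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p = NA_real_, n = n, df = n - 2L,
                  degenerate = TRUE))
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(r = unname(ct$estimate), p = ct$p.value, n = n,
         df = unname(ct$parameter), degenerate = FALSE)
}

#' Conformity-rating association table
#'
#' The combined-analysis table: for each dependent measure (vection,
#' sickness, presence), head-motion axis, and speed condition, the Pearson
#' correlation across participants between conformity to the normative
#' (leave-one-out median) trajectory and the rating from the matching
#' upright, world-aligned, forward-facing lap. 3 measures x 3 axes x 2
#' speeds = 18 rows.
#'
#' @param scores Output of [conformity_scores()].
#' @param records Trial-record tibble; rows are filtered to the upright /
#'   aligned / forward lap trials before joining.
#' @param alpha Significance threshold recorded in the `significant` column.
#' @return An `association_table` tibble: `dv`, `speed`, `axis`, `r`, `p`,
#'   `n`, `significant`, `insufficient_n`.
#' @export
conformity_association_table <- function(scores, records, alpha = 0.05) {
  baseline <- records
  for (col in c("posture", "alignment", "direction")) {
    if (!col %in% names(baseline)) next
    ref <- c(posture = "upright", alignment = "aligned",
             direction = "forward")[[col]]
    baseline <- baseline[is.na(baseline[[col]]) | baseline[[col]] == ref, ]
  }
  baseline <- baseline[baseline$speed %in% c("slow", "fast"), ]
  dvs <- c(vection = "vection_magnitude", sickness = "sickness",
           presence = "presence")
  grid <- tidyr::expand_grid(
    dv = names(dvs),
    speed = c("slow", "fast"),
    axis = c("pitch", "yaw", "roll")
  )
  out <- purrr::pmap_dfr(grid, function(dv, speed, axis) {
    sc <- scores[scores$axis == axis & scores$speed == speed &
                   !scores$degenerate, ]
    rec <- baseline[baseline$speed == speed, c("participant_id", dvs[[dv]])]
    joined <- dplyr::inner_join(sc, rec, by = "participant_id")
    base <- tibble(dv = dv, speed = speed, axis = axis)
    if (nrow(joined) < 3) {
      return(dplyr::bind_cols(base, tibble(
        r = NA_real_, p = NA_real_, n = nrow(joined),
        significant = NA, insufficient_n = TRUE
      )))
    }
    pa <- pearson_assoc(joined$r, joined[[dvs[[dv]]]])
    dplyr::bind_cols(base, tibble(
      r = pa$r, p = pa$p, n = pa$n,
      significant = !pa$degenerate & pa$p < alpha,
      insufficient_n = FALSE
    ))
  })
  structure(out, class = c("association_table", class(out)), alpha = alpha)
}

#' Pairwise correlations of participant-mean ratings
#'
#' Averages each participant's ratings across the lap conditions and
#' correlates the participant means between measures (the analysis behind
#' statements like "vection magnitude and presence were strongly positively
#' correlated").
#'
#' @param records Trial-record tibble; stationary baselines are excluded.
#' @return A tibble with one row per measure pair: `measure_1`, `measure_2`,
#'   `r`, `p`, `n`, `df`.
#' @export
rating_correlations <- function(records) {
  laps <- records[records$speed != "stationary", ]
  means <- laps |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      vection = mean(.data$vection_magnitude),
      sickness = mean(.data$sickness),
      presence = mean(.data$presence),
      .groups = "drop"
    )
  pairs <- utils::combn(c("vection", "sickness", "presence"), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    pa <- pearson_assoc(means[[pairs[1, i]]], means[[pairs[2, i]]])
    dplyr::bind_cols(
      tibble(measure_1 = pairs[1, i], measure_2 = pairs[2, i]), pa
    )
  })
}
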