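#' Factorial design of the two passive-driving experiments
#'
#' Both studies are within-subjects, partially counterbalanced designs built
#' from blocks of three trials: a leading stationary baseline followed by the
#' two lap trials (slow then fast, or fast then slow -- fixed within a
#' participant, counterbalanced across participants).
#'
#' * Experiment 1 crosses posture (upright/reclined, the two main blocks) with
#'   real/virtual world alignment (aligned/misaligned, the two sub-blocks of
#'   each main block) and playback speed: 12 trials, 4 of them stationary.
#' * Experiment 2 crosses driving direction (forward/reverse/lateral, the
#'   three main blocks in counterbalanced order) with playback speed:
#'   9 trials, 3 of them stationary.
#'
#' @param experiment `1` or `2`.
#' @return A `design_spec` list with the within-subject factors and block
#'   structure.
#' @export
#' @examples
#' nrow(enumerate_orders(design_spec(2)))  # 12 counterbalanced orders
design_spec <- function(experiment) {
  if (!length(experiment) == 1 || !experiment %in% c(1, 2)) {
    abort_config("`experiment` must be 1 or 2")
  }
  if (experiment == 1) {
    structure(list(
      experiment = 1L,
      within_factors = list(
        posture = c("upright", "reclined"),
        alignment = c("aligned", "misaligned"),
        speed = c("slow", "fast")
      )
    ), class = "design_spec")
  } else {
    structure(list(
      experiment = 2L,
      within_factors = list(
        direction = c("forward", "reverse", "lateral"),
        speed = c("slow", "fast")
      )
    ), class = "design_spec")
  }
}

#' @rdname design_spec
#' @param within_factors Named list of factor levels for a user-supplied
#'   design.
#' @param order_components Named list of counterbalanced order components
#'   (each a character vector of levels); their cartesian product is the
#'   order enumeration.
#' @export
custom_design_spec <- function(within_factors, order_components) {
  if (length(order_components) == 0 || is.null(names(order_components))) {
    abort_config("`order_components` must be a named, non-empty list")
  }
  structure(list(experiment = NA_integer_,
                 within_factors = within_factors,
                 order_components = order_components),
            class = "design_spec")
}

permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) {
      out[[length(out) + 1]] <- c(x[i], rest)
    }
  }
  out
}

#' Enumerate the counterbalanced order conditions of a design
#'
#' Experiment 1 has four independent binary order choices -- which posture
#' block comes first, which alignment sub-block comes first within each of the
#' two main blocks, and the participant's fixed speed order -- giving
#' 2 x 2 x 2 x 2 = 16 order levels. Experiment 2 has the 3! direction-block
#' permutations crossed with the speed order, giving 12. The enumeration is
#' deterministic and duplicate-free, ordered by the components' level order.
#'
#' @param design A [design_spec()].
#' @return A tibble with one row per order; `order_index` plus one column per
#'   order component.
#' @export
enumerate_orders <- function(design) {
  if (!inherits(design, "design_spec")) {
    abort_config("`design` must be a design_spec object")
  }
  speed_orders <- c("slow_first", "fast_first")
  if (!is.null(design$order_components)) {
    grid <- tidyr::expand_grid(!!!design$order_components)
    return(tibble::add_column(grid, order_index = seq_len(nrow(grid)),
                              .before = 1))
  }
  if (design$experiment == 1) {
    grid <- tidyr::expand_grid(
      posture_block_order = c("upright_first", "reclined_first"),
      subblock_order_block1 = c("aligned_first", "misaligned_first"),
      subblock_order_block2 = c("aligned_first", "misaligned_first"),
      speed_order = speed_orders
    )
  } else {
    perms <- permutations(design$within_factors$direction)
    grid <- tidyr::expand_grid(
      direction_order = purrr::map_chr(perms, paste, collapse = ","),
      speed_order = speed_orders
    )
  }
  tibble::add_column(grid, order_index = seq_len(nrow(grid)), .before = 1)
}

block_trials <- function(speed_order) {
  speeds <- if (speed_order == "slow_first") c("slow", "fast") else
    c("fast", "slow")
  c("stationary", speeds)
}

#' Build one participant's trial schedule from an order assignment
#'
#' Expands an order row from [enumerate_orders()] into the ordered trial list
#' the participant experiences: each (sub-)block starts with its stationary
#' baseline and continues with the two lap trials in the participant's fixed
#' speed order. The multiset of non-stationary trials is always the full
#' within-subject factorial.
#'
#' @param design A [design_spec()].
#' @param order A one-row tibble (or list) from [enumerate_orders()] for the
#'   same design.
#' @return A tibble with `trial_index`, block labels, the condition factors
#'   (`posture`/`alignment` or `direction`), `speed`, and `stationary`.
#' @export
build_session_schedule <- function(design, order) {
  if (!inherits(design, "design_spec")) {
    abort_config("`design` must be a design_spec object")
  }
  order <- as.list(order)
  needed <- if (design$experiment == 1) {
    c("posture_block_order", "subblock_order_block1",
      "subblock_order_block2", "speed_order")
  } else {
    c("direction_order", "speed_order")
  }
  missing <- setdiff(needed, names(order))
  if (length(missing) > 0) {
    abort_config(sprintf(
      "Order assignment does not match the experiment %d design (missing %s)",
      design$experiment, paste0("'", missing, "'", collapse = ", ")
    ))
  }

  if (design$experiment == 1) {
    postures <- if (order$posture_block_order == "upright_first") {
      c("upright", "reclined")
    } else {
      c("reclined", "upright")
    }
    sub_orders <- list(order$subblock_order_block1,
                       order$subblock_order_block2)
    rows <- purrr::map2(seq_along(postures), postures, function(b, posture) {
      alignments <- if (sub_orders[[b]] == "aligned_first") {
        c("aligned", "misaligned")
      } else {
        c("misaligned", "aligned")
      }
      purrr::map2_dfr(seq_along(alignments), alignments,
                      function(s, alignment) {
        tibble(
          main_block = b, sub_block = s,
          posture = posture, alignment = alignment,
          direction = "forward",
          speed = block_trials(order$speed_order)
        )
      })
    })
  } else {
    directions <- strsplit(order$direction_order, ",", fixed = TRUE)[[1]]
    rows <- purrr::map2(seq_along(directions), directions,
                        function(b, direction) {
      tibble(
        main_block = b, sub_block = 1L,
        posture = "upright", alignment = "aligned",
        direction = direction,
        speed = block_trials(order$speed_order)
      )
    })
  }
  schedule <- dplyr::bind_rows(rows)
  schedule$stationary <- schedule$speed == "stationary"
  tibble::add_column(schedule, trial_index = seq_len(nrow(schedule)),
                     .before = 1)
}

#' Assign a cohort to order conditions and build every schedule
#'
#' Orders are assigned round-robin by participant index, which balances the
#' cohort exactly when its size is a multiple of the order count and as
#' evenly as possible (with a warning) otherwise.
#'
#' @param design A [design_spec()].
#' @param n_participants Cohort size.
#' @param participant_ids Optional character labels (default `P001`, ...).
#' @return A tibble of stacked schedules with `participant_id` and
#'   `order_index` columns; ratings columns are absent (a schedule skeleton).
#' @export
build_cohort_schedule <- function(design, n_participants,
                                  participant_ids = NULL) {
  orders <- enumerate_orders(design)
  if (is.null(participant_ids)) {
    participant_ids <- sprintf("P%03d", seq_len(n_participants))
  }
  if (n_participants %% nrow(orders) != 0) {
    warn(sprintf(
      "Cohort size %d is not a multiple of the %d order levels; assigning round-robin as evenly as possible",
      n_participants, nrow(orders)
    ), class = "headconform_balance_warning")
  }
  idx <- ((seq_len(n_participants) - 1L) %% nrow(orders)) + 1L
  # schedules depend only on the order row; build each once
  cache <- lapply(seq_len(nrow(orders)), function(j) {
    build_session_schedule(design, orders[j, ])
  })
  purrr::map_dfr(seq_len(n_participants), function(i) {
    tibble::add_column(cache[[idx[i]]],
                       participant_id = participant_ids[i],
                       order_index = orders$order_index[idx[i]],
                       .before = 1)
  })
}
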