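# Independent brute-force oracles. Deliberately naive: loops, hand formulas,
# and per-point recomputation, sharing no code with the implementation.

oracle_unwrap_center <- function(x) {
  out <- numeric(length(x))
  for (i in seq_along(x)[-1]) {
    d <- x[i] - x[i - 1]
    while (d > 180) d <- d - 360
    while (d <= -180) d <- d + 360
    out[i] <- out[i - 1] + d
  }
  out
}

oracle_interp <- function(t, x, grid) {
  vapply(grid, function(g) {
    if (g <= t[1]) return(x[1])
    if (g >= t[length(t)]) return(x[length(x)])
    j <- max(which(t <= g))
    if (t[j] == g) return(x[j])
    w <- (g - t[j]) / (t[j + 1] - t[j])
    (1 - w) * x[j] + w * x[j + 1]
  }, numeric(1))
}

oracle_mav <- function(x, rate) {
  total <- 0
  for (i in seq_along(x)[-1]) total <- total + abs(x[i] - x[i - 1])
  total / (length(x) - 1) * rate
}

oracle_median <- function(v) {
  s <- sort(v)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_loo_median <- function(mat, target_col) {
  apply(mat[, -target_col, drop = FALSE], 1, oracle_median)
}

oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Exhaustive lag search: lag k means head(t) ~ vehicle(t - k); ties go to the
# smallest |k|.
oracle_lag <- function(x, y, max_samples) {
  best_k <- NA; best_r <- -Inf
  for (k in -max_samples:max_samples) {
    n <- length(x)
    if (k >= 0) {
      xs <- x[(1 + k):n]; ys <- y[1:(n - k)]
    } else {
      xs <- x[1:(n + k)]; ys <- y[(1 - k):n]
    }
    if (sd(xs) == 0 || sd(ys) == 0) next
    r <- oracle_pearson(xs, ys)
    if (r > best_r + 1e-12 ||
          (abs(r - best_r) <= 1e-12 && abs(k) < abs(best_k))) {
      best_r <- r; best_k <- k
    }
  }
  list(lag = best_k, r = best_r)
}

oracle_mean_sem <- function(mat) {
  n <- ncol(mat)
  mu <- numeric(nrow(mat)); sem <- numeric(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    mu[i] <- sum(mat[i, ]) / n
    sem[i] <- sqrt(sum((mat[i, ] - mu[i])^2) / (n - 1)) / sqrt(n)
  }
  list(mean = mu, sem = sem)
}

# Balanced fully-crossed within-subject ANOVA by inclusion-exclusion on cell
# means: effect(U) at a cell is the alternating sum of margin means over
# subsets of U; SS(U) sums the squared effect over all observations. Each
# within effect E is tested against its E-by-subject interaction.
oracle_rm_anova <- function(data, dv, within, subject) {
  factors <- c(within, subject)
  margin_mean <- function(cols) {
    if (length(cols) == 0) {
      return(rep(mean(data[[dv]]), nrow(data)))
    }
    key <- interaction(data[cols], drop = FALSE)
    ave(data[[dv]], key)
  }
  subsets <- function(set) {
    out <- list(character(0))
    for (el in set) out <- c(out, lapply(out, function(s) c(s, el)))
    out
  }
  effect_values <- function(U) {
    vals <- rep(0, nrow(data))
    for (V in subsets(U)) {
      vals <- vals + (-1)^(length(U) - length(V)) * margin_mean(V)
    }
    vals
  }
  ss_of <- function(U) sum(effect_values(U)^2)
  df_of <- function(U) {
    prod(vapply(U, function(f) length(unique(data[[f]])) - 1, numeric(1)))
  }
  effects <- Filter(function(U) length(U) > 0, subsets(within))
  rows <- lapply(effects, function(E) {
    ss_e <- ss_of(E); df_e <- df_of(E)
    err <- c(E, subject)
    ss_r <- ss_of(err); df_r <- df_of(err)
    f <- (ss_e / df_e) / (ss_r / df_r)
    data.frame(
      effect = paste(E, collapse = ":"),
      df_num = df_e, df_den = df_r, ss_effect = ss_e, ss_error = ss_r,
      F = f, p = pf(f, df_e, df_r, lower.tail = FALSE),
      eta_p = ss_e / (ss_e + ss_r),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
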