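# Independent oracles, kept deliberately naive: explicit loops and direct
# textbook formulas, no shared code with the implementation.

# two-way crossed ANOVA sums of squares by explicit triple loops
oracle_mean_squares <- function(table, variable) {
  evs <- sort(unique(table$evaluator_id))
  hrs <- sort(unique(table$horse_id))
  I <- length(evs); J <- length(hrs)
  n <- nrow(table)
  K <- n / (I * J)
  y <- table[[variable]]
  grand <- mean(y)
  ss_h <- 0
  for (j in hrs) {
    mj <- mean(y[table$horse_id == j])
    ss_h <- ss_h + I * K * (mj - grand)^2
  }
  ss_e <- 0
  for (i in evs) {
    mi <- mean(y[table$evaluator_id == i])
    ss_e <- ss_e + J * K * (mi - grand)^2
  }
  ss_t <- 0
  for (r in seq_len(n)) ss_t <- ss_t + (y[r] - grand)^2
  ss_err <- ss_t - ss_h - ss_e
  list(
    ms_horse = ss_h / (J - 1),
    ms_evaluator = ss_e / (I - 1),
    ms_error = ss_err / (n - 1 - (I - 1) - (J - 1))
  )
}

# brute-force double-loop summed squared difference representative stride
oracle_representative <- function(cycles, window) {
  best <- NA; best_val <- Inf
  for (i in window) {
    tot <- 0
    for (j in window) {
      tot <- tot + sum((cycles[i, ] - cycles[j, ])^2)
    }
    if (tot < best_val - 1e-12) {
      best_val <- tot
      best <- i
    }
  }
  best
}

# sort-based linear-interpolation quantile (independent of stats::quantile)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

random_balanced_table <- function(I = 6, J = 10, K = 3, seed = 1) {
  withr::with_seed(seed, {
    grid <- expand.grid(
      evaluator_id = sprintf("E%d", seq_len(I)),
      horse_id = sprintf("H%02d", seq_len(J)),
      repetition = seq_len(K),
      stringsAsFactors = FALSE
    )
    grid$y <- rnorm(nrow(grid))
    tibble::as_tibble(grid)
  })
}

fake_stride_series <- function(durations, sample_rate = 102.4) {
  b <- cumsum(c(1, round(durations * sample_rate)))
  structure(
    list(
      boundaries = as.integer(b),
      boundary_offsets = rep(0, length(b)),
      durations = diff(b) / sample_rate,
      sample_rate = sample_rate
    ),
    class = "stride_series"
  )
}
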