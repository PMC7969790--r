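# Internal helpers: condition signalling, seeded sub-streams, circular helpers.

abort_eg <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "equigait_error"), ...)
}

# Counter-based expansion of one user seed into independent sub-stream seeds.
# Pure integer arithmetic in double precision; result always in [1, 2^31 - 2]
# so it is a valid `set.seed()` input on 32-bit integer platforms.
substream_seed <- function(seed, counter = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  s <- (abs(seed) %% 2147483647) + 1
  s <- (s * 48271 + (counter %% 65521) * 97003 + 12345) %% 2147483629
  as.integer(s %% 2147483646 + 1)
}

# Evaluate `expr` under a seeded RNG sub-stream, restoring the caller's RNG
# state afterwards. `seed = NULL` means: use (and advance) the global stream.
with_substream <- function(seed, counter, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(substream_seed(seed, counter))
  force(expr)
}

wrap_pct <- function(x) x %% 100

# circular distance between two positions on the [0, 100) stride cycle
circ_dist_pct <- function(a, b) {
  d <- abs(a - b) %% 100
  pmin(d, 100 - d)
}

cv <- function(x) {
  if (length(x) < 2L) return(0)
  m <- mean(x)
  if (m == 0) return(Inf)
  stats::sd(x) / abs(m)
}

# centered moving average with edge replication; width forced odd
roll_mean <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2L))[
    (half + 1L):(half + length(x))
  ]
}

# Quadratic (three-point) refinement of an extremum location on a circular
# grid. Returns a fractional index offset in (-0.5, 0.5] around `idx`.
parabolic_offset <- function(y, idx) {
  n <- length(y)
  ym <- y[(idx - 2L) %% n + 1L]
  y0 <- y[idx]
  yp <- y[idx %% n + 1L]
  den <- ym - 2 * y0 + yp
  if (abs(den) < .Machine$double.eps * 100) return(0)
  off <- 0.5 * (ym - yp) / den
  max(min(off, 0.5), -0.5)
}

`%||%` <- rlang::`%||%`
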