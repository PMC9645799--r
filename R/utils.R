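# Internal helpers shared across modules: classed error conditions,
# rolling-window operations on uniformly sampled series, and a
# counter-based sub-seed stream for reproducible simulation.

# Raise a classed condition so callers can catch specific failure modes
# (e.g. class "palpmetrics_missing_channel") rather than matching messages.
stop_palp <- function(class, msg, ...) {
  stop(structure(
    class = c(paste0("palpmetrics_", class), "palpmetrics_error",
              "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# Centered moving average with window of `k` samples (k forced odd).
# Ends are averaged over the available samples so no frames are lost.
moving_average <- function(x, k) {
  k <- as.integer(k)
  if (k <= 1L) return(x)
  if (k %% 2L == 0L) k <- k + 1L
  n <- length(x)
  if (n == 0L) return(x)
  half <- (k - 1L) %/% 2L
  # cumulative-sum trick; NA-safe by treating NA as 0 and counting valid
  valid <- !is.na(x)
  xv <- ifelse(valid, x, 0)
  cs <- c(0, cumsum(xv))
  cn <- c(0, cumsum(as.numeric(valid)))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  s <- cs[hi + 1L] - cs[lo]
  m <- cn[hi + 1L] - cn[lo]
  out <- ifelse(m > 0, s / m, NA_real_)
  out[!valid] <- NA_real_
  out
}

# Trailing-window rolling max over the last `k` samples (inclusive),
# via the doubling decomposition max[i-k+1..i] = max(M_p[i], M_p[i-(k-p)])
# — O(n log k). NAs are ignored (window max of the available samples).
rolling_max_trailing <- function(x, k) {
  n <- length(x)
  if (n == 0L) return(x)
  x[is.na(x)] <- -Inf
  m <- x
  p <- 1L
  while (p < k) {
    s <- min(p, k - p)
    shifted <- c(rep(-Inf, s), m[seq_len(n - s)])
    m <- pmax(m, shifted)
    p <- p + s
  }
  m[is.infinite(m)] <- NA_real_
  m
}

rolling_min_trailing <- function(x, k) -rolling_max_trailing(-x, k)

# Trailing-window rolling range (max - min) over the last `k` samples.
rolling_range_trailing <- function(x, k) {
  rolling_max_trailing(x, k) - rolling_min_trailing(x, k)
}

# Deterministic 31-bit sub-seed stream: independent trials can be
# regenerated individually from (global seed, counter). Constants kept
# small enough that all products stay exact in double precision.
derive_seed <- function(seed, counter) {
  s <- (as.numeric(seed) %% 94906265)
  k <- as.numeric(counter)
  as.integer((s * 1103 + k * 7919 + 104729) %% 2147483629)
}

# Evaluate `expr` with a local RNG state so library code never clobbers
# the caller's random stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
}

read_json_file <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
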