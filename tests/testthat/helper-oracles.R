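# Independent brute-force oracles, written as plain loops so they share
# no code path with the implementation they check.

# Single-pass recomputation of the per-trial metrics from the same
# inputs (window, touchpoints, projection series) the package uses.
bf_trial_metrics <- function(bundle, window, touchpoints, proj,
                             cfg = peak_config()) {
  tt <- bundle$channels$force_index$t
  span <- window$T_end - window$T_start
  fr_max <- -Inf; fr_min <- Inf
  for (i in seq_along(tt)) {
    if (tt[i] >= window$T_start && tt[i] <= window$T_end) {
      v <- bundle$channels$force_index$v[i] + bundle$channels$force_middle$v[i]
      if (!is.na(v)) {
        if (v > fr_max) fr_max <- v
        if (v < fr_min) fr_min <- v
      }
    }
  }
  dwell <- 0; tf <- 0
  for (k in seq_len(nrow(touchpoints))) {
    dwell <- dwell + touchpoints$TPT[k]
    tf <- tf + touchpoints$TPT[k] * touchpoints$TPF[k]
  }
  # smoothed path length, recomputed sample by sample
  inw <- which(tt >= window$T_start & tt <= window$T_end)
  xs <- palpmetrics:::moving_average(bundle$channels$finger_x$v[inw], 5L)
  ys <- palpmetrics:::moving_average(bundle$channels$finger_y$v[inw], 5L)
  pl <- 0
  for (i in seq_len(length(inw) - 1L)) {
    if (!is.na(xs[i]) && !is.na(xs[i + 1]) &&
        !is.na(ys[i]) && !is.na(ys[i + 1]))
      pl <- pl + sqrt((xs[i + 1] - xs[i])^2 + (ys[i + 1] - ys[i])^2)
  }
  n_tow <- 0L; n_sig <- 0L
  for (v in proj$V_p) {
    if (!is.na(v)) {
      if (v > cfg$rcm_speed_threshold) { n_tow <- n_tow + 1L; n_sig <- n_sig + 1L }
      else if (-v > cfg$rcm_speed_threshold) n_sig <- n_sig + 1L
    }
  }
  n_near <- 0L; n_loc <- 0L; tpd_sum <- 0
  for (d in touchpoints$TPD) {
    if (!is.na(d)) {
      n_loc <- n_loc + 1L
      tpd_sum <- tpd_sum + d
      if (d < cfg$rntp_radius) n_near <- n_near + 1L
    }
  }
  list(
    frequency = nrow(touchpoints) / span,
    total_force = tf,
    force_range = fr_max - fr_min,
    dwell_time = dwell,
    idle_time = span - dwell,
    path_length = pl,
    rcm = if (n_sig > 0L) 100 * n_tow / n_sig else NA_real_,
    rntp = if (n_loc > 0L) 100 * n_near / n_loc else NA_real_,
    mean_tpd = if (n_loc > 0L) tpd_sum / n_loc else NA_real_)
}

# Exact two-sided Mann-Whitney p by exhaustive enumeration of all
# C(n1 + n2, n1) rank arrangements (tie-free samples only).
enum_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, function(idx) sum(seq_len(n1 + n2)[idx]) -
                n1 * (n1 + 1) / 2)
  p_lo <- mean(us <= u_obs); p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Dense-grid maximum of the Bernoulli log-likelihood over an
# (intercept, slope) box, vectorized over grid points.
grid_loglik_max <- function(x, y, box_b0, box_b1, n_grid = 200) {
  b0 <- seq(box_b0[1], box_b0[2], length.out = n_grid)
  b1 <- seq(box_b1[1], box_b1[2], length.out = n_grid)
  gr <- as.matrix(expand.grid(b0 = b0, b1 = b1))
  eta <- cbind(1, x) %*% t(gr)            # n x n_grid^2
  ll <- colSums(y * eta - log1p(exp(eta)))
  max(ll)
}

bernoulli_loglik <- function(x, y, b0, b1) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Closed-form Wilson score interval, written out directly.
wilson_direct <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  lo <- (p + z^2 / (2 * n) - z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  hi <- (p + z^2 / (2 * n) + z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))) /
    (1 + z^2 / n)
  c(lo, hi)
}
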