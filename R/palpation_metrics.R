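# Touchpoint detection and the twelve per-trial palpation metrics.
#
# A touchpoint is one episode of applied fingertip pressure, identified as
# a peak in the combined index+middle force signal inside the palpation
# window. Per touchpoint we record the dwell time TPT (full width of the
# force peak at half prominence), the peak force TPF, the planar fingertip
# location, and the distance TPD to the active fistula's motor. Per trial
# the metrics are: Touchpoints, Frequency, Total Force, Force Range, RCM
# (ratio of correct movement), RNTP (ratio of near touchpoints), Path
# Length, Dwell Time and Idle Time, plus per-touchpoint means of TPT, TPF
# and TPD.

#' Peak-detection and location-metric configuration
#'
#' @param min_prominence Minimum peak prominence (N) for a force peak to
#'   count as a touchpoint (default 0.05, about 4 standard deviations of
#'   smoothed sensor noise).
#' @param min_separation Minimum time separation between touchpoints (s);
#'   on conflict the higher peak is kept, the earlier on an exact tie
#'   (default 0.10).
#' @param width_reference Reference level for the dwell-time width; only
#'   `"half_prominence"` is supported.
#' @param rcm_speed_threshold Speed (mm/s) above which a velocity
#'   projection counts as a significant movement (fixed at 20 by the RCM
#'   definition).
#' @param rntp_radius Radius (mm) within which a touchpoint counts as near
#'   the anastomosis (fixed at 40 by the RNTP definition).
#' @param smoothing_window Width (s) of the triangular-weighted moving
#'   average applied to the combined force before peak detection
#'   (default 0.05).
#' @return Object of class `peak_config`.
#' @export
peak_config <- function(min_prominence = 0.05,
                        min_separation = 0.10,
                        width_reference = "half_prominence",
                        rcm_speed_threshold = 20,
                        rntp_radius = 40,
                        smoothing_window = 0.05) {
  if (!identical(width_reference, "half_prominence"))
    stop_palp("schema", "only width_reference = 'half_prominence' is supported")
  for (v in c(min_prominence, min_separation, rcm_speed_threshold,
              rntp_radius, smoothing_window))
    if (!is_scalar_number(v) || v <= 0)
      stop_palp("schema", "peak config values must be positive numbers")
  structure(list(min_prominence = min_prominence,
                 min_separation = min_separation,
                 width_reference = width_reference,
                 rcm_speed_threshold = rcm_speed_threshold,
                 rntp_radius = rntp_radius,
                 smoothing_window = smoothing_window),
            class = "peak_config")
}

# Triangular-weighted centered moving average (weights 1..m..1). Chosen
# over a flat box because it attenuates sharp apexes less, keeping
# half-prominence widths within one sample of their closed form.
smooth_triangular <- function(x, k) {
  k <- as.integer(k)
  if (k %% 2L == 0L) k <- k + 1L
  if (k <= 1L || length(x) < 2L) return(x)
  half <- (k - 1L) %/% 2L
  w <- c(seq_len(half + 1L), rev(seq_len(half)))
  n <- length(x)
  if (!anyNA(x)) {
    # interior via linear filter, ends renormalised over available weights
    out <- as.numeric(stats::filter(x, w / sum(w), sides = 2))
    for (i in c(seq_len(min(half, n)), seq.int(max(n - half + 1L, 1L), n))) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      wi <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(wi * x[lo:hi]) / sum(wi)
    }
    return(out)
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    wi <- w[(lo - i + half + 1L):(hi - i + half + 1L)]
    xi <- x[lo:hi]
    keep <- !is.na(xi)
    out[i] <- if (any(keep)) sum(wi[keep] * xi[keep]) / sum(wi[keep]) else NA_real_
  }
  out[is.na(x)] <- NA_real_
  out
}

# Prominence of a local maximum: height above the higher of the two
# minima separating it from the nearest higher ground (or signal edge).
# Also returns the positions of those two base minima.
peak_prominence <- function(v, i) {
  n <- length(v)
  left_min <- v[i]; lb <- i
  j <- i - 1L
  while (j >= 1L && v[j] <= v[i]) {
    if (v[j] < left_min) { left_min <- v[j]; lb <- j }
    j <- j - 1L
  }
  right_min <- v[i]; rb <- i
  j <- i + 1L
  while (j <= n && v[j] <= v[i]) {
    if (v[j] < right_min) { right_min <- v[j]; rb <- j }
    j <- j + 1L
  }
  c(v[i] - max(left_min, right_min), lb, rb)
}

# Local maxima (first sample of any plateau), prominence filter,
# minimum-separation enforcement, and full width at half prominence with
# sub-sample linear interpolation of the crossings.
find_force_peaks <- function(t, v, min_prominence, min_separation) {
  n <- length(v)
  if (n < 3L) return(data.frame(idx = integer(), t = numeric(),
                                height = numeric(), prominence = numeric(),
                                width = numeric()))
  # rising before, non-rising after; plateau: first index of run
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(data.frame(idx = integer(), t = numeric(),
                                       height = numeric(),
                                       prominence = numeric(),
                                       width = numeric()))
  pr <- vapply(cand, function(i) peak_prominence(v, i), numeric(3))
  prom <- pr[1, ]; base_lo <- as.integer(pr[2, ]); base_hi <- as.integer(pr[3, ])
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  base_lo <- base_lo[keep]; base_hi <- base_hi[keep]
  if (!length(cand)) return(data.frame(idx = integer(), t = numeric(),
                                       height = numeric(),
                                       prominence = numeric(),
                                       width = numeric()))
  # enforce separation: highest first, earlier wins exact ties
  ord <- order(-v[cand], cand)
  kept <- integer(0)
  for (k in ord) {
    if (!length(kept) ||
        all(abs(t[cand[k]] - t[cand[kept]]) >= min_separation))
      kept <- c(kept, k)
  }
  kept <- sort(kept)
  cand <- cand[kept]; prom <- prom[kept]
  base_lo <- base_lo[kept]; base_hi <- base_hi[kept]
  # dwell = time spent at or above the half-prominence level around the
  # peak. The interval is bounded on each side by the first sample below
  # level - prominence/4 (a margin far beyond noise, so near-level dips
  # or bumps never truncate it, while neighbouring lower pulses stay
  # outside), and the width counts the above-level samples within it,
  # which is symmetric under near-level noise.
  h <- if (n > 1L) (t[n] - t[1L]) / (n - 1L) else 0
  width <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    level <- v[i] - prom[k] / 2
    stop_level <- level - prom[k] / 4
    lo <- base_lo[k]; hi <- base_hi[k]
    j <- i - 1L; cl <- lo
    while (j >= lo) {
      if (!is.na(v[j]) && v[j] < stop_level) { cl <- j; break }
      j <- j - 1L
    }
    j <- i + 1L; cr <- hi
    while (j <= hi) {
      if (!is.na(v[j]) && v[j] < stop_level) { cr <- j; break }
      j <- j + 1L
    }
    seg <- cl:cr
    above <- seg[!is.na(v[seg]) & v[seg] >= level]
    if (!length(above)) return(h)
    il <- above[1L]; ir <- above[length(above)]
    # sub-sample extension beyond the outermost above-level samples
    fl <- if (il > 1L && !is.na(v[il - 1L]) && v[il - 1L] < level)
      (v[il] - level) / (v[il] - v[il - 1L]) else 0.5
    fr <- if (ir < n && !is.na(v[ir + 1L]) && v[ir + 1L] < level)
      (v[ir] - level) / (v[ir] - v[ir + 1L]) else 0.5
    h * (length(above) - 1 + min(fl, 1) + min(fr, 1))
  }, 0)
  data.frame(idx = cand, t = t[cand], height = v[cand],
             prominence = prom, width = width)
}

#' Detect touchpoints within the palpation window
#'
#' Local maxima of the smoothed combined index+middle force inside the
#' window, with prominence at least `min_prominence` and pairwise
#' separation at least `min_separation`. Dwell time `TPT` is the full
#' width at half prominence; `TPF` is the combined force at the peak
#' sample; the planar fingertip location at the peak sample gives `TPD`,
#' the distance to the active fistula's motor. Touchpoints whose position
#' frame is missing keep their force fields and get `NA` location fields.
#'
#' @param bundle A resampled [trial_bundle()].
#' @param window A `palpation_window` with status `"ok"`.
#' @param layout A [simulator_layout()].
#' @param cfg A [peak_config()].
#' @return Data frame with one row per touchpoint: `t_tp`, `TPT`, `TPF`,
#'   `x_tp`, `y_tp`, `TPD`.
#' @export
detect_touchpoints <- function(bundle, window, layout,
                               cfg = peak_config()) {
  if (is.null(bundle$rate))
    stop_palp("not_resampled", "bundle must be resampled to a uniform grid")
  if (!is.null(window$status) && window$status != "ok")
    stop_palp("empty_window", "window status is '%s'", window$status)
  if (!(window$T_end > window$T_start))
    stop_palp("empty_window", "T_end must exceed T_start")
  tt <- ch(bundle, "force_index")$t
  inw <- which(tt >= window$T_start & tt <= window$T_end)
  if (length(inw) < 3L)
    stop_palp("empty_window", "palpation window contains < 3 samples")
  f <- ch(bundle, "force_index")$v[inw] + ch(bundle, "force_middle")$v[inw]
  h <- 1 / bundle$rate
  k <- max(1L, round(cfg$smoothing_window / h))
  fs <- smooth_triangular(f, k)
  pk <- find_force_peaks(tt[inw], fs, cfg$min_prominence, cfg$min_separation)
  fx <- ch(bundle, "finger_x")$v[inw]
  fy <- ch(bundle, "finger_y")$v[inw]
  m <- motor_location(layout, bundle$fistula_id)
  x_tp <- fx[pk$idx]; y_tp <- fy[pk$idx]
  tpd <- sqrt((x_tp - m[1])^2 + (y_tp - m[2])^2)
  data.frame(t_tp = pk$t, TPT = pk$width, TPF = pk$height,
             x_tp = x_tp, y_tp = y_tp, TPD = tpd)
}

#' Projected velocity toward the active motor
#'
#' Planar fingertip velocity by central difference on the position
#' smoothed with a 5-sample moving average, projected onto the unit
#' vector from the current fingertip position toward the motor. Positive
#' values mean the finger is moving toward the anastomosis.
#'
#' @param bundle A resampled [trial_bundle()].
#' @param window A `palpation_window` with status `"ok"`.
#' @param motor Numeric `c(x, y)` motor location in mm.
#' @return Data frame with `t` and `V_p` (mm/s); frames with missing
#'   position give `NA`.
#' @export
compute_velocity_projection <- function(bundle, window, motor) {
  if (is.null(bundle$rate))
    stop_palp("not_resampled", "bundle must be resampled to a uniform grid")
  tt <- ch(bundle, "finger_x")$t
  inw <- which(tt >= window$T_start & tt <= window$T_end)
  if (sum(!is.na(ch(bundle, "finger_x")$v[inw])) < 3L)
    stop_palp("too_few_frames", "need at least 3 valid position frames")
  h <- 1 / bundle$rate
  x <- moving_average(ch(bundle, "finger_x")$v[inw], 5L)
  y <- moving_average(ch(bundle, "finger_y")$v[inw], 5L)
  n <- length(inw)
  vx <- rep(NA_real_, n); vy <- rep(NA_real_, n)
  if (n >= 3L) {
    idx <- 2:(n - 1L)
    vx[idx] <- (x[idx + 1L] - x[idx - 1L]) / (2 * h)
    vy[idx] <- (y[idx + 1L] - y[idx - 1L]) / (2 * h)
  }
  dx <- motor[1] - x; dy <- motor[2] - y
  nrm <- sqrt(dx * dx + dy * dy)
  ux <- ifelse(nrm > 0, dx / nrm, NA_real_)
  uy <- ifelse(nrm > 0, dy / nrm, NA_real_)
  data.frame(t = tt[inw], V_p = vx * ux + vy * uy)
}

#' Ratio of correct movement (RCM)
#'
#' Percentage of significant movements (|V_p| above the speed threshold)
#' that are directed toward the motor. Undefined (`NA`) when there are no
#' significant movements.
#'
#' @param proj Data frame from [compute_velocity_projection()].
#' @param cfg A [peak_config()] (supplies the 20 mm/s threshold).
#' @return Percentage in `[0, 100]`, or `NA` when undefined.
#' @export
compute_rcm <- function(proj, cfg = peak_config()) {
  vp <- proj$V_p[!is.na(proj$V_p)]
  thr <- cfg$rcm_speed_threshold
  denom <- sum(abs(vp) > thr)
  if (denom == 0L) return(NA_real_)
  100 * sum(vp > thr) / denom
}

#' Ratio of near touchpoints (RNTP)
#'
#' Percentage of touchpoints strictly within `rntp_radius` (40 mm) of the
#' motor. Undefined (`NA`) when no touchpoint has a valid location.
#'
#' @param touchpoints Data frame from [detect_touchpoints()].
#' @param cfg A [peak_config()].
#' @return Percentage in `[0, 100]`, or `NA` when undefined.
#' @export
compute_rntp <- function(touchpoints, cfg = peak_config()) {
  tpd <- touchpoints$TPD[!is.na(touchpoints$TPD)]
  if (!length(tpd)) return(NA_real_)
  100 * sum(tpd < cfg$rntp_radius) / length(tpd)
}

#' Compute the twelve per-trial palpation metrics
#'
#' @param bundle A resampled [trial_bundle()].
#' @param window A `palpation_window` with status `"ok"`.
#' @param touchpoints Data frame from [detect_touchpoints()].
#' @param proj Data frame from [compute_velocity_projection()].
#' @param cfg A [peak_config()].
#' @return One-row data frame with columns `touchpoints`, `frequency`
#'   (Hz), `total_force` (sum of TPT x TPF over touchpoints; units N s,
#'   reported under the conventional label "Total Force (N)"),
#'   `force_range` (N), `dwell_time` (s), `idle_time` (s), `path_length`
#'   (mm), `rcm` (%), `rntp` (%), `mean_tpt` (s), `mean_tpf` (N),
#'   `mean_tpd` (mm) and `location_valid`.
#' @export
compute_trial_metrics <- function(bundle, window, touchpoints, proj,
                                  cfg = peak_config()) {
  if (!(window$T_end > window$T_start))
    stop_palp("empty_window", "T_end must exceed T_start")
  span <- window$T_end - window$T_start
  tt <- ch(bundle, "force_index")$t
  inw <- which(tt >= window$T_start & tt <= window$T_end)
  f <- ch(bundle, "force_index")$v[inw] + ch(bundle, "force_middle")$v[inw]
  fv <- f[!is.na(f)]
  force_range <- if (length(fv)) max(fv) - min(fv) else NA_real_

  n_tp <- nrow(touchpoints)
  dwell <- sum(touchpoints$TPT)
  idle <- span - dwell
  total_force <- sum(touchpoints$TPT * touchpoints$TPF)

  # planar path length over valid consecutive frames of the smoothed
  # fingertip trajectory (smoothing keeps the sum a movement measure
  # rather than an accumulation of sensor jitter)
  x <- moving_average(ch(bundle, "finger_x")$v[inw], 5L)
  y <- moving_average(ch(bundle, "finger_y")$v[inw], 5L)
  okf <- !is.na(x) & !is.na(y)
  seg_ok <- okf[-length(okf)] & okf[-1L]
  dx <- diff(x); dy <- diff(y)
  path_length <- sum(sqrt(dx[seg_ok]^2 + dy[seg_ok]^2))

  raw_ok <- !is.na(ch(bundle, "finger_x")$v[inw]) &
    !is.na(ch(bundle, "finger_y")$v[inw])
  location_valid <- all(raw_ok)

  data.frame(
    touchpoints = n_tp,
    frequency = n_tp / span,
    total_force = total_force,
    force_range = force_range,
    dwell_time = dwell,
    idle_time = idle,
    path_length = path_length,
    rcm = compute_rcm(proj, cfg),
    rntp = compute_rntp(touchpoints, cfg),
    mean_tpt = if (n_tp) mean(touchpoints$TPT) else NA_real_,
    mean_tpf = if (n_tp) mean(touchpoints$TPF) else NA_real_,
    mean_tpd = if (any(!is.na(touchpoints$TPD))) {
      mean(touchpoints$TPD, na.rm = TRUE)
    } else NA_real_,
    location_valid = location_valid
  )
}

#' Run segmentation and metrics for one trial
#'
#' Convenience wrapper: resample (if needed), detect the palpation window,
#' detect touchpoints and compute all per-trial metrics.
#'
#' @param bundle A [trial_bundle()].
#' @param layout A [simulator_layout()].
#' @param seg_cfg,peak_cfg Configurations.
#' @param rate Resampling rate (Hz).
#' @return List with `window`, `touchpoints`, `proj`, and `metrics` (the
#'   one-row data frame, or `NULL` when the window status is not ok).
#' @export
analyze_trial <- function(bundle, layout,
                          seg_cfg = segmentation_config(),
                          peak_cfg = peak_config(),
                          rate = 100) {
  if (is.null(bundle$rate)) bundle <- resample_to_grid(bundle, rate)
  w <- detect_palpation_window(bundle, seg_cfg)
  if (w$status != "ok")
    return(list(window = w, touchpoints = NULL, proj = NULL, metrics = NULL))
  tp <- detect_touchpoints(bundle, w, layout, peak_cfg)
  m <- motor_location(layout, bundle$fistula_id)
  proj <- tryCatch(compute_velocity_projection(bundle, w, m),
                   palpmetrics_too_few_frames = function(e) {
                     data.frame(t = numeric(), V_p = numeric())
                   })
  metrics <- compute_trial_metrics(bundle, w, tp, proj, peak_cfg)
  list(window = w, touchpoints = tp, proj = proj, metrics = metrics)
}

#' Compute metrics for a whole cohort
#'
#' @param bundles List of trial bundles (e.g. from [read_cohort()] or
#'   [generate_cohort()]).
#' @param layout A [simulator_layout()].
#' @param seg_cfg,peak_cfg Configurations.
#' @param rate Resampling rate (Hz).
#' @return Data frame, one row per trial: ids, conditions, skill group,
#'   `stb`, window fields, and (for trials with an ok window) all twelve
#'   metrics.
#' @export
compute_cohort_metrics <- function(bundles, layout,
                                   seg_cfg = segmentation_config(),
                                   peak_cfg = peak_config(),
                                   rate = 100) {
  rows <- lapply(bundles, function(b) {
    res <- analyze_trial(b, layout, seg_cfg, peak_cfg, rate)
    base <- data.frame(
      trial_id = b$trial_id, subject_id = b$subject_id,
      fistula_id = b$fistula_id, skin = b$skin, vibration = b$vibration,
      group = as.character(classify_skill(b$grs_palpation, b$grs_overall)),
      stb = b$stb,
      T_start = res$window$T_start %||% NA_real_,
      T_end = res$window$T_end %||% NA_real_,
      seg_method = res$window$method, seg_status = res$window$status)
    if (is.null(res$metrics)) {
      empty <- data.frame(touchpoints = NA_integer_, frequency = NA_real_,
                          total_force = NA_real_, force_range = NA_real_,
                          dwell_time = NA_real_, idle_time = NA_real_,
                          path_length = NA_real_, rcm = NA_real_,
                          rntp = NA_real_, mean_tpt = NA_real_,
                          mean_tpf = NA_real_, mean_tpd = NA_real_,
                          location_valid = NA)
      cbind(base, empty)
    } else cbind(base, res$metrics)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
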