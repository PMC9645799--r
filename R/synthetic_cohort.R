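# Synthetic cohort generator with ground truth.
#
# Stands in for the study's (non-deposited) raw recordings: each trial is
# built from an explicit event list -- a quiescent period, a train of
# touch events (parabolic force pulses whose full width at half maximum
# equals the intended dwell), a fingertip trajectory that dwells at each
# touch location and travels between them in the inter-touch gaps, and a
# needle-pickup event (thumb-force ramp plus needle displacement) that
# ends palpation -- then rendered to per-channel sample streams with
# additive Gaussian sensor noise. The event list is returned as ground
# truth so every pipeline stage can be validated against it.
#
# Default skill profiles are parameterized so that the observable group
# medians land on the published LP/MP/HP central values where those are
# jointly attainable; quantities that are algebraically determined by
# other parameters (dwell time, frequency, total force, force range)
# carry derived targets instead. Touch-location sequencing uses a
# Gaussian copula over the touch-to-motor distance: the marginal distance
# law (which fixes mean TPD and RNTP) is a truncated lognormal, while the
# move structure (seek legs toward the motor, slow deliberate inbound
# travel vs ballistic outbound travel, angular wander) shapes RCM and
# path length and is calibrated by simulation to those targets.

# solve truncated-lognormal (at d_max) parameters so that the truncated
# mean equals `mean_target` and P(d < near_radius) equals `near_frac`
solve_distance_params <- function(mean_target, near_frac, d_max,
                                  near_radius = 40) {
  trunc_mean <- function(mu, s) {
    exp(mu + s^2 / 2) * stats::pnorm((log(d_max) - mu - s^2) / s) /
      stats::pnorm((log(d_max) - mu) / s)
  }
  mu_for_s <- function(s) {
    f <- function(mu) {
      lr <- stats::pnorm((log(near_radius) - mu) / s, log.p = TRUE) -
        stats::pnorm((log(d_max) - mu) / s, log.p = TRUE)
      exp(lr) - near_frac
    }
    stats::uniroot(f, c(log(near_radius) - 8 * max(s, 1),
                        log(d_max) + 8 * max(s, 1)),
                   extendInt = "yes", tol = 1e-10)$root
  }
  g <- function(s) trunc_mean(mu_for_s(s), s) - mean_target
  s <- stats::uniroot(g, c(0.05, 2.5), tol = 1e-9)$root
  list(meanlog = mu_for_s(s), sdlog = s, d_max = d_max)
}

# Per-touchpoint near-motor probability whose per-trial binomial
# proportion has median equal to the RNTP target. Trial RNTP values are
# quantized to multiples of 1/count, so the observable median is pinned
# by solving P(100 K/N >= target) = 0.5 over the count distribution.
solve_near_prob <- function(rntp_target, nb_size, nb_mu) {
  ns <- 2:stats::qnbinom(0.999, size = nb_size, mu = nb_mu)
  wn <- stats::dnbinom(ns, size = nb_size, mu = nb_mu)
  wn[1] <- wn[1] + stats::pnbinom(1, size = nb_size, mu = nb_mu)
  wn <- wn / sum(wn)
  g <- function(p) {
    kmin <- ceiling(rntp_target * ns / 100 - 1e-9)
    sum(wn * (1 - stats::pbinom(kmin - 1, ns, p))) - 0.5
  }
  stats::uniroot(g, c(0.005, 0.95), tol = 1e-8)$root
}

# quantile of the truncated lognormal distance law
q_distance <- function(p, dist) {
  stats::qlnorm(p * stats::plnorm(dist$d_max, dist$meanlog, dist$sdlog),
                dist$meanlog, dist$sdlog)
}

#' Construct a skill profile for the synthetic generator
#'
#' @param name Profile label (e.g. `"LP"`).
#' @param touchpoint_median Target median touchpoint count (negative
#'   binomial, dispersion `touchpoint_size`).
#' @param tpt_mean,tpt_sdlog Per-touchpoint dwell: lognormal with this
#'   mean (s) and log-scale sd.
#' @param tpf_mean,tpf_sdlog Per-touchpoint peak force: lognormal mean (N)
#'   and log-scale sd.
#' @param idle_target Target idle time (s); sets the inter-touch gap law.
#' @param tpd_mean Target mean touch-to-motor distance (mm).
#' @param rntp_target Target percentage of touchpoints within 40 mm.
#' @param rcm_target Target ratio of correct movement (%); realised via
#'   `seek_prob` and `toward_slowdown`.
#' @param pl_target Target path length (mm); realised via `angle_sd`,
#'   `wander_rho` and `seek_depth`.
#' @param approach_bias Descending drift of the distance sequence in
#'   copula (z) units; larger values mean the subject homes in on the
#'   motor more steadily.
#' @param seek_prob Probability that an inter-touch move first heads
#'   toward the motor (a "seek" leg) before veering out to the next touch
#'   location.
#' @param seek_depth Range of the seek-leg depth: the fraction of the
#'   current distance to the motor covered by the inbound leg.
#' @param toward_slowdown Factor by which motor-directed travel is slower
#'   than outbound travel (deliberate homing versus ballistic
#'   repositioning); together with `seek_prob` this sets RCM, which is a
#'   time-frame ratio.
#' @param angle_sd Sd (rad) of the angular random-walk step between
#'   successive touch locations; with `wander_rho`, the main determinant
#'   of path length.
#' @param wander_rho AR(1) correlation of successive touch distances in
#'   copula units; higher values mean more local exploration (shorter
#'   direct moves).
#' @param touchpoint_size Negative-binomial size (dispersion).
#' @param gap_sdlog Log-scale sd of the inter-touch gap law.
#' @param quiescence Range (s) of the pre-palpation quiet period.
#' @param stb_intercept,stb_coefs Logistic outcome model: intercept is the
#'   group log-odds of success at target behaviour; `stb_coefs` is a named
#'   vector of slopes on (true metric - target) differences.
#' @param atypical `"none"`, `"needle_in_hand"` (needle carried in the
#'   free hand: no pickup event, needle moves throughout) or
#'   `"thumb_only"` (palpation with the thumb; no index/middle force).
#' @return Object of class `skill_profile` with a `targets` element
#'   holding the implied central value of each of the twelve metrics.
#' @export
skill_profile <- function(name,
                          touchpoint_median,
                          tpt_mean, tpt_sdlog = 0.40,
                          tpf_mean, tpf_sdlog = 0.50,
                          idle_target,
                          tpd_mean, rntp_target,
                          rcm_target, pl_target,
                          approach_bias = 0.5,
                          seek_prob = 0.5,
                          seek_depth = c(0.35, 0.7),
                          toward_slowdown = 2.5,
                          angle_sd = 0.7,
                          wander_rho = 0.3,
                          touchpoint_size = 40,
                          gap_sdlog = 0.5,
                          quiescence = c(2, 4),
                          stb_intercept = 0,
                          stb_coefs = c(),
                          atypical = "none") {
  if (touchpoint_median < 1)
    stop_palp("degenerate_profile", "touchpoint_median must be >= 1")
  for (v in c(tpt_mean, tpf_mean, idle_target, tpd_mean))
    if (!is_scalar_number(v) || v <= 0)
      stop_palp("degenerate_profile", "scale parameters must be positive")
  # gap mean such that measured idle (window minus summed half-prominence
  # widths) hits idle_target: pulse support is sqrt(2) x FWHM, so each
  # pulse contributes (sqrt(2)-1) x dwell of non-dwell time
  gap_mean <- idle_target / touchpoint_median - (sqrt(2) - 1) * tpt_mean
  if (gap_mean <= 0.12)
    stop_palp("degenerate_profile",
              "idle_target too small for the requested dwell structure")
  # negative-binomial mean placing the median robustly at the requested
  # count: P(X <= target - 1) pinned at 0.42 so that small stochastic
  # shifts cannot move the realized median off target
  nb_mu <- tryCatch(stats::uniroot(function(mu)
    stats::pnbinom(touchpoint_median - 1, size = touchpoint_size,
                   mu = mu) - 0.42,
    c(touchpoint_median * 0.7, touchpoint_median * 2))$root,
    error = function(e) touchpoint_median)
  near_p <- solve_near_prob(rntp_target, touchpoint_size, nb_mu)
  dist <- solve_distance_params(tpd_mean, near_p, d_max = 195)

  # derived targets ----------------------------------------------------
  dwell_t <- touchpoint_median * tpt_mean
  window_t <- dwell_t + idle_target
  # median maximum of n iid lognormal peak forces (F_max = F^n), plus
  # the raw-noise excess at the tallest pulse apex; sensors clip at zero
  # so the window minimum is ~0
  mlf <- log(tpf_mean) - tpf_sdlog^2 / 2
  n <- touchpoint_median
  force_range_t <- exp(mlf + tpf_sdlog *
                         stats::qnorm(0.5^(1 / n))) + 0.025
  # path-length noise floor: stationary frames accumulate smoothed-jitter
  # steps of E|step| = pos_sd * 0.3545 at the default 100 Hz / MA(5)
  stationary_t <- window_t - (touchpoint_median - 1) * gap_mean
  pl_floor <- stationary_t * 100 * 0.5 * 0.3545

  targets <- c(
    touchpoints = touchpoint_median,
    frequency = touchpoint_median / window_t,
    total_force = touchpoint_median * tpt_mean * tpf_mean,
    force_range = force_range_t,
    dwell_time = dwell_t,
    idle_time = idle_target,
    path_length = pl_target,
    rcm = rcm_target,
    rntp = rntp_target,
    mean_tpt = tpt_mean,
    mean_tpf = tpf_mean,
    mean_tpd = tpd_mean)

  structure(list(
    name = name,
    touchpoint_median = touchpoint_median,
    touchpoint_size = touchpoint_size,
    nb_mu = nb_mu,
    tpt_mean = tpt_mean, tpt_sdlog = tpt_sdlog,
    tpf_mean = tpf_mean, tpf_sdlog = tpf_sdlog,
    idle_target = idle_target,
    gap_mean = gap_mean, gap_sdlog = gap_sdlog,
    dist = dist,
    approach_bias = approach_bias,
    seek_prob = seek_prob,
    seek_depth = seek_depth,
    toward_slowdown = toward_slowdown,
    angle_sd = angle_sd,
    wander_rho = wander_rho,
    rcm_target = rcm_target, pl_target = pl_target,
    pl_floor = pl_floor,
    quiescence = quiescence,
    stb_intercept = stb_intercept,
    stb_coefs = stb_coefs,
    atypical = atypical,
    targets = targets
  ), class = "skill_profile")
}

#' Default LP / MP / HP skill profiles
#'
#' Parameterized to the published group central values: touchpoint counts
#' 20/15/13, per-touchpoint dwell 0.326/0.386/0.350 s, peak force
#' 0.305/0.322/0.267 N, idle time 6.73/6.04/5.05 s, mean touch-to-motor
#' distance 81.0/80.9/54.0 mm, near-touchpoint ratio 12.1/22.2/27.9 %,
#' ratio of correct movement 66.7/66.7/75 % and path length 1373/1128/871
#' mm for LP/MP/HP respectively. Outcome-model intercepts put the success
#' probability at 0.548/0.850/0.946, and slopes carry the signs of the
#' published stratified models (LP success falls with idle time,
#' touchpoints and frequency and rises with per-touchpoint dwell; MP
#' success falls with dwell time and total force and rises with
#' frequency).
#'
#' @return Named list of three [skill_profile()] objects (`LP`, `MP`,
#'   `HP`).
#' @export
default_skill_profiles <- function() {
  list(
    LP = skill_profile("LP",
      touchpoint_median = 20, tpt_mean = 0.326, tpf_mean = 0.305,
      idle_target = 6.73, tpd_mean = 81.0, rntp_target = 12.1,
      rcm_target = 66.7, pl_target = 1373,
      approach_bias = 0.62, seek_prob = 0.85, seek_depth = c(0.22, 0.45),
      toward_slowdown = 6.0, angle_sd = 0.45, wander_rho = 0.60,
      stb_intercept = 0.1928,
      stb_coefs = c(idle_time = -0.35, touchpoints = -0.12,
                    frequency = -3.0, mean_tpt = 8.0)),
    MP = skill_profile("MP",
      touchpoint_median = 15, tpt_mean = 0.386, tpf_mean = 0.322,
      idle_target = 6.04, tpd_mean = 80.9, rntp_target = 22.2,
      rcm_target = 66.7, pl_target = 1128,
      approach_bias = 0.62, seek_prob = 0.85, seek_depth = c(0.22, 0.45),
      toward_slowdown = 5.5, angle_sd = 0.55, wander_rho = 0.65,
      stb_intercept = 1.7346,
      stb_coefs = c(dwell_time = -0.30, total_force = -1.2,
                    frequency = 2.0)),
    HP = skill_profile("HP",
      touchpoint_median = 13, tpt_mean = 0.350, tpf_mean = 0.267,
      idle_target = 5.05, tpd_mean = 54.0, rntp_target = 27.9,
      rcm_target = 75, pl_target = 871,
      approach_bias = 0.93, seek_prob = 1.0, seek_depth = c(0.40, 0.70),
      toward_slowdown = 16, angle_sd = 0.70, wander_rho = 0.30,
      stb_intercept = 2.8608,
      stb_coefs = c())
  )
}

# clamp a touch direction into the arc for which the touch location stays
# on the bed (needed when the draw distance exceeds bed_radius - |motor|)
feasible_angle <- function(theta, d, motor, bed_radius) {
  mm <- sqrt(sum(motor^2))
  if (mm < 1e-9) return(theta)
  cmax <- (bed_radius^2 - mm^2 - d^2) / (2 * d * mm)
  if (cmax >= 1) return(theta)
  phi <- atan2(motor[2], motor[1])
  amin <- acos(max(-1, cmax))
  psi <- (theta - phi + pi) %% (2 * pi) - pi
  if (abs(psi) < amin) psi <- ifelse(psi >= 0, amin, -amin)
  phi + psi
}

#' Generate one synthetic palpation trial
#'
#' @param profile A [skill_profile()].
#' @param layout A [simulator_layout()].
#' @param fistula_id Active fistula (1..4).
#' @param skin,vibration Trial conditions.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param trial_id,subject_id Identifiers.
#' @param grs Integer `c(palpation, overall)` GRS scores for the metadata.
#' @param noise List with `force` (N) and `pos` (mm) Gaussian sds.
#' @param dropout_prob Probability of a 0.3 s fingertip position dropout
#'   burst inside the palpation window.
#' @return List with `bundle` (a [trial_bundle()]) and `truth` (the event
#'   list and analytically implied metric values).
#' @export
generate_trial <- function(profile, layout, fistula_id = 1L,
                           skin = "thin", vibration = "low",
                           seed = 1L,
                           trial_id = "trial", subject_id = "subject",
                           grs = c(4L, 3L),
                           noise = list(force = 0.02, pos = 0.5),
                           dropout_prob = 0.15) {
  with_seed(seed, {
    motor <- motor_location(layout, fistula_id)
    R <- layout$bed_radius

    # ---- event list ---------------------------------------------------
    q <- stats::runif(1, profile$quiescence[1], profile$quiescence[2])
    n <- max(2L, stats::rnbinom(1, size = profile$touchpoint_size,
                                mu = profile$nb_mu))
    dwell <- stats::rlnorm(n, log(profile$tpt_mean) - profile$tpt_sdlog^2 / 2,
                           profile$tpt_sdlog)
    # peak forces: lognormal truncated below 0.08 N (lighter contacts do
    # not register as distinct touches on the force sensor)
    mlf <- log(profile$tpf_mean) - profile$tpf_sdlog^2 / 2
    p0 <- stats::plnorm(0.08, mlf, profile$tpf_sdlog)
    force <- stats::qlnorm(stats::runif(n, p0, 1), mlf, profile$tpf_sdlog)
    force[1] <- max(force[1], 0.25)   # initial contact is a deliberate press
    gfloor <- 0.1
    gmu <- max(profile$gap_mean - gfloor, 0.02)
    gap <- gfloor + stats::rlnorm(n, log(gmu) - profile$gap_sdlog^2 / 2,
                                  profile$gap_sdlog)

    # distance sequence: truncated-lognormal marginal via Gaussian copula
    # with descending drift (approach) and AR(1) wander
    a <- profile$approach_bias
    drift <- if (n > 1) a * seq(1, -1, length.out = n) else 0
    vdrift <- if (n > 1) mean(drift^2) else 0
    sres <- sqrt(max(1 - vdrift, 0.05))
    rho <- profile$wander_rho
    eps <- stats::rnorm(n)
    u <- numeric(n); u[1] <- eps[1]
    if (n > 1) for (i in 2:n) u[i] <- rho * u[i - 1] + sqrt(1 - rho^2) * eps[i]
    z <- drift + sres * u
    d_tp <- q_distance(stats::pnorm(z), profile$dist)

    theta <- numeric(n)
    theta[1] <- stats::runif(1, 0, 2 * pi)
    if (n > 1) {
      steps <- stats::rnorm(n - 1, 0, profile$angle_sd)
      theta[2:n] <- theta[1] + cumsum(steps)
    }
    loc <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      th <- feasible_angle(theta[i], d_tp[i], motor, R)
      loc[i, ] <- motor + d_tp[i] * c(cos(th), sin(th))
    }

    W <- sqrt(2) * dwell                 # parabolic pulse support widths
    s_start <- numeric(n)
    s_start[1] <- q
    if (n > 1) for (i in 2:n) s_start[i] <- s_start[i - 1] + W[i - 1] + gap[i - 1]
    T_start <- q
    T_end <- s_start[n] + W[n] + gap[n]
    tail_s <- 3.0
    trial_end <- T_end + tail_s
    centers <- s_start + W / 2

    # inter-touch move polylines: with probability seek_prob the finger
    # first homes in toward the motor (a "seek" leg) before veering out
    # to the next touch location
    moves <- vector("list", max(n - 1L, 0L))
    if (n > 1) {
      for (i in 1:(n - 1)) {
        A <- loc[i, ]; B <- loc[i + 1, ]
        if (stats::runif(1) < profile$seek_prob) {
          gam <- stats::runif(1, profile$seek_depth[1], profile$seek_depth[2])
          C <- A + gam * (motor - A) + stats::rnorm(2, 0, 3)
          moves[[i]] <- rbind(C, B)
        } else moves[[i]] <- rbind(B)
      }
    }

    # ---- move timing and true metrics ---------------------------------
    # per-move legs: length, toward-fraction (share of the leg on which
    # the motor distance is decreasing), and a time allocation in which
    # motor-directed travel is toward_slowdown times slower
    span <- T_end - T_start
    seg_len <- 0; t_move <- 0; t_toward <- 0
    move_times <- vector("list", max(n - 1L, 0L))
    if (n > 1) {
      for (i in 1:(n - 1)) {
        P <- rbind(loc[i, ], moves[[i]])
        nl <- nrow(P) - 1L
        len <- frac <- numeric(nl)
        for (j in seq_len(nl)) {
          A <- P[j, ]; B <- P[j + 1, ]
          ab <- B - A; len[j] <- sqrt(sum(ab^2))
          frac[j] <- if (len[j] > 1e-12) {
            min(max(sum((motor - A) * ab) / sum(ab^2), 0), 1)
          } else 0
        }
        w <- len * (1 + (profile$toward_slowdown - 1) * frac)
        tj <- if (sum(w) > 1e-12) gap[i] * w / sum(w) else
          rep(gap[i] / nl, nl)
        move_times[[i]] <- tj
        seg_len <- seg_len + sum(len)
        t_move <- t_move + sum(tj)
        t_toward <- t_toward + sum(tj * frac)
      }
    }
    true_metrics <- c(
      touchpoints = n,
      frequency = n / span,
      total_force = sum(dwell * force),
      force_range = max(force),
      dwell_time = sum(dwell),
      idle_time = span - sum(dwell),
      path_length = seg_len,
      rcm = if (t_move > 0) 100 * t_toward / t_move else NA_real_,
      rntp = 100 * mean(d_tp < 40),
      mean_tpt = mean(dwell),
      mean_tpf = mean(force),
      mean_tpd = mean(d_tp))

    # ---- outcome ------------------------------------------------------
    eta <- profile$stb_intercept
    if (length(profile$stb_coefs)) {
      for (nm in names(profile$stb_coefs))
        eta <- eta + profile$stb_coefs[[nm]] *
          (true_metrics[[nm]] - profile$targets[[nm]])
    }
    p_succ <- stats::plogis(eta)
    stb <- stats::rbinom(1, 1, p_succ)

    # ---- render channels ---------------------------------------------
    thumb_only <- identical(profile$atypical, "thumb_only")
    needle_in_hand <- identical(profile$atypical, "needle_in_hand")

    t_force <- seq(0, trial_end, by = 1 / 80)
    t_pos   <- seq(0, trial_end, by = 1 / 100)
    t_flash <- seq(0, trial_end, by = 1 / 50)

    pulse_sum <- function(tt) {
      out <- numeric(length(tt))
      for (i in seq_len(n)) {
        lo <- s_start[i]; hi <- s_start[i] + W[i]
        idx <- which(tt >= lo & tt <= hi)
        if (length(idx)) {
          x <- (tt[idx] - centers[i]) / (W[i] / 2)
          out[idx] <- out[idx] + force[i] * pmax(0, 1 - x^2)
        }
      }
      out
    }
    comb <- pulse_sum(t_force)
    share <- stats::runif(1, 0.55, 0.75)
    if (thumb_only) {
      f_index <- numeric(length(t_force))
      f_middle <- numeric(length(t_force))
      f_thumb_base <- comb
    } else {
      f_index <- share * comb
      f_middle <- (1 - share) * comb
      f_thumb_base <- rep(0.05, length(t_force))
    }
    if (!needle_in_hand && !thumb_only) {
      ramp <- pmin(pmax((t_force - T_end) / 0.3, 0), 1) * 1.5
      f_thumb <- f_thumb_base + ramp
    } else f_thumb <- f_thumb_base

    # fingertip trajectory from keyframes (rest -> approach -> dwell at
    # each touch location, travelling during the inter-touch gaps)
    rest_ang <- stats::runif(1, 0, 2 * pi)
    P0 <- 0.85 * R * c(cos(rest_ang), sin(rest_ang))
    kf_t <- c(0, max(q - 0.5, 0.1))
    kf_x <- c(P0[1], P0[1]); kf_y <- c(P0[2], P0[2])
    for (i in seq_len(n)) {
      kf_t <- c(kf_t, s_start[i], s_start[i] + W[i])
      kf_x <- c(kf_x, loc[i, 1], loc[i, 1])
      kf_y <- c(kf_y, loc[i, 2], loc[i, 2])
      if (i < n && nrow(moves[[i]]) > 1L) {
        # travel through the move waypoints during the gap, using the
        # per-leg time allocation
        P <- rbind(loc[i, ], moves[[i]])
        cumt <- cumsum(move_times[[i]])
        wp_t <- s_start[i] + W[i] + cumt[-length(cumt)]
        kf_t <- c(kf_t, wp_t)
        kf_x <- c(kf_x, P[2:(nrow(P) - 1), 1])
        kf_y <- c(kf_y, P[2:(nrow(P) - 1), 2])
      }
    }
    kf_t <- c(kf_t, trial_end)
    kf_x <- c(kf_x, loc[n, 1]); kf_y <- c(kf_y, loc[n, 2])
    fx <- stats::approx(kf_t, kf_x, xout = t_pos, rule = 2)$y
    fy <- stats::approx(kf_t, kf_y, xout = t_pos, rule = 2)$y
    fz <- rep(10, length(t_pos))

    # needle: parked until pickup, then a 30 mm displacement over 0.5 s
    npark <- c(0.9 * R, -0.9 * R, 15)
    if (needle_in_hand) {
      # carried in the free hand: slow continuous wander, no pickup
      wander <- apply(matrix(stats::rnorm(3 * length(t_pos), 0, 1.5), ncol = 3),
                      2, cumsum) / sqrt(seq_along(t_pos))
      nx <- npark[1] + 20 * sin(2 * pi * t_pos / 7) + wander[, 1]
      ny <- npark[2] + 20 * cos(2 * pi * t_pos / 9) + wander[, 2]
      nz <- npark[3] + 10 * sin(2 * pi * t_pos / 5) + wander[, 3]
    } else {
      mv <- pmin(pmax((t_pos - T_end) / 0.5, 0), 1) * 30
      nx <- npark[1] - mv * 0.5
      ny <- npark[2] + mv * 0.5
      nz <- npark[3] + mv * sqrt(0.5)
    }

    flash <- as.numeric(stb == 1 & t_flash >= trial_end - 2.5)

    nf <- function(x, sd) x + stats::rnorm(length(x), 0, sd)
    fx <- nf(fx, noise$pos); fy <- nf(fy, noise$pos); fz <- nf(fz, noise$pos)
    nx <- nf(nx, noise$pos); ny <- nf(ny, noise$pos); nz <- nf(nz, noise$pos)
    # force sensors clip at zero: no negative readings
    f_index <- pmax(nf(f_index, noise$force), 0)
    f_middle <- pmax(nf(f_middle, noise$force), 0)
    f_thumb <- pmax(nf(f_thumb, noise$force), 0)

    dropout <- stats::runif(1) < dropout_prob
    if (dropout) {
      d0 <- stats::runif(1, T_start + 0.5, max(T_end - 1, T_start + 0.6))
      bad <- t_pos >= d0 & t_pos <= d0 + 0.3
      fx[bad] <- NA_real_; fy[bad] <- NA_real_; fz[bad] <- NA_real_
    }

    chans <- list(
      force_thumb = channel_series("force_thumb", t_force, f_thumb),
      force_index = channel_series("force_index", t_force, f_index),
      force_middle = channel_series("force_middle", t_force, f_middle),
      finger_x = channel_series("finger_x", t_pos, fx),
      finger_y = channel_series("finger_y", t_pos, fy),
      finger_z = channel_series("finger_z", t_pos, fz),
      needle_x = channel_series("needle_x", t_pos, nx),
      needle_y = channel_series("needle_y", t_pos, ny),
      needle_z = channel_series("needle_z", t_pos, nz),
      flashback = channel_series("flashback", t_flash, flash))

    bundle <- trial_bundle(
      trial_id = trial_id, subject_id = subject_id,
      fistula_id = fistula_id, skin = skin, vibration = vibration,
      grs_palpation = grs[1], grs_overall = grs[2],
      stb = stb, channels = chans)

    truth <- list(
      T_start = T_start, T_end = T_end,
      touchpoints = data.frame(t = centers, dwell = dwell, force = force,
                               x = loc[, 1], y = loc[, 2], tpd = d_tp),
      metrics = as.list(true_metrics),
      p_success = as.numeric(p_succ),
      stb = stb,
      dropout = dropout,
      profile = profile$name)

    list(bundle = bundle, truth = truth)
  })
}

# GRS score pairs consistent with each group's classification rule
draw_grs <- function(group) {
  switch(group,
    HP = c(7L, 7L),
    LP = c(sample(1:5, 1), sample(1:4, 1)),
    MP = {
      pick <- sample(1:3, 1)
      if (pick == 1L) c(6L, sample(4:7, 1))
      else if (pick == 2L) c(7L, sample(4:6, 1))
      else c(sample(4:5, 1), sample(5:7, 1))
    },
    stop_palp("schema", "unknown group '%s'", group))
}

#' Generate a synthetic cohort
#'
#' Every subject performs `trials_per_subject` trials covering a seeded
#' random permutation of the 16 condition combinations (4 fistulas x 2
#' skin thicknesses x 2 vibration intensities; with fewer trials, a
#' random subset of that permutation). GRS scores are drawn once per
#' subject, consistent with the subject's group, so [classify_skill()]
#' recovers the intended grouping. Trials are seeded individually from
#' the global seed via a counter scheme, so any single trial can be
#' regenerated in isolation.
#'
#' @param n_subjects Named vector of subject counts per group, e.g.
#'   `c(LP = 10, MP = 10, HP = 10)`.
#' @param trials_per_subject Trials per subject (default 16).
#' @param profiles Named list of [skill_profile()]s (defaults to
#'   [default_skill_profiles()]).
#' @param layout A [simulator_layout()].
#' @param seed Global integer seed.
#' @param dir Optional directory: when given, bundles are written in the
#'   on-disk cohort format together with `ground_truth.json`.
#' @param ... Passed to [generate_trial()] (noise, dropout).
#' @return List with `bundles` (named list), `truth` (named list) and
#'   `info` (data frame of ids, group and conditions).
#' @export
generate_cohort <- function(n_subjects = c(LP = 10, MP = 10, HP = 10),
                            trials_per_subject = 16,
                            profiles = default_skill_profiles(),
                            layout = default_layout(),
                            seed = 1L, dir = NULL, ...) {
  if (any(n_subjects < 1)) stop_palp("schema", "subject counts must be >= 1")
  conds <- expand.grid(fistula_id = 1:4, skin = c("thin", "thick"),
                       vibration = c("low", "high"),
                       stringsAsFactors = FALSE)
  bundles <- list(); truths <- list(); info <- list()
  counter <- 0L
  for (g in names(n_subjects)) {
    prof <- profiles[[g]]
    if (is.null(prof)) stop_palp("schema", "no profile for group '%s'", g)
    for (s in seq_len(n_subjects[[g]])) {
      counter <- counter + 1L
      subj_seed <- derive_seed(seed, counter * 100000L)
      subj <- with_seed(subj_seed, list(
        grs = draw_grs(g),
        order = sample(nrow(conds))))
      subject_id <- sprintf("%s%02d", tolower(g), s)
      for (k in seq_len(trials_per_subject)) {
        counter <- counter + 1L
        cid <- subj$order[(k - 1L) %% nrow(conds) + 1L]
        trial_id <- sprintf("%s_t%02d", subject_id, k)
        res <- generate_trial(
          prof, layout,
          fistula_id = conds$fistula_id[cid],
          skin = conds$skin[cid], vibration = conds$vibration[cid],
          seed = derive_seed(seed, counter),
          trial_id = trial_id, subject_id = subject_id,
          grs = subj$grs, ...)
        bundles[[trial_id]] <- res$bundle
        truths[[trial_id]] <- res$truth
        info[[length(info) + 1L]] <- data.frame(
          trial_id = trial_id, subject_id = subject_id, group = g,
          fistula_id = conds$fistula_id[cid], skin = conds$skin[cid],
          vibration = conds$vibration[cid])
      }
    }
  }
  info <- do.call(rbind, info)
  rownames(info) <- NULL
  if (!is.null(dir)) {
    write_cohort(bundles, dir)
    gt <- lapply(truths, function(tr) {
      list(T_start = tr$T_start, T_end = tr$T_end, metrics = tr$metrics,
           p_success = tr$p_success, stb = tr$stb, dropout = tr$dropout,
           profile = tr$profile)
    })
    write_json_file(gt, file.path(dir, "ground_truth.json"))
  }
  list(bundles = bundles, truth = truths, info = info)
}
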