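ok_window <- function(T_start, T_end) {
  list(T_start = T_start, T_end = T_end, method = "manual", status = "ok")
}

test_that("a triangular pulse gives the closed-form touchpoint", {
  t <- seq(0, 10, by = 0.01)
  tri <- pmax(0, 1 - abs(t - 5))          # apex 1 N at t = 5 s, base 2 s
  b <- as_resampled(make_bundle(t, force_index = tri), 100)
  tp <- detect_touchpoints(b, ok_window(2, 8), default_layout())
  expect_equal(nrow(tp), 1L)
  expect_equal(tp$t_tp, 5, tolerance = 0.011)
  # half-prominence width of a triangle is half its base
  expect_equal(tp$TPT, 1.0, tolerance = 0.011)
  expect_equal(tp$TPF, 1.0, tolerance = 0.02)
})

test_that("well-separated pulses are each recovered at their centre", {
  t <- seq(0, 20, by = 0.01)
  centers <- c(4, 6.5, 9, 12.5, 16)
  f <- numeric(length(t))
  for (ct in centers) f <- f + 0.4 * exp(-(t - ct)^2 / (2 * 0.15^2))
  b <- as_resampled(make_bundle(t, force_index = f), 100)
  tp <- detect_touchpoints(b, ok_window(2, 18), default_layout())
  expect_equal(nrow(tp), length(centers))
  expect_true(all(abs(tp$t_tp - centers) <= 0.0100001))
})

test_that("degenerate windows are rejected", {
  t <- seq(0, 10, by = 0.01)
  b <- as_resampled(make_bundle(t), 100)
  expect_error(detect_touchpoints(b, ok_window(5, 5), default_layout()),
               class = "palpmetrics_empty_window")
})

test_that("touchpoints with missing position keep force fields only", {
  t <- seq(0, 10, by = 0.01)
  tri <- pmax(0, 1 - abs(t - 5))
  fx <- rep(30, length(t)); fx[t > 4.5 & t < 5.5] <- NA
  b <- as_resampled(make_bundle(t, force_index = tri, finger_x = fx,
                                finger_y = rep(40, length(t))), 100)
  tp <- detect_touchpoints(b, ok_window(2, 8), default_layout())
  expect_equal(nrow(tp), 1L)
  expect_true(is.na(tp$x_tp) && is.na(tp$TPD))
  expect_false(is.na(tp$TPF))
})

test_that("velocity projection has the right sign and magnitude", {
  motor <- c(0, 0)
  t <- seq(0, 4, by = 0.01)
  # straight toward the motor at 50 mm/s
  b <- as_resampled(make_bundle(t, finger_x = 210 - 50 * t,
                                finger_y = rep(0, length(t))), 100)
  pr <- compute_velocity_projection(b, ok_window(0.1, 3.9), motor)
  vp <- pr$V_p[!is.na(pr$V_p)]
  expect_equal(median(vp), 50, tolerance = 1e-6)
  # straight away: sign flips
  b2 <- as_resampled(make_bundle(t, finger_x = 10 + 50 * t,
                                 finger_y = rep(0, length(t))), 100)
  pr2 <- compute_velocity_projection(b2, ok_window(0.1, 3.9), motor)
  expect_equal(median(pr2$V_p, na.rm = TRUE), -50, tolerance = 1e-6)
})

test_that("circular motion about the motor projects to (near) zero", {
  motor <- c(10, -20)
  t <- seq(0, 6.28, by = 0.01)
  b <- as_resampled(make_bundle(t, finger_x = motor[1] + 50 * cos(t),
                                finger_y = motor[2] + 50 * sin(t)), 100)
  pr <- compute_velocity_projection(b, ok_window(0.1, 6.2), motor)
  vp <- pr$V_p[!is.na(pr$V_p)]
  expect_lt(max(abs(vp)), 0.02 * 50)      # below 2% of the 50 mm/s speed
})

test_that("RCM matches its definition on constructed projections", {
  cfg <- peak_config()
  expect_equal(compute_rcm(data.frame(t = 1:10, V_p = rep(50, 10)), cfg), 100)
  expect_equal(compute_rcm(
    data.frame(t = 1:10, V_p = rep(c(50, -50), 5)), cfg), 50)
  expect_true(is.na(compute_rcm(
    data.frame(t = 1:10, V_p = runif(10, -19, 19)), cfg)))
  # random series vs an independent recount
  set.seed(5)
  vp <- rnorm(500, 0, 40); vp[sample(500, 30)] <- NA
  got <- compute_rcm(data.frame(t = seq_along(vp), V_p = vp), cfg)
  tow <- 0L; sig <- 0L
  for (v in vp) if (!is.na(v) && abs(v) > 20) {
    sig <- sig + 1L
    if (v > 20) tow <- tow + 1L
  }
  expect_equal(got, 100 * tow / sig)
})

test_that("RNTP uses a strict 40 mm threshold", {
  cfg <- peak_config()
  tp <- data.frame(TPD = c(10, 39.9, 40.0, 100))
  expect_equal(compute_rntp(tp, cfg), 50)      # 40.0 is excluded
  expect_equal(compute_rntp(data.frame(TPD = c(0, 0, 0)), cfg), 100)
  expect_true(is.na(compute_rntp(data.frame(TPD = numeric(0)), cfg)))
  expect_true(is.na(compute_rntp(data.frame(TPD = NA_real_), cfg)))
})

test_that("trial metrics reproduce their closed-form examples", {
  t <- seq(0, 10, by = 0.01)
  b <- as_resampled(make_bundle(t), 100)
  w <- ok_window(0, 10)
  tp <- data.frame(t_tp = seq(0.5, 9.5, by = 1), TPT = rep(0.1, 10),
                   TPF = rep(0.5, 10), x_tp = 0, y_tp = 0, TPD = 10)
  pr <- data.frame(t = t, V_p = rep(0, length(t)))
  m <- compute_trial_metrics(b, w, tp, pr)
  expect_equal(m$frequency, 1.0)
  expect_equal(m$touchpoints, 10L)

  tp2 <- data.frame(t_tp = c(2, 6), TPT = c(1, 2), TPF = c(2, 3),
                    x_tp = 0, y_tp = 0, TPD = 10)
  m2 <- compute_trial_metrics(b, w, tp2, pr)
  expect_equal(m2$total_force, 8.0)
  expect_equal(m2$dwell_time, 3.0)
  expect_equal(m2$idle_time, 10 - 3.0)
})

test_that("force range is max minus min of the combined force", {
  t <- c(0, 1, 2)
  b <- as_resampled(make_bundle(t, force_index = c(0.1, 0.5, 0.3)), 1)
  m <- compute_trial_metrics(b, ok_window(0, 2),
                             data.frame(t_tp = 1, TPT = 0.5, TPF = 0.5,
                                        x_tp = 0, y_tp = 0, TPD = 1),
                             data.frame(t = t, V_p = NA_real_))
  expect_equal(m$force_range, 0.4)
})

test_that("path length recovers a square perimeter and a stationary finger", {
  n_side <- 100
  side <- seq(0, 10, length.out = n_side)
  sq_x <- c(side, rep(10, n_side), rev(side), rep(0, n_side))
  sq_y <- c(rep(0, n_side), side, rep(10, n_side), rev(side))
  t <- seq(0, by = 0.01, length.out = length(sq_x))
  b <- as_resampled(make_bundle(t, finger_x = sq_x, finger_y = sq_y), 100)
  tp <- data.frame(t_tp = 1, TPT = 0.1, TPF = 0.5, x_tp = 0, y_tp = 0, TPD = 1)
  pr <- data.frame(t = t, V_p = NA_real_)
  m <- compute_trial_metrics(b, ok_window(0, max(t)), tp, pr)
  expect_equal(m$path_length, 40, tolerance = 0.02)

  b0 <- as_resampled(make_bundle(t, finger_x = rep(5, length(t)),
                                 finger_y = rep(5, length(t))), 100)
  m0 <- compute_trial_metrics(b0, ok_window(0, max(t)), tp, pr)
  expect_equal(m0$path_length, 0)
})

test_that("dwell and idle time exactly partition the window", {
  lay <- default_layout()
  prof <- default_skill_profiles()$LP
  for (s in 1:5) {
    res <- generate_trial(prof, lay, seed = 400 + s)
    an <- analyze_trial(res$bundle, lay)
    expect_equal(an$metrics$dwell_time + an$metrics$idle_time,
                 an$window$T_end - an$window$T_start, tolerance = 1e-9)
  }
})

test_that("path length and TPD are invariant under rigid rotation", {
  lay <- default_layout()
  prof <- default_skill_profiles()$MP
  res <- generate_trial(prof, lay, seed = 99, dropout_prob = 0)
  b <- resample_to_grid(res$bundle, 100)
  w <- detect_palpation_window(b)
  motor <- motor_location(lay, b$fistula_id)
  tp <- detect_touchpoints(b, w, lay)
  m <- compute_trial_metrics(b, w, tp, data.frame(t = 0, V_p = NA_real_))

  th <- 1.1
  rot <- function(x, y) list(x = cos(th) * x - sin(th) * y,
                             y = sin(th) * x + cos(th) * y)
  b2 <- b
  r <- rot(b$channels$finger_x$v, b$channels$finger_y$v)
  b2$channels$finger_x <- channel_series("finger_x", b$channels$finger_x$t, r$x)
  b2$channels$finger_y <- channel_series("finger_y", b$channels$finger_y$t, r$y)
  mrot <- rot(motor[1], motor[2])
  lay2 <- lay
  lay2$fistulas[[b$fistula_id]]$motor <- c(mrot$x, mrot$y)
  tp2 <- detect_touchpoints(b2, w, lay2)
  m2 <- compute_trial_metrics(b2, w, tp2, data.frame(t = 0, V_p = NA_real_))
  expect_equal(m2$path_length, m$path_length, tolerance = 1e-9)
  expect_equal(tp2$TPD, tp$TPD, tolerance = 1e-9)
})

test_that("metrics agree with a brute-force recomputation on random trials", {
  lay <- default_layout()
  profs <- default_skill_profiles()
  for (s in 1:12) {
    prof <- profs[[(s %% 3) + 1]]
    res <- generate_trial(prof, lay, fistula_id = (s %% 4) + 1L,
                          seed = 6000 + s)
    an <- analyze_trial(res$bundle, lay)
    bf <- bf_trial_metrics(resample_to_grid(res$bundle, 100), an$window,
                           an$touchpoints, an$proj)
    for (nm in names(bf)) {
      if (is.na(bf[[nm]])) expect_true(is.na(an$metrics[[nm]]))
      else expect_equal(an$metrics[[nm]], bf[[nm]], tolerance = 1e-9,
                        info = nm)
    }
  }
})

test_that("appending touchpoints never decreases cumulative metrics", {
  t <- seq(0, 10, by = 0.01)
  b <- as_resampled(make_bundle(t), 100)
  w <- ok_window(0, 10)
  pr <- data.frame(t = t, V_p = NA_real_)
  tp <- data.frame(t_tp = c(2, 4), TPT = c(0.3, 0.4), TPF = c(0.5, 0.2),
                   x_tp = 0, y_tp = 0, TPD = 10)
  m1 <- compute_trial_metrics(b, w, tp, pr)
  tp2 <- rbind(tp, data.frame(t_tp = 6, TPT = 0.2, TPF = 0.3,
                              x_tp = 0, y_tp = 0, TPD = 10))
  m2 <- compute_trial_metrics(b, w, tp2, pr)
  expect_gt(m2$total_force, m1$total_force)
  expect_gt(m2$dwell_time, m1$dwell_time)
  expect_gt(m2$touchpoints, m1$touchpoints)
})
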