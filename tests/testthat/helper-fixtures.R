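# Fixtures built in code: minimal trial bundles on a uniform grid.

# A bundle whose channels are supplied as vectors on a common grid; any
# channel not given is flat at `fill`.
make_bundle <- function(t, ..., fill = 0, fistula_id = 1L, stb = 0L,
                        grs = c(4L, 3L), manual_window = NULL) {
  given <- list(...)
  chans <- list()
  for (nm in required_channels()) {
    v <- if (!is.null(given[[nm]])) given[[nm]] else rep(fill, length(t))
    chans[[nm]] <- channel_series(nm, t, v)
  }
  trial_bundle(trial_id = "t1", subject_id = "s1",
               fistula_id = fistula_id, skin = "thin", vibration = "low",
               grs_palpation = grs[1], grs_overall = grs[2], stb = stb,
               channels = chans, manual_window = manual_window)
}

# Mark a bundle as already resampled at `rate` (grid bundles built by
# make_bundle are uniform by construction).
as_resampled <- function(bundle, rate) {
  bundle$rate <- rate
  bundle
}

# A realistic trial: quiescence, an index/middle pulse train, then a
# thumb-grip + needle-move pickup. Deterministic (no noise).
make_pulse_trial <- function(pulse_times = c(4, 5, 6, 7, 8),
                             pulse_force = 0.5, pulse_fwhm = 0.4,
                             pickup_time = 12, rate = 100,
                             duration = 15, noise = 0) {
  t <- seq(0, duration, by = 1 / rate)
  f <- numeric(length(t))
  W <- sqrt(2) * pulse_fwhm
  for (ct in pulse_times) {
    x <- (t - ct) / (W / 2)
    f <- f + pulse_force * pmax(0, 1 - x^2)
  }
  thumb <- 0.05 + pmin(pmax((t - pickup_time) / 0.3, 0), 1) * 1.5
  mv <- pmin(pmax((t - pickup_time) / 0.5, 0), 1) * 30
  if (noise > 0) {
    f <- pmax(f + rnorm(length(t), 0, noise), 0)
    thumb <- pmax(thumb + rnorm(length(t), 0, noise), 0)
  }
  b <- make_bundle(t,
    force_index = 0.6 * f, force_middle = 0.4 * f, force_thumb = thumb,
    finger_x = rep(10, length(t)), finger_y = rep(20, length(t)),
    finger_z = rep(10, length(t)),
    needle_x = 100 - 0.5 * mv, needle_y = -100 + 0.5 * mv,
    needle_z = 15 + sqrt(0.5) * mv)
  as_resampled(b, rate)
}
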