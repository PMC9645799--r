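test_that("channel_series enforces its invariants", {
  expect_s3_class(channel_series("f", c(0, 1, 2), c(1, 2, 3)),
                  "channel_series")
  expect_error(channel_series("f", c(0, 1), c(1, 2, 3)),
               class = "palpmetrics_schema")
  expect_error(channel_series("f", c(0, 1, 1), c(1, 2, 3)),
               class = "palpmetrics_non_monotone_time")
  expect_error(channel_series("f", c(0, NaN, 2), c(1, 2, 3)),
               class = "palpmetrics_non_monotone_time")
})

test_that("skill classification follows the GRS rules", {
  expect_equal(as.character(classify_skill(7, 7)), "HP")
  expect_equal(as.character(classify_skill(5, 4)), "LP")
  expect_equal(as.character(classify_skill(7, 6)), "MP")
  expect_error(classify_skill(0, 5), class = "palpmetrics_range")
  expect_error(classify_skill(3, 8), class = "palpmetrics_range")
})

test_that("skill classification partitions the full 7 x 7 score grid", {
  grid <- expand.grid(p = 1:7, o = 1:7)
  g <- classify_skill(grid$p, grid$o)
  expect_false(anyNA(g))
  expect_equal(sum(g == "HP"), 1L)                    # only (7,7)
  expect_equal(sum(g == "LP"), 5L * 4L)               # p <= 5, o <= 4
  expect_equal(sum(table(g)), 49L)
})

test_that("trial bundles round-trip through the on-disk format", {
  t <- seq(0, 2, by = 0.013)
  b <- make_bundle(t, force_index = sin(t) + 1, finger_x = 17.25 * t,
                   stb = 1L, manual_window = c(0.5, 1.5))
  b$extra <- list(session = "morning", rig = 3L)
  dir <- withr::local_tempdir()
  write_trial_bundle(b, dir)
  b2 <- read_trial_bundle(dir)
  expect_identical(b2$trial_id, b$trial_id)
  expect_identical(b2$fistula_id, b$fistula_id)
  expect_identical(b2$stb, b$stb)
  expect_equal(b2$manual_window, b$manual_window)
  expect_identical(b2$extra$session, "morning")       # unknown keys preserved
  for (nm in required_channels()) {
    expect_identical(b2$channels[[nm]]$t, b$channels[[nm]]$t)
    expect_identical(b2$channels[[nm]]$v, b$channels[[nm]]$v)
  }
})

test_that("a bundle lacking a required channel file fails to read", {
  t <- seq(0, 1, by = 0.01)
  b <- make_bundle(t)
  dir <- withr::local_tempdir()
  write_trial_bundle(b, dir)
  file.remove(file.path(dir, "force_thumb.csv"))
  expect_error(read_trial_bundle(dir), class = "palpmetrics_missing_channel")
})

test_that("cohorts round-trip through the directory format", {
  t <- seq(0, 1, by = 0.01)
  bs <- list(a = make_bundle(t), b = make_bundle(t))
  bs$a$trial_id <- "a"; bs$b$trial_id <- "b"
  dir <- withr::local_tempdir()
  write_cohort(bs, dir)
  back <- read_cohort(dir)
  expect_named(back, c("a", "b"))
  expect_identical(back$a$channels$finger_x$v, bs$a$channels$finger_x$v)
})

test_that("resampling is the identity on channels already on the grid", {
  t <- seq(0, 2, by = 0.01)
  b <- make_bundle(t, force_index = sin(t))
  r <- resample_to_grid(b, 100)
  expect_identical(r$channels$force_index$v, b$channels$force_index$v)
})

test_that("resampling interpolates linearly between samples", {
  chans <- list()
  for (nm in required_channels())
    chans[[nm]] <- channel_series(nm, c(0, 1), c(0, 10))
  b <- trial_bundle("t", "s", 1, "thin", "low", 4, 3, 0, chans)
  r <- resample_to_grid(b, 2, gap_max = 2)      # grid 0, 0.5, 1
  expect_equal(r$channels$force_index$v[2], 5.0)
})

test_that("resampled sine stays within the linear-interpolation bound", {
  set.seed(7)
  t <- sort(runif(400, 0, 4))
  t <- t[c(TRUE, diff(t) > 1e-4)]
  h_max <- max(diff(t))
  chans <- list()
  for (nm in required_channels())
    chans[[nm]] <- channel_series(nm, t, sin(2 * pi * t))
  b <- trial_bundle("t", "s", 1, "thin", "low", 4, 3, 0, chans)
  r <- resample_to_grid(b, 100, gap_max = 1)
  grid <- r$channels$force_index$t
  err <- abs(r$channels$force_index$v - sin(2 * pi * grid))
  expect_lt(max(err), h_max^2 * (2 * pi)^2 / 8)
})

test_that("resampling is idempotent at a fixed rate", {
  set.seed(8)
  t <- sort(runif(300, 0, 3))
  b <- make_bundle(seq(0, 3, by = 0.01))
  b$channels$force_index <- channel_series("force_index", t, cumsum(rnorm(length(t))))
  r1 <- resample_to_grid(b, 100)
  r2 <- resample_to_grid(r1, 100)
  for (nm in required_channels())
    expect_identical(r2$channels[[nm]]$v, r1$channels[[nm]]$v)
})

test_that("gaps longer than gap_max become missing, not interpolated", {
  t <- c(seq(0, 1, by = 0.01), seq(1.5, 2.5, by = 0.01))
  b <- make_bundle(seq(0, 2.5, by = 0.01))
  b$channels$finger_x <- channel_series("finger_x", t, rep(1, length(t)))
  r <- resample_to_grid(b, 100, gap_max = 0.1)
  v <- r$channels$finger_x$v
  tt <- r$channels$finger_x$t
  expect_true(all(is.na(v[tt > 1.01 & tt < 1.49])))
  expect_true(all(!is.na(v[tt <= 1.0 | tt >= 1.5])))
})

test_that("flashback resamples by previous-value hold", {
  t50 <- seq(0, 2, by = 0.02)
  b <- make_bundle(seq(0, 2, by = 0.01))
  b$channels$flashback <- channel_series("flashback", t50,
                                         as.numeric(t50 >= 1))
  r <- resample_to_grid(b, 100)
  v <- r$channels$flashback$v
  tt <- r$channels$flashback$t
  expect_true(all(v %in% c(0, 1)))
  expect_equal(v[tt == 0.99], 0)
  expect_equal(v[tt == 1.00], 1)
})

test_that("non-overlapping channel time ranges are rejected", {
  chans <- list()
  for (nm in required_channels())
    chans[[nm]] <- channel_series(nm, c(0, 1), c(0, 0))
  chans$finger_x <- channel_series("finger_x", c(5, 6), c(0, 0))
  expect_error(
    trial_bundle("t", "s", 1, "thin", "low", 4, 3, 0, chans),
    class = "palpmetrics_empty_overlap")
})
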