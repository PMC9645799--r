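test_that("Mann-Whitney U and p behave on canonical cases", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)                      # 1 of C(6,3)=20 per tail
  expect_equal(r$method, "exact")

  same <- mann_whitney_u(1:6, 1:6)
  expect_equal(same$U, 18)                    # n1*n2/2
  expect_gt(same$p, 0.9)

  expect_error(mann_whitney_u(numeric(0), 1:3),
               class = "palpmetrics_empty_sample")
})

test_that("exact p matches exhaustive enumeration for small samples", {
  set.seed(21)
  for (rep in 1:12) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(100, n1 + n2)                 # tie-free
    a <- x[seq_len(n1)]; b <- x[-seq_len(n1)]
    r <- mann_whitney_u(a, b)
    expect_equal(r$p, enum_mw_p(a, b), tolerance = 1e-12)
  }
})

test_that("the normal approximation tracks a permutation oracle", {
  set.seed(31)
  a <- rnorm(30, 0.3); b <- rnorm(30)
  r <- mann_whitney_u(a, b)
  expect_equal(r$method, "normal")
  pooled <- c(a, b)
  us <- replicate(40000, {
    idx <- sample(60, 30)
    sum(rank(pooled)[idx]) - 30 * 31 / 2
  })
  mid <- 30 * 30 / 2
  p_perm <- min(1, 2 * min(mean(us <= r$U), mean(us >= r$U)))
  expect_lt(abs(r$p - p_perm), 0.01)
})

test_that("the p-value is invariant under monotone transforms", {
  set.seed(41)
  a <- rlnorm(20); b <- rlnorm(25, 0.4)
  p1 <- mann_whitney_u(a, b)$p
  p2 <- mann_whitney_u(log(a), log(b))$p
  p3 <- mann_whitney_u(a^3, b^3)$p
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("Wilson intervals respect boundaries and the closed form", {
  z0 <- success_probability_ci(0, 10)
  expect_equal(z0$p_hat, 0)
  expect_equal(z0$lo, 0)
  z1 <- success_probability_ci(10, 10)
  expect_equal(z1$p_hat, 1)
  expect_equal(z1$hi, 1)

  ci <- success_probability_ci(84, 153)
  expect_equal(c(ci$lo, ci$hi), wilson_direct(84, 153), tolerance = 1e-12)
  # cross-check against the score interval in stats::prop.test
  pt <- prop.test(84, 153, correct = FALSE)
  expect_equal(c(ci$lo, ci$hi), as.numeric(pt$conf.int), tolerance = 1e-9)

  expect_error(success_probability_ci(1, 0), class = "palpmetrics_zero_trials")
})

test_that("Wilson interval width shrinks with n at fixed proportion", {
  w <- vapply(c(20, 80, 320), function(n) {
    ci <- success_probability_ci(round(0.3 * n), n)
    ci$hi - ci$lo
  }, 0)
  expect_true(all(diff(w) < 0))
})

test_that("logistic fits recover a null and a known slope", {
  set.seed(51)
  x <- rnorm(2000)
  y0 <- rbinom(2000, 1, 0.5)
  f0 <- fit_univariate_logistic(x, y0)
  expect_lt(abs(f0$slope), 3 * f0$se_slope)

  x1 <- runif(2000, -4, 8)
  y1 <- rbinom(2000, 1, plogis(-1 + 0.5 * x1))
  f1 <- fit_univariate_logistic(x1, y1)
  expect_true(f1$converged)
  expect_lt(abs(f1$slope - 0.5), 1.96 * f1$se_slope)
  # the IRLS optimum dominates a dense likelihood grid
  gmax <- grid_loglik_max(x1, y1, c(-2, 0), c(0.2, 0.8))
  expect_gte(f1$loglik, gmax)
})

test_that("perfect separation is flagged without coefficients", {
  x <- c(1, 2, 3, 4, 10, 11, 12, 13)
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  f <- fit_univariate_logistic(x, y)
  expect_true(f$separation)
  expect_true(is.na(f$slope))
  expect_error(fit_univariate_logistic(1:10, rep(1, 10)),
               class = "palpmetrics_single_class")
})

test_that("Hill fits recover known parameters and stay monotone", {
  set.seed(61)
  n <- 5000
  x <- runif(n, 0, 30)
  p_true <- 0.2 + (0.9 - 0.2) * x^2 / (10^2 + x^2)
  y <- rbinom(n, 1, p_true)
  hc <- fit_hill_curve(x, y, direction = "increasing")
  expect_lt(abs(hc$p_min - 0.2) / 0.2, 0.15)
  expect_lt(abs(hc$p_max - 0.9) / 0.9, 0.15)
  expect_lt(abs(hc$k - 10) / 10, 0.15)
  expect_lt(abs(hc$h - 2) / 2, 0.15)
  grid <- seq(0, 30, length.out = 400)
  pred <- predict(hc, grid)
  expect_true(all(diff(pred) >= -1e-12))
  expect_true(all(pred >= 0 & pred <= 1))
})

test_that("flat responses are refused rather than fitted", {
  set.seed(71)
  x <- runif(500, 0, 10)
  y <- rbinom(500, 1, 0.5)
  expect_error(fit_hill_curve(x, y), class = "palpmetrics_not_significant")
  y1 <- rep(c(0, 1), 250)
  expect_error(fit_hill_curve(sort(x), y1, require_significant = FALSE),
               class = "palpmetrics_fit_failure")
})

test_that("reports have the three pairwise rows per metric", {
  set.seed(81)
  mk_rows <- function(g, n, mu) data.frame(
    trial_id = paste0(g, seq_len(n)), subject_id = g, fistula_id = 1,
    skin = "thin", vibration = "low", group = g,
    stb = rbinom(n, 1, 0.7), T_start = 1, T_end = 11,
    seg_method = "auto", seg_status = "ok",
    touchpoints = rpois(n, mu), frequency = rnorm(n, 1.3, 0.1),
    total_force = rlnorm(n), force_range = rlnorm(n, -0.3, 0.2),
    dwell_time = rlnorm(n, 1.6, 0.2), idle_time = rlnorm(n, 1.7, 0.2),
    path_length = rlnorm(n, 7, 0.3), rcm = runif(n, 40, 90),
    rntp = runif(n, 0, 50), mean_tpt = rlnorm(n, -1, 0.2),
    mean_tpf = rlnorm(n, -1.2, 0.2), mean_tpd = rlnorm(n, 4.3, 0.3),
    location_valid = TRUE)
  metrics <- rbind(mk_rows("LP", 30, 20), mk_rows("MP", 30, 15),
                   mk_rows("HP", 30, 13))
  rep <- build_reports(metrics)
  expect_equal(nrow(rep$table1), 12L * 3L)
  expect_setequal(unique(rep$table1$metric), metric_names("all"))
  expect_equal(nrow(rep$table2), 3L * 7L)
  expect_equal(rep$success$group, c("LP", "MP", "HP"))

  # an empty group is marked not-computable, others intact
  rep2 <- build_reports(metrics[metrics$group != "LP", ])
  t1 <- rep2$table1
  expect_true(all(t1$star[t1$group_1 == "LP"] == "not_computable"))
  expect_true(all(t1$star[t1$group_1 == "MP"] != "not_computable"))
})

test_that("report files are byte-identical across reruns", {
  set.seed(91)
  lay <- default_layout()
  coh <- generate_cohort(n_subjects = c(LP = 2, MP = 2, HP = 2),
                         trials_per_subject = 4, seed = 5)
  metrics <- compute_cohort_metrics(coh$bundles, lay)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  build_reports(metrics, out_dir = d1)
  build_reports(metrics, out_dir = d2)
  for (f in c("table1.csv", "success.csv", "table2.csv", "hill_curves.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})
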