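# Group comparisons, success probabilities, and outcome models.
#
# Skill-group contrasts use two-sided Mann-Whitney tests on trial-level
# metric values (raw p-values, starred at 0.05 / 0.01 / 0.001, no
# multiple-testing correction). Cannulation success per group is a
# binomial proportion with a Wilson score interval. The link between a
# metric and the stable-flashback outcome is a stratified univariate
# logistic model; significant metrics are additionally summarised by a
# monotone Hill curve fitted to decile-binned empirical success rates.

#' Names of the twelve per-trial metrics
#'
#' @param which `"all"`, `"location"` (the four metrics requiring complete
#'   position data), or `"force_models"` (the seven metrics entering the
#'   stratified univariate logistic outcome models).
#' @return Character vector of metric column names.
#' @export
metric_names <- function(which = "all") {
  switch(which,
    all = c("idle_time", "dwell_time", "path_length", "rcm", "rntp",
            "mean_tpd", "touchpoints", "total_force", "force_range",
            "frequency", "mean_tpt", "mean_tpf"),
    location = c("path_length", "rcm", "rntp", "mean_tpd"),
    force_models = c("idle_time", "dwell_time", "mean_tpt", "touchpoints",
                     "total_force", "force_range", "frequency"),
    stop_palp("schema", "unknown metric set '%s'", which))
}

significance_star <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' Two-sided Mann-Whitney U test
#'
#' U is the number of pairs (a_i, b_j) with a_i > b_j (ties counted 1/2).
#' The p-value uses the exact rank distribution when both samples have at
#' most 8 observations and there are no ties, and otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric samples.
#' @return List with `U` (for sample `a`), `p` (two-sided), `n_a`, `n_b`,
#'   and `method` (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b))
    stop_palp("empty_sample", "both samples must be non-empty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && na <= 8L && nb <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(U = unname(U), p = wt$p.value, n_a = na, n_b = nb,
       method = if (use_exact) "exact" else "normal")
}

#' Binomial success probability with Wilson score interval
#'
#' @param k Number of successes.
#' @param n Number of trials (must be at least 1).
#' @param conf Confidence level (default 0.95).
#' @return List with `k`, `n`, `p_hat`, `lo`, `hi`.
#' @export
success_probability_ci <- function(k, n, conf = 0.95) {
  if (!is_scalar_number(n) || n < 1)
    stop_palp("zero_trials", "n must be at least 1")
  if (!is_scalar_number(k) || k < 0 || k > n)
    stop_palp("schema", "k must be in 0..n")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  list(k = k, n = n, p_hat = p,
       lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Univariate logistic outcome model
#'
#' Maximum-likelihood fit of `logit p(stb = 1) = intercept + slope * x` by
#' iteratively reweighted least squares, with a Wald test for the slope.
#' Complete separation (one class entirely above the other on `x`) is
#' detected up front; separated fits are flagged and report no
#' coefficients, since the maximum-likelihood estimate diverges.
#'
#' @param x Numeric metric values.
#' @param y Binary outcomes (0/1).
#' @return List with `intercept`, `slope`, `se_slope`, `p` (Wald, slope),
#'   `loglik`, `n`, `converged`, `separation`.
#' @export
fit_univariate_logistic <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (!all(y %in% c(0, 1)))
    stop_palp("schema", "y must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop_palp("single_class", "y is constant; cannot fit outcome model")
  if (max(x[y == 0]) < min(x[y == 1]) || max(x[y == 1]) < min(x[y == 0])) {
    return(list(intercept = NA_real_, slope = NA_real_, se_slope = NA_real_,
                p = NA_real_, loglik = NA_real_, n = length(y),
                converged = FALSE, separation = TRUE))
  }
  fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  co <- summary(fit)$coefficients
  list(intercept = unname(co[1, 1]), slope = unname(co[2, 1]),
       se_slope = unname(co[2, 2]), p = unname(co[2, 4]),
       loglik = as.numeric(stats::logLik(fit)), n = length(y),
       converged = isTRUE(fit$converged), separation = FALSE)
}

hill_value <- function(x, p_min, p_max, k, h, direction) {
  s <- x^h / (k^h + x^h)
  if (direction == "decreasing") s <- 1 - s
  p_min + (p_max - p_min) * s
}

#' Fit a monotone Hill curve relating a metric to success probability
#'
#' Success rates are computed in deciles of `x` and a four-parameter Hill
#' function `p(x) = p_min + (p_max - p_min) * x^h / (k^h + x^h)` (mirrored
#' for a decreasing relationship) is fitted by count-weighted least
#' squares under box constraints: `0 <= p_min <= p_max <= 1`, `h > 0`, `k`
#' within the data range. The fitted curve is monotone by construction.
#'
#' @param x Nonnegative metric values.
#' @param y Binary outcomes (0/1).
#' @param direction `"auto"` (sign of the logistic slope), `"increasing"`
#'   or `"decreasing"`.
#' @param require_significant When `TRUE` (default), refuse to fit unless
#'   the univariate logistic slope is significant at 0.05.
#' @param n_bins Number of quantile bins (default 10).
#' @return Object of class `hill_curve`: `direction`, `p_min`, `p_max`,
#'   `k`, `h`, `sse`, `bins` (the binned rates used for fitting).
#' @export
fit_hill_curve <- function(x, y, direction = "auto",
                           require_significant = TRUE, n_bins = 10) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (any(x < 0)) stop_palp("schema", "Hill fits require nonnegative x")
  lf <- fit_univariate_logistic(x, y)
  if (require_significant && (is.na(lf$p) || lf$p >= 0.05))
    stop_palp("not_significant",
              "logistic slope not significant (p = %.3g)", lf$p %||% NA)
  if (direction == "auto")
    direction <- if (!is.na(lf$slope) && lf$slope < 0) "decreasing" else "increasing"
  brk <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(brk) < 3L)
    stop_palp("fit_failure", "too few distinct x values to bin")
  bin <- cut(x, brk, include.lowest = TRUE)
  xb <- tapply(x, bin, stats::median)
  pb <- tapply(y, bin, mean)
  nb <- tapply(y, bin, length)
  ok <- !is.na(xb)
  xb <- xb[ok]; pb <- pb[ok]; nb <- nb[ok]
  if (stats::sd(pb) < 1e-9)
    stop_palp("fit_failure", "constant success rate; Hill parameters unidentifiable")

  obj <- function(par) {
    p_min <- par[1]; p_max <- par[2]; k <- par[3]; h <- par[4]
    if (p_min > p_max) return(1e6 + (p_min - p_max) * 1e6)
    pr <- hill_value(xb, p_min, p_max, k, h, direction)
    sum(nb * (pb - pr)^2)
  }
  lo <- c(0, 0, max(min(x), 1e-9), 0.1)
  hi <- c(1, 1, max(x), 10)
  starts <- list(
    c(max(0, min(pb)), min(1, max(pb)), stats::median(x), 1),
    c(max(0, min(pb)), min(1, max(pb)), stats::median(x), 2),
    c(0.1, 0.9, unname(stats::quantile(x, 0.3)), 0.5))
  best <- NULL
  for (st in starts) {
    st <- pmin(pmax(st, lo), hi)
    res <- tryCatch(
      stats::optim(st, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    stop_palp("fit_failure", "Hill-curve optimisation did not converge")
  structure(list(direction = direction,
                 p_min = best$par[1], p_max = best$par[2],
                 k = best$par[3], h = best$par[4],
                 sse = best$value,
                 logistic = lf,
                 bins = data.frame(x = as.numeric(xb), rate = as.numeric(pb),
                                   n = as.numeric(nb))),
            class = "hill_curve")
}

#' Evaluate a fitted Hill curve
#'
#' @param object A `hill_curve`.
#' @param newdata Numeric vector of metric values.
#' @param ... Unused.
#' @return Predicted success probabilities.
#' @export
predict.hill_curve <- function(object, newdata, ...) {
  hill_value(newdata, object$p_min, object$p_max, object$k, object$h,
             object$direction)
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf(
    "<hill curve (%s): p_min=%.3f p_max=%.3f k=%.3g h=%.3g>\n",
    x$direction, x$p_min, x$p_max, x$k, x$h))
  invisible(x)
}

group_pairs <- function() list(c("LP", "HP"), c("LP", "MP"), c("MP", "HP"))

#' Build the group-comparison and outcome-model reports
#'
#' For every metric, the three pairwise skill-group comparisons (LP-HP,
#' LP-MP, MP-HP) with group means, medians, U statistics, raw p-values and
#' significance stars; per-group success estimates with Wilson intervals;
#' per-stratum univariate logistic fits for the seven force-model metrics;
#' and Hill curves for the significant stratum/metric combinations.
#' Location metrics only use trials with complete position data
#' (`location_valid`). Row and column order is deterministic, and when
#' `out_dir` is given the files `table1.csv`, `success.csv`, `table2.csv`
#' and `hill_curves.json` are (re)written byte-identically for identical
#' inputs.
#'
#' @param metrics Data frame from [compute_cohort_metrics()].
#' @param out_dir Optional output directory.
#' @param by_subject When `TRUE`, group comparisons use per-subject metric
#'   medians instead of pooled trials (a sensitivity mode; the default
#'   pools trials, ignoring within-subject clustering).
#' @return List with `table1`, `success`, `table2`, `hill` (named list of
#'   `hill_curve` objects or `NULL` entries).
#' @export
build_reports <- function(metrics, out_dir = NULL, by_subject = FALSE) {
  ok <- metrics[!is.na(metrics$seg_status) & metrics$seg_status == "ok", ,
                drop = FALSE]
  loc_names <- metric_names("location")
  all_names <- intersect(metric_names("all"), names(ok))

  rows <- list()
  for (mname in all_names) {
    dat <- ok
    if (mname %in% loc_names)
      dat <- dat[!is.na(dat$location_valid) & dat$location_valid, ,
                 drop = FALSE]
    if (by_subject) {
      agg <- stats::aggregate(dat[[mname]],
                              by = list(subject_id = dat$subject_id,
                                        group = dat$group),
                              FUN = stats::median, na.rm = TRUE)
      dat <- data.frame(group = agg$group)
      dat[[mname]] <- agg$x
    }
    for (pair in group_pairs()) {
      g1 <- dat[[mname]][dat$group == pair[1]]
      g2 <- dat[[mname]][dat$group == pair[2]]
      g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
      if (length(g1) && length(g2)) {
        mw <- mann_whitney_u(g1, g2)
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mname, group_1 = pair[1], group_2 = pair[2],
          n_1 = length(g1), n_2 = length(g2),
          mean_1 = mean(g1), mean_2 = mean(g2),
          median_1 = stats::median(g1), median_2 = stats::median(g2),
          U = mw$U, p = mw$p, star = significance_star(mw$p))
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          metric = mname, group_1 = pair[1], group_2 = pair[2],
          n_1 = length(g1), n_2 = length(g2),
          mean_1 = NA_real_, mean_2 = NA_real_,
          median_1 = NA_real_, median_2 = NA_real_,
          U = NA_real_, p = NA_real_, star = "not_computable")
      }
    }
  }
  table1 <- do.call(rbind, rows)
  rownames(table1) <- NULL

  succ <- lapply(c("LP", "MP", "HP"), function(g) {
    d <- metrics[metrics$group == g, , drop = FALSE]
    if (!nrow(d)) return(data.frame(group = g, n = 0L, k = 0L,
                                    p_hat = NA_real_, lo = NA_real_,
                                    hi = NA_real_))
    ci <- success_probability_ci(sum(d$stb), nrow(d))
    data.frame(group = g, n = ci$n, k = ci$k, p_hat = ci$p_hat,
               lo = ci$lo, hi = ci$hi)
  })
  success <- do.call(rbind, succ)

  t2rows <- list(); hill <- list()
  for (g in c("LP", "MP", "HP")) {
    d <- ok[ok$group == g, , drop = FALSE]
    for (mname in metric_names("force_models")) {
      x <- d[[mname]]; y <- d$stb
      keep <- !is.na(x)
      row <- data.frame(stratum = g, metric = mname,
                        n = sum(keep), intercept = NA_real_,
                        slope = NA_real_, p = NA_real_,
                        star = "not_computable",
                        converged = FALSE, separation = FALSE)
      if (sum(keep) >= 10 && length(unique(y[keep])) == 2L) {
        lf <- fit_univariate_logistic(x[keep], y[keep])
        row$intercept <- lf$intercept; row$slope <- lf$slope
        row$p <- lf$p
        row$star <- if (lf$separation) "separation" else
          significance_star(lf$p)
        row$converged <- lf$converged; row$separation <- lf$separation
        if (!lf$separation && !is.na(lf$p) && lf$p < 0.05) {
          hc <- tryCatch(fit_hill_curve(x[keep], y[keep]),
                         palpmetrics_error = function(e) NULL)
          hill[[paste(g, mname, sep = ".")]] <- hc
        }
      }
      t2rows[[length(t2rows) + 1L]] <- row
    }
  }
  table2 <- do.call(rbind, t2rows)
  rownames(table2) <- NULL

  out <- list(table1 = table1, success = success, table2 = table2,
              hill = hill)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(table1, file.path(out_dir, "table1.csv"),
                     row.names = FALSE)
    utils::write.csv(success, file.path(out_dir, "success.csv"),
                     row.names = FALSE)
    utils::write.csv(table2, file.path(out_dir, "table2.csv"),
                     row.names = FALSE)
    hill_json <- lapply(hill, function(hc) {
      if (is.null(hc)) return(NULL)
      list(direction = hc$direction, p_min = hc$p_min, p_max = hc$p_max,
           k = hc$k, h = hc$h, sse = hc$sse)
    })
    write_json_file(hill_json, file.path(out_dir, "hill_curves.json"))
  }
  out
}
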