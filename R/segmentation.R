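# Isolating the palpation window [T_start, T_end] from a trial.
#
# Palpation starts when force is first applied to the index or middle
# finger after a period of no change in force (the subject begins to feel
# for the fistula), and ends when the thumb force changes in conjunction
# with a movement of the needle (the subject grips the needle for
# insertion). Trials where no qualifying start or end exists get an
# explicit non-ok status and are excluded from metrics; a manual window
# from video review, when present in the bundle, takes precedence.

#' Segmentation configuration
#'
#' Numeric thresholds operationalizing the window-detection rules. The
#' defaults are scaled to fingertip-force sensor noise (about 0.02 N per
#' sample) and needle jitter.
#'
#' @param quiescence_window Seconds of "no change in force" that must
#'   precede the start of palpation (default 1.0).
#' @param start_force_delta Rise in index or middle force (N) that marks
#'   the start (default 0.10); "no change" means peak-to-peak variation
#'   below this over the quiescence window.
#' @param thumb_force_delta Change in thumb force (N) that, together with
#'   needle movement, marks the end (default 0.15).
#' @param needle_disp_threshold Needle-tip displacement (mm) that must
#'   coincide with the thumb-force change (default 5).
#' @param coincidence_window Window (s) within which the thumb change and
#'   needle movement must co-occur (default 0.5).
#' @param smoothing_window Width (s) of the centered moving average applied
#'   to force channels before thresholding (default 0.05).
#' @return Object of class `segmentation_config`.
#' @export
segmentation_config <- function(quiescence_window = 1.0,
                                start_force_delta = 0.10,
                                thumb_force_delta = 0.15,
                                needle_disp_threshold = 5.0,
                                coincidence_window = 0.5,
                                smoothing_window = 0.05) {
  cfg <- list(quiescence_window = quiescence_window,
              start_force_delta = start_force_delta,
              thumb_force_delta = thumb_force_delta,
              needle_disp_threshold = needle_disp_threshold,
              coincidence_window = coincidence_window,
              smoothing_window = smoothing_window)
  for (nm in names(cfg))
    if (!is_scalar_number(cfg[[nm]]) || cfg[[nm]] <= 0)
      stop_palp("schema", "segmentation config '%s' must be positive", nm)
  structure(cfg, class = "segmentation_config")
}

palpation_window <- function(T_start, T_end, method, status) {
  structure(list(T_start = T_start, T_end = T_end,
                 method = method, status = status),
            class = "palpation_window")
}

#' @export
print.palpation_window <- function(x, ...) {
  cat(sprintf("<palpation window: status=%s method=%s [%.3f, %.3f] s>\n",
              x$status, x$method,
              x$T_start %||% NA_real_, x$T_end %||% NA_real_))
  invisible(x)
}

#' Detect the palpation window of a trial
#'
#' `T_start` is the first time at which the smoothed index or middle force
#' rises by at least `start_force_delta` above its quiescent level, after
#' at least `quiescence_window` seconds during which both channels varied
#' by less than that delta. `T_end` is the first time after `T_start` at
#' which the thumb force changes by at least `thumb_force_delta` while the
#' needle tip displaces by at least `needle_disp_threshold` mm within the
#' same trailing `coincidence_window`. If the bundle carries a manual
#' window it is returned as-is with `method = "manual"`. Trials with no
#' qualifying start (or end) return status `"no_start"` (`"no_end"`).
#'
#' @param bundle A resampled [trial_bundle()].
#' @param cfg A [segmentation_config()].
#' @return A `palpation_window` with fields `T_start`, `T_end`, `method`
#'   (`auto`/`manual`) and `status` (`ok`, `no_start`, `no_end`).
#' @export
detect_palpation_window <- function(bundle, cfg = segmentation_config()) {
  if (!is.null(bundle$manual_window)) {
    return(palpation_window(bundle$manual_window[1], bundle$manual_window[2],
                            "manual", "ok"))
  }
  if (is.null(bundle$rate))
    stop_palp("not_resampled", "bundle must be resampled to a uniform grid")
  for (nm in c("force_thumb", "force_index", "force_middle",
               "needle_x", "needle_y", "needle_z"))
    if (is.null(bundle$channels[[nm]]))
      stop_palp("missing_channel", "channel '%s' required for segmentation", nm)

  h <- 1 / bundle$rate
  tt <- ch(bundle, "force_index")$t
  n <- length(tt)
  ksm <- max(1L, round(cfg$smoothing_window / h))
  f_ind <- moving_average(ch(bundle, "force_index")$v, ksm)
  f_mid <- moving_average(ch(bundle, "force_middle")$v, ksm)
  f_th  <- moving_average(ch(bundle, "force_thumb")$v, ksm)

  kq <- max(2L, round(cfg$quiescence_window / h))
  rng_ind <- rolling_range_trailing(f_ind, kq)
  rng_mid <- rolling_range_trailing(f_mid, kq)
  # a frame is "quiescent" when its trailing window is fully observed and
  # both palpating-finger channels varied by less than the start delta
  quiet <- seq_len(n) >= kq &
    !is.na(rng_ind) & !is.na(rng_mid) &
    rng_ind < cfg$start_force_delta & rng_mid < cfg$start_force_delta

  # --- T_start ---------------------------------------------------------
  # level = channel mean over the most recent quiescent window; start =
  # first frame whose force exceeds that level by >= start_force_delta
  cs_ind <- c(0, cumsum(ifelse(is.na(f_ind), 0, f_ind)))
  cs_mid <- c(0, cumsum(ifelse(is.na(f_mid), 0, f_mid)))
  lev_ind <- rep(NA_real_, n); lev_mid <- rep(NA_real_, n)
  i_full <- seq.int(kq, n)
  lev_ind[i_full] <- (cs_ind[i_full + 1L] - cs_ind[i_full - kq + 1L]) / kq
  lev_mid[i_full] <- (cs_mid[i_full + 1L] - cs_mid[i_full - kq + 1L]) / kq
  last_quiet <- cummax(ifelse(quiet, seq_len(n), 0L))
  has_q <- last_quiet > 0L
  lq <- pmax(last_quiet, 1L)
  fire <- has_q &
    ((!is.na(f_ind) & f_ind - lev_ind[lq] >= cfg$start_force_delta) |
     (!is.na(f_mid) & f_mid - lev_mid[lq] >= cfg$start_force_delta))
  idx_start <- if (any(fire, na.rm = TRUE)) which(fire)[1L] else NA_integer_
  if (is.na(idx_start))
    return(palpation_window(NA_real_, NA_real_, "auto", "no_start"))
  T_start <- tt[idx_start]

  # --- T_end -----------------------------------------------------------
  kc <- max(2L, round(cfg$coincidence_window / h))
  th_rng <- rolling_range_trailing(f_th, kc)
  # needle displacement across the trailing coincidence window
  nx <- ch(bundle, "needle_x")$v
  ny <- ch(bundle, "needle_y")$v
  nz <- ch(bundle, "needle_z")$v
  lag <- function(x) c(rep(NA_real_, kc - 1L), x[seq_len(n - kc + 1L)])
  disp <- sqrt((nx - lag(nx))^2 + (ny - lag(ny))^2 + (nz - lag(nz))^2)
  ok_end <- which(seq_len(n) > idx_start &
                    !is.na(th_rng) & th_rng >= cfg$thumb_force_delta &
                    !is.na(disp) & disp >= cfg$needle_disp_threshold)
  if (!length(ok_end))
    return(palpation_window(T_start, NA_real_, "auto", "no_end"))
  palpation_window(T_start, tt[ok_end[1L]], "auto", "ok")
}
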