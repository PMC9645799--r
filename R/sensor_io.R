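# Trial-bundle data model and on-disk format.
#
# A trial bundle holds one palpation trial's synchronized sensor channels
# (three fingertip forces in N, fingertip and needle-tip positions in mm in
# the simulator-bed frame, a binary flashback line) together with trial
# metadata: subject, fistula (1-4), skin thickness, vibration intensity,
# expert GRS scores, and the stable-flashback outcome flag `stb`.
# Timestamps are seconds from trial start; the bed plane (x, y) with origin
# at the bed centre is the canonical plane for all location metrics.

#' Required sensor channels of a complete trial
#'
#' @return Character vector of the ten channel names every complete trial
#'   bundle carries.
#' @export
required_channels <- function() {
  c("force_thumb", "force_index", "force_middle",
    "finger_x", "finger_y", "finger_z",
    "needle_x", "needle_y", "needle_z",
    "flashback")
}

#' Construct a single sensor channel
#'
#' A channel is one time series from one sensor: time in seconds (strictly
#' increasing, no NaN) and values (N for forces, mm for positions, 0/1 for
#' the flashback line). Missing samples are encoded as `NA` values.
#'
#' @param name Channel name (see [required_channels()]).
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param v Numeric vector of values, same length as `t`.
#' @return An object of class `channel_series`.
#' @export
channel_series <- function(name, t, v) {
  t <- as.numeric(t)
  v <- as.numeric(v)
  if (length(t) != length(v))
    stop_palp("schema", "channel '%s': t and v lengths differ (%d vs %d)",
              name, length(t), length(v))
  if (anyNA(t))
    stop_palp("non_monotone_time", "channel '%s': NA/NaN in timestamps", name)
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_palp("non_monotone_time",
              "channel '%s': timestamps not strictly increasing", name)
  structure(list(name = name, t = t, v = v), class = "channel_series")
}

#' @export
print.channel_series <- function(x, ...) {
  cat(sprintf("<channel %s: %d samples, t in [%.3f, %.3f] s>\n",
              x$name, length(x$t),
              if (length(x$t)) min(x$t) else NA, if (length(x$t)) max(x$t) else NA))
  invisible(x)
}

#' Construct a trial bundle
#'
#' @param trial_id,subject_id Identifier strings.
#' @param fistula_id Integer 1-4, which fistula (and hence which vibration
#'   motor) was active.
#' @param skin `"thin"` or `"thick"` skin layer.
#' @param vibration `"low"` or `"high"` motor intensity.
#' @param grs_palpation,grs_overall Expert global-rating-scale scores, 1-7.
#' @param stb Cannulation outcome flag: 1 when stable flashback (at least
#'   2 s uninterrupted to the end of the trial) was achieved, else 0.
#' @param channels Named list of [channel_series()] objects.
#' @param manual_window Optional numeric `c(T_start, T_end)` from manual
#'   video review, used instead of automatic segmentation when present.
#' @param extra Named list of additional metadata preserved on round-trip.
#' @return An object of class `trial_bundle`. The element `complete` is
#'   `TRUE` when all [required_channels()] are present.
#' @export
trial_bundle <- function(trial_id, subject_id, fistula_id, skin, vibration,
                         grs_palpation, grs_overall, stb, channels,
                         manual_window = NULL, extra = list()) {
  if (!is.list(channels) || is.null(names(channels)))
    stop_palp("schema", "channels must be a named list of channel_series")
  for (nm in names(channels)) {
    if (!inherits(channels[[nm]], "channel_series"))
      stop_palp("schema", "channel '%s' is not a channel_series", nm)
  }
  if (!fistula_id %in% 1:4)
    stop_palp("schema", "fistula_id must be in 1..4, got %s", fistula_id)
  if (!skin %in% c("thin", "thick"))
    stop_palp("schema", "skin must be 'thin' or 'thick'")
  if (!vibration %in% c("low", "high"))
    stop_palp("schema", "vibration must be 'low' or 'high'")
  for (g in c(grs_palpation, grs_overall))
    if (!is_scalar_number(g) || g < 1 || g > 7)
      stop_palp("range", "GRS scores must be in 1..7")
  if (!stb %in% c(0, 1))
    stop_palp("schema", "stb must be 0 or 1")
  if (!is.null(manual_window)) {
    manual_window <- as.numeric(manual_window)
    if (length(manual_window) != 2L || anyNA(manual_window) ||
        manual_window[1] >= manual_window[2])
      stop_palp("schema", "manual_window must be c(T_start, T_end), start < end")
  }
  missing_ch <- setdiff(required_channels(), names(channels))
  # all channel time ranges must overlap on a common interval
  if (length(channels) > 1L) {
    lo <- max(vapply(channels, function(c) min(c$t), 0))
    hi <- min(vapply(channels, function(c) max(c$t), 0))
    if (hi <= lo)
      stop_palp("empty_overlap", "channel time ranges do not intersect")
  }
  structure(list(
    trial_id = as.character(trial_id),
    subject_id = as.character(subject_id),
    fistula_id = as.integer(fistula_id),
    skin = skin, vibration = vibration,
    grs_palpation = as.integer(grs_palpation),
    grs_overall = as.integer(grs_overall),
    stb = as.integer(stb),
    channels = channels,
    manual_window = manual_window,
    complete = length(missing_ch) == 0L,
    missing_channels = missing_ch,
    rate = NULL,          # set by resample_to_grid()
    extra = extra
  ), class = "trial_bundle")
}

#' @export
print.trial_bundle <- function(x, ...) {
  cat(sprintf(
    "<trial %s: subject %s, fistula %d, %s skin, %s vibration, stb=%d>\n",
    x$trial_id, x$subject_id, x$fistula_id, x$skin, x$vibration, x$stb))
  cat(sprintf("  channels: %s\n", paste(names(x$channels), collapse = ", ")))
  if (!is.null(x$rate)) cat(sprintf("  resampled at %g Hz\n", x$rate))
  invisible(x)
}

# Convenience accessor used throughout the metrics code.
ch <- function(bundle, name) {
  s <- bundle$channels[[name]]
  if (is.null(s)) stop_palp("missing_channel", "channel '%s' absent", name)
  s
}

known_metadata_keys <- c(
  "schema_version", "trial_id", "subject_id", "fistula_id", "skin",
  "vibration", "grs_palpation", "grs_overall", "stb", "manual_window")

#' Write a trial bundle to a directory
#'
#' One directory per trial: `metadata.json` plus one `t,v` CSV per channel
#' (RFC 4180, UTF-8, '.' decimal separator). Numeric values are written
#' with 17 significant digits so a read-back is bit-identical.
#'
#' @param bundle A [trial_bundle()].
#' @param path Directory to create/fill.
#' @return `path`, invisibly.
#' @export
write_trial_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- c(list(
    schema_version = 1L,
    trial_id = bundle$trial_id,
    subject_id = bundle$subject_id,
    fistula_id = bundle$fistula_id,
    skin = bundle$skin,
    vibration = bundle$vibration,
    grs_palpation = bundle$grs_palpation,
    grs_overall = bundle$grs_overall,
    stb = bundle$stb,
    manual_window = if (is.null(bundle$manual_window)) NULL else
      I(bundle$manual_window)
  ), bundle$extra)
  write_json_file(meta, file.path(path, "metadata.json"))
  for (nm in names(bundle$channels)) {
    s <- bundle$channels[[nm]]
    con <- file(file.path(path, paste0(nm, ".csv")), "w", encoding = "UTF-8")
    writeLines("t,v", con)
    writeLines(paste(sprintf("%.17g", s$t), sprintf("%.17g", s$v), sep = ","),
               con)
    close(con)
  }
  invisible(path)
}

#' Read a trial bundle from a directory
#'
#' @param path Directory holding `metadata.json` and per-channel CSVs.
#' @return A validated [trial_bundle()].
#' @export
read_trial_bundle <- function(path) {
  meta_path <- file.path(path, "metadata.json")
  if (!file.exists(meta_path))
    stop_palp("schema", "no metadata.json in %s", path)
  meta <- read_json_file(meta_path)
  for (key in c("trial_id", "subject_id", "fistula_id", "skin", "vibration",
                "grs_palpation", "grs_overall", "stb"))
    if (is.null(meta[[key]]))
      stop_palp("schema", "metadata.json missing required key '%s'", key)
  chans <- list()
  for (nm in required_channels()) {
    f <- file.path(path, paste0(nm, ".csv"))
    if (!file.exists(f))
      stop_palp("missing_channel", "required channel file absent: %s", f)
    d <- utils::read.csv(f)
    if (!all(c("t", "v") %in% names(d)))
      stop_palp("schema", "%s lacks t,v header", f)
    chans[[nm]] <- channel_series(nm, d$t, d$v)
  }
  # pick up any non-required channel files too
  extra_files <- setdiff(list.files(path, pattern = "\\.csv$"),
                         paste0(required_channels(), ".csv"))
  for (f in extra_files) {
    nm <- sub("\\.csv$", "", f)
    d <- utils::read.csv(file.path(path, f))
    chans[[nm]] <- channel_series(nm, d$t, d$v)
  }
  extra <- meta[setdiff(names(meta), known_metadata_keys)]
  trial_bundle(
    trial_id = meta$trial_id, subject_id = meta$subject_id,
    fistula_id = meta$fistula_id, skin = meta$skin,
    vibration = meta$vibration,
    grs_palpation = meta$grs_palpation, grs_overall = meta$grs_overall,
    stb = meta$stb, channels = chans,
    manual_window = if (is.null(meta$manual_window)) NULL else
      unlist(meta$manual_window),
    extra = extra)
}

#' Write a cohort of trial bundles
#'
#' @param bundles List of [trial_bundle()] objects.
#' @param dir Cohort directory; one sub-directory per trial plus a
#'   `cohort.json` index.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(bundles, function(b) b$trial_id, "")
  if (anyDuplicated(ids)) stop_palp("schema", "duplicate trial ids in cohort")
  for (b in bundles) write_trial_bundle(b, file.path(dir, b$trial_id))
  write_json_file(list(schema_version = 1L, trials = ids),
                  file.path(dir, "cohort.json"))
  invisible(dir)
}

#' Read a cohort directory
#'
#' @param dir Cohort directory written by [write_cohort()].
#' @return Named list of trial bundles, in index order.
#' @export
read_cohort <- function(dir) {
  idx <- read_json_file(file.path(dir, "cohort.json"))
  out <- lapply(idx$trials, function(id)
    read_trial_bundle(file.path(dir, id)))
  names(out) <- idx$trials
  out
}

#' Resample all channels of a trial onto a common uniform grid
#'
#' The four sensor systems run at heterogeneous rates; all metrics assume a
#' common clock. Channels are linearly interpolated onto a uniform grid
#' spanning the intersection of the channel time ranges. Gaps between
#' consecutive valid samples longer than `gap_max` are marked missing
#' (`NA`) rather than interpolated; the binary flashback channel is
#' resampled by previous-value hold. A channel already on the target grid
#' is returned unchanged, which makes the operation idempotent.
#'
#' @param bundle A [trial_bundle()].
#' @param rate Target rate in Hz (default 100).
#' @param gap_max Longest gap (s) that may be bridged by interpolation.
#' @return A resampled [trial_bundle()] with `rate` set.
#' @export
resample_to_grid <- function(bundle, rate = 100, gap_max = 0.1) {
  if (!is_scalar_number(rate) || rate <= 0)
    stop_palp("schema", "rate must be a positive number")
  for (nm in names(bundle$channels))
    if (length(bundle$channels[[nm]]$t) < 2L)
      stop_palp("schema", "channel '%s' has fewer than 2 samples", nm)
  lo <- max(vapply(bundle$channels, function(c) min(c$t), 0))
  hi <- min(vapply(bundle$channels, function(c) max(c$t), 0))
  if (hi <= lo)
    stop_palp("empty_overlap", "channel time ranges do not intersect")
  h <- 1 / rate
  grid <- seq(lo, hi + 1e-9, by = h)
  grid <- grid[grid <= hi + 1e-9]
  out <- bundle
  for (nm in names(bundle$channels)) {
    s <- bundle$channels[[nm]]
    if (length(s$t) == length(grid) && max(abs(s$t - grid)) < 1e-9) {
      out$channels[[nm]] <- s          # already on the target grid
      next
    }
    keep <- !is.na(s$v)
    tk <- s$t[keep]; vk <- s$v[keep]
    if (length(tk) < 2L)
      stop_palp("schema", "channel '%s' has fewer than 2 valid samples", nm)
    if (nm == "flashback") {
      vi <- stats::approx(tk, vk, xout = grid, method = "constant",
                          f = 0, rule = 2)$y
    } else {
      vi <- stats::approx(tk, vk, xout = grid, method = "linear",
                          rule = 2)$y
      # mark interior gaps longer than gap_max as missing
      gaps <- which(diff(tk) > gap_max)
      for (g in gaps) {
        bad <- grid > tk[g] + 1e-12 & grid < tk[g + 1L] - 1e-12
        vi[bad] <- NA_real_
      }
      # never extrapolate beyond this channel's valid samples
      vi[grid < tk[1L] - 1e-12 | grid > tk[length(tk)] + 1e-12] <- NA_real_
    }
    out$channels[[nm]] <- channel_series(nm, grid, vi)
  }
  out$rate <- rate
  out
}

#' Classify skill group from expert GRS scores
#'
#' High performers (HP) scored 7 in both palpation and overall skill; low
#' performers (LP) scored at most 5 in palpation and at most 4 overall;
#' everyone else is a mid performer (MP).
#'
#' @param grs_palpation,grs_overall Integer scores in 1..7 (vectorized).
#' @return Factor with levels `LP`, `MP`, `HP`.
#' @export
classify_skill <- function(grs_palpation, grs_overall) {
  p <- as.numeric(grs_palpation); o <- as.numeric(grs_overall)
  if (length(p) != length(o))
    stop_palp("schema", "score vectors must have equal length")
  if (anyNA(p) || anyNA(o) || any(p < 1 | p > 7) || any(o < 1 | o > 7))
    stop_palp("range", "GRS scores must be in 1..7")
  g <- ifelse(p == 7 & o == 7, "HP", ifelse(p <= 5 & o <= 4, "LP", "MP"))
  factor(g, levels = c("LP", "MP", "HP"))
}
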