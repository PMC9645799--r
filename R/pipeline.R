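# End-to-end pipeline: simulate -> segment -> metrics -> stats.
#
# Each stage writes its artifact before the next consumes it, a manifest
# records the configuration and seed, and identical configuration plus
# seed reproduces byte-identical artifacts.

#' Default pipeline configuration
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed.
#' @param n_subjects Named per-group subject counts.
#' @param trials_per_subject Trials per subject.
#' @param rate Resampling rate (Hz).
#' @param gap_max Longest interpolatable gap (s).
#' @param seg Segmentation configuration (list of overrides for
#'   [segmentation_config()]).
#' @param peaks Peak configuration (list of overrides for
#'   [peak_config()]).
#' @return Named list, validated by [run_pipeline()].
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            n_subjects = c(LP = 10, MP = 10, HP = 10),
                            trials_per_subject = 16,
                            rate = 100, gap_max = 0.1,
                            seg = list(), peaks = list()) {
  list(out_dir = out_dir, seed = seed, n_subjects = n_subjects,
       trials_per_subject = trials_per_subject, rate = rate,
       gap_max = gap_max, seg = seg, peaks = peaks)
}

validate_pipeline_config <- function(config) {
  for (key in c("out_dir", "seed", "n_subjects", "trials_per_subject",
                "rate", "gap_max"))
    if (is.null(config[[key]]))
      stop_palp("schema", "pipeline config missing '%s'", key)
  if (!all(c("LP", "MP", "HP") %in% names(config$n_subjects)))
    stop_palp("schema", "n_subjects must name LP, MP and HP")
  invisible(config)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates a cohort, writes it in the on-disk format, segments every
#' trial, computes the twelve metrics per trial, and builds the
#' group-comparison and outcome reports. Artifacts: `cohort/` (trial
#' bundles + ground truth), `segments.csv`, `metrics.csv`, `table1.csv`,
#' `success.csv`, `table2.csv`, `hill_curves.json`, `manifest.json`.
#'
#' @param config List from [pipeline_config()].
#' @return The metrics data frame, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- default_layout()
  write_layout(layout, file.path(config$out_dir, "layout.json"))

  coh <- generate_cohort(n_subjects = config$n_subjects,
                         trials_per_subject = config$trials_per_subject,
                         layout = layout, seed = config$seed,
                         dir = file.path(config$out_dir, "cohort"))

  seg_cfg <- do.call(segmentation_config, config$seg)
  peak_cfg <- do.call(peak_config, config$peaks)
  metrics <- compute_cohort_metrics(coh$bundles, layout, seg_cfg, peak_cfg,
                                    rate = config$rate)

  segments <- metrics[, c("trial_id", "T_start", "T_end",
                          "seg_method", "seg_status")]
  utils::write.csv(segments, file.path(config$out_dir, "segments.csv"),
                   row.names = FALSE)
  utils::write.csv(metrics, file.path(config$out_dir, "metrics.csv"),
                   row.names = FALSE)
  build_reports(metrics, out_dir = config$out_dir)

  manifest <- list(
    package = "palpmetrics",
    version = as.character(utils::packageVersion("palpmetrics")),
    seed = config$seed,
    n_subjects = as.list(config$n_subjects),
    trials_per_subject = config$trials_per_subject,
    rate = config$rate, gap_max = config$gap_max,
    seg = unclass(do.call(segmentation_config, config$seg)),
    peaks = unclass(do.call(peak_config, config$peaks)))
  write_json_file(manifest, file.path(config$out_dir, "manifest.json"))
  invisible(metrics)
}
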