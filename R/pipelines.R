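# End-to-end pipelines: video -> displacement -> force -> beat metrics, and
# trace -> dF/F0 -> per-beat features -> ROI summaries. A strict config and a
# run log make every run reproducible and auditable.

config_schema <- list(
  input = "character",
  output_dir = "character",
  pixel_scale_um = "numeric",
  frame_rate_hz = "numeric",
  pacing_rate_hz = "numeric",
  seed = "numeric",
  geometry = c("length_m", "youngs_modulus_pa", "diameter_m"),
  tracking = c("mode", "roi", "axis")
)

#' Build a validated run configuration
#'
#' All physical quantities must be positive; unknown keys are rejected
#' (fail fast — a typo in a config must not silently fall back to a
#' default).
#'
#' @param input Input path (video file/directory, or trace CSV).
#' @param output_dir Output directory for the run (created if missing).
#' @param pixel_scale_um Micrometres per pixel (default 3.79).
#' @param frame_rate_hz Video frame rate, Hz (required for video runs; no
#'   default is assumed because image containers carry no timing metadata).
#' @param pacing_rate_hz Pacing rate, Hz (default 1).
#' @param geometry Named list overriding [pillar_geometry()] arguments.
#' @param tracking Named list: `mode` (`"cumulative"`/`"fixed_reference"`),
#'   optional `roi` (x, y, width, height) and `axis` (x, y).
#' @param seed Integer seed recorded with the run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input = NULL, output_dir = tempfile("pillarbeat_run_"),
                       pixel_scale_um = 3.79, frame_rate_hz = NULL,
                       pacing_rate_hz = 1, geometry = list(),
                       tracking = list(), seed = 1L) {
  cfg <- list(input = input, output_dir = output_dir,
              pixel_scale_um = pixel_scale_um, frame_rate_hz = frame_rate_hz,
              pacing_rate_hz = pacing_rate_hz, geometry = geometry,
              tracking = tracking, seed = seed)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown)) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (blk in c("geometry", "tracking")) {
    bad <- setdiff(names(cfg[[blk]]), config_schema[[blk]])
    if (length(bad)) {
      abort(sprintf("unknown %s key(s): %s", blk, paste(bad, collapse = ", ")))
    }
  }
  for (key in c("pixel_scale_um", "pacing_rate_hz")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0) {
      abort(sprintf("config `%s` must be a single positive number", key))
    }
  }
  if (!is.null(cfg$frame_rate_hz) &&
      (!is.numeric(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0)) {
    abort("config `frame_rate_hz` must be a positive number")
  }
  if (!is.null(cfg$tracking$mode) &&
      !cfg$tracking$mode %in% c("cumulative", "fixed_reference")) {
    abort("tracking mode must be 'cumulative' or 'fixed_reference'")
  }
  geom <- do.call(pillar_geometry, cfg$geometry %||% list())
  cfg$geometry <- cfg$geometry %||% list()
  attr(cfg, "geometry_obj") <- geom
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a run configuration from YAML
#'
#' @param path YAML file; keys as in [run_config()]. Unknown keys are
#'   rejected.
#' @return A validated `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  raw <- yaml::read_yaml(path)
  # YAML 1.1 parses exponents without a sign ("1.7e6") as strings
  raw <- rapply(raw, function(x) {
    if (is.character(x) && length(x) == 1 &&
        grepl("^-?[0-9]+(\\.[0-9]*)?([eE][+-]?[0-9]+)?$", x)) as.numeric(x) else x
  }, how = "replace")
  defaults <- list(pixel_scale_um = 3.79, pacing_rate_hz = 1,
                   geometry = list(), tracking = list(), seed = 1L,
                   output_dir = tempfile("pillarbeat_run_"))
  validate_config(modifyList(defaults, raw))
}

# run-log bookkeeping ---------------------------------------------------------

new_run_log <- function(cfg, pipeline) {
  list(pipeline = pipeline,
       package_version = as.character(utils::packageVersion("pillarbeat")),
       started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       config = cfg[setdiff(names(cfg), character(0))],
       stages = list(), warnings = list(), outputs = character(0))
}

log_stage <- function(log, stage, message) {
  log$stages[[length(log$stages) + 1L]] <-
    list(stage = stage, time = format(Sys.time(), "%H:%M:%OS2"),
         message = message)
  log
}

run_dirs <- function(output_dir) {
  dirs <- file.path(output_dir, c("traces", "metrics", "report"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  setNames(as.list(dirs), c("traces", "metrics", "report"))
}

write_log <- function(log, output_dir) {
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  path <- file.path(output_dir, "run_log.json")
  jsonlite::write_json(log, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

collect_warnings <- function(expr, log_env) {
  withCallingHandlers(expr, warning = function(w) {
    log_env$log$warnings[[length(log_env$log$warnings) + 1L]] <-
      conditionMessage(w)
    invokeRestart("muffleWarning")
  })
}

#' Run the video-to-force pipeline
#'
#' Reads the video named in the config (or takes a [video_stack()]
#' directly), tracks the pillar head by phase-only correlation, converts
#' displacement to force through the cantilever model, summarises beats, and
#' writes: `traces/displacement.csv`, `traces/force.csv`,
#' `metrics/beat_metrics.json`, `report/config_echo.yaml` and
#' `run_log.json` under the config's `output_dir`. Deterministic given
#' inputs and config.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @param video Optional [video_stack()], bypassing `config$input`.
#' @return Invisibly, a list with `displacement`, `force`, `metrics`,
#'   `log_path` and `output_dir`.
#' @export
run_force_pipeline <- function(config, video = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  env <- new.env(); env$log <- new_run_log(config, "force")
  dirs <- run_dirs(config$output_dir)
  geom <- attr(config, "geometry_obj")

  if (is.null(video)) {
    if (is.null(config$input)) abort("config `input` is required (stage: read)")
    video <- read_video(config$input, config$pixel_scale_um,
                        config$frame_rate_hz)
  }
  env$log <- log_stage(env$log, "read",
                       sprintf("%d frames", n_frames(video)))

  disp <- collect_warnings(
    track_stack(video,
                mode = config$tracking$mode %||% "cumulative",
                roi = config$tracking$roi,
                axis = config$tracking$axis),
    env)
  env$log <- log_stage(env$log, "track",
                       sprintf("mean peak value %.3f", mean(disp$peak_value)))

  force <- collect_warnings(displacement_to_force(disp, geom), env)
  env$log <- log_stage(env$log, "force",
                       sprintf("baseline %.2f um", attr(force, "baseline_um")))

  metrics <- collect_warnings(beat_metrics(force, config$pacing_rate_hz), env)
  env$log <- log_stage(env$log, "beats",
                       if (metrics$detected)
                         sprintf("%d beats", metrics$n_beats)
                       else "no beats detected")

  f_disp <- file.path(dirs$traces, "displacement.csv")
  utils::write.csv(disp, f_disp, row.names = FALSE)
  f_force <- file.path(dirs$traces, "force.csv")
  utils::write.csv(force, f_force, row.names = FALSE)
  f_metrics <- file.path(dirs$metrics, "beat_metrics.json")
  jsonlite::write_json(
    c(as.list(glance(metrics)), list(beats = metrics$beats)),
    f_metrics, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f_cfg <- file.path(dirs$report, "config_echo.yaml")
  yaml::write_yaml(unclass(config), f_cfg)
  env$log$outputs <- c(f_disp, f_force, f_metrics, f_cfg)
  log_path <- write_log(env$log, config$output_dir)

  invisible(list(displacement = disp, force = force, metrics = metrics,
                 log_path = log_path, output_dir = config$output_dir))
}

#' Run the trace-to-calcium-features pipeline
#'
#' Reads per-ROI fluorescence traces (tidy or wide CSV, see
#' [read_calcium_traces()]), extracts per-beat transient features, and
#' aggregates them per ROI. Writes `traces/features.csv`,
#' `metrics/roi_summary.csv`, `report/config_echo.yaml` and `run_log.json`.
#'
#' @param config A `run_config` (or path to YAML).
#' @param traces Optional tidy trace tibble, bypassing `config$input`.
#' @return Invisibly, a list with `features`, `roi_summary`, `log_path`,
#'   `output_dir`.
#' @export
run_calcium_pipeline <- function(config, traces = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  env <- new.env(); env$log <- new_run_log(config, "calcium")
  dirs <- run_dirs(config$output_dir)

  if (is.null(traces)) {
    if (is.null(config$input)) abort("config `input` is required (stage: read)")
    traces <- read_calcium_traces(config$input)
  }
  env$log <- log_stage(env$log, "read",
                       sprintf("%d ROI(s)", length(unique(traces$roi_id))))

  features <- collect_warnings(
    transient_features(traces, config$pacing_rate_hz), env)
  env$log <- log_stage(env$log, "features",
                       sprintf("%d beats, %d valid", nrow(features),
                               sum(features$valid)))

  summary <- collect_warnings(aggregate_roi(features), env)
  env$log <- log_stage(env$log, "aggregate",
                       sprintf("%d ROI summaries", nrow(summary)))

  f_feat <- file.path(dirs$traces, "features.csv")
  utils::write.csv(features, f_feat, row.names = FALSE)
  f_sum <- file.path(dirs$metrics, "roi_summary.csv")
  utils::write.csv(summary, f_sum, row.names = FALSE)
  f_cfg <- file.path(dirs$report, "config_echo.yaml")
  yaml::write_yaml(unclass(config), f_cfg)
  env$log$outputs <- c(f_feat, f_sum, f_cfg)
  log_path <- write_log(env$log, config$output_dir)

  invisible(list(features = features, roi_summary = summary,
                 log_path = log_path, output_dir = config$output_dir))
}

#' Synthetic two-group demonstration cohort, end to end
#'
#' Generates a disease-like vs control cohort — reduced peak force, reduced
#' calcium amplitude, prolonged time to peak and decay in the disease group —
#' runs both analysis pipelines on every synthetic recording, compares the
#' groups feature by feature, and writes a single summary report
#' (`report/comparisons.csv`, `report/summary.txt`, and plot-ready
#' `report/box_summaries.json`).
#'
#' @param seed Master seed.
#' @param n_per_group Tissues per group for the force arm (videos).
#' @param n_roi_per_group ROIs per group for the calcium arm (traces).
#' @param output_dir Where to write the report.
#' @param force_ratio,amplitude_ratio Disease/control ratios (defaults 0.5
#'   and 0.6).
#' @param kinetics_factor Disease multiplier for rise time and for 1/decay
#'   rate (default 1.3: slower kinetics).
#' @return Invisibly: list with `force_samples`, `calcium_summary`,
#'   `comparisons` (per-feature glance rows), `output_dir`.
#' @export
run_demo_cohort <- function(seed = 1L, n_per_group = 5, n_roi_per_group = 12,
                            output_dir = tempfile("pillarbeat_demo_"),
                            force_ratio = 0.5, amplitude_ratio = 0.6,
                            kinetics_factor = 1.3) {
  dirs <- run_dirs(output_dir)
  control_force <- 30e-6

  # force arm: render videos, track, convert, summarise per tissue
  vid_cohort <- simulate_cohort(
    n_per_group, what = "video",
    control = list(peak_force_n = control_force, n_frames = 75),
    disease = list(peak_force_n = control_force * force_ratio, n_frames = 75),
    seed = seed, render = TRUE)
  force_samples <- purrr::map2_dfr(
    vid_cohort$members$recording,
    seq_len(nrow(vid_cohort$members)),
    function(rec, i) {
      disp <- track_stack(rec$video)
      frc <- displacement_to_force(disp)
      bm <- beat_metrics(frc, pacing_rate_hz = rec$params$pacing_rate_hz)
      tibble::tibble(
        group = vid_cohort$members$group[i],
        tissue = vid_cohort$members$member[i],
        max_force_n = bm$max_force_n,
        mean_peak_force_n = bm$mean_peak_force_n,
        prescribed_force_n = vid_cohort$members$peak_force_n[i])
    })

  # calcium arm: traces with reduced amplitude, slowed kinetics
  ca_cohort <- simulate_cohort(
    n_roi_per_group, what = "trace",
    control = list(amplitude = 100, rise_time_s = 0.15, decay_rate = 7),
    disease = list(amplitude = 100 * amplitude_ratio,
                   rise_time_s = 0.15 * kinetics_factor,
                   decay_rate = 7 / kinetics_factor),
    seed = seed + 1L, render = TRUE)
  ca_features <- purrr::map2_dfr(
    ca_cohort$members$recording, ca_cohort$members$group,
    function(rec, g) {
      feats <- transient_features(rec$trace)
      if (nrow(feats)) feats$group <- g
      feats
    })
  ca_summary <- ca_features %>%
    aggregate_roi() %>%
    dplyr::left_join(dplyr::distinct(ca_features, .data$roi_id, .data$group),
                     by = "roi_id")

  comparisons <- dplyr::bind_rows(
    compare_features(force_samples, "max_force_n", "group"),
    compare_features(ca_summary,
                     c("amplitude", "time_to_peak_s", "decay80_s"), "group"))

  f_cmp <- file.path(dirs$report, "comparisons.csv")
  utils::write.csv(comparisons, f_cmp, row.names = FALSE)
  box <- dplyr::bind_rows(
    summarize_groups(force_samples, "max_force_n", "group"),
    summarize_groups(ca_summary,
                     c("amplitude", "time_to_peak_s", "decay80_s"), "group"))
  f_box <- file.path(dirs$report, "box_summaries.json")
  jsonlite::write_json(box, f_box, pretty = TRUE, digits = NA)
  f_txt <- file.path(dirs$report, "summary.txt")
  writeLines(c(
    "pillarbeat synthetic cohort demo",
    sprintf("seed %d; %d tissues and %d ROIs per group", seed, n_per_group,
            n_roi_per_group),
    sprintf("prescribed ratios: force %.2f, amplitude %.2f, kinetics x%.2f",
            force_ratio, amplitude_ratio, kinetics_factor),
    "",
    utils::capture.output(as.data.frame(
      comparisons[, c("feature", "estimate", "t_statistic", "p_value")]))
  ), f_txt)

  invisible(list(force_samples = force_samples, calcium_summary = ca_summary,
                 comparisons = comparisons, output_dir = output_dir))
}
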