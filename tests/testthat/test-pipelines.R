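test_that("run configs validate physical quantities", {
  cfg <- run_config(frame_rate_hz = 30)
  expect_s3_class(cfg, "run_config")
  expect_error(run_config(pixel_scale_um = 0), "positive")
  expect_error(run_config(frame_rate_hz = -2), "positive")
  expect_error(run_config(tracking = list(mode = "sideways")), "mode")
})

test_that("YAML configs round trip and fail fast on bad keys", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_scale_um = 3.79, frame_rate_hz = 30,
                        pacing_rate_hz = 1,
                        geometry = list(length_m = 12e-3)), f)
  cfg <- read_run_config(f)
  expect_equal(cfg$frame_rate_hz, 30)
  expect_equal(attr(cfg, "geometry_obj")$length_m, 12e-3)

  # YAML sign-less exponents ("1.7e6" parses as a string) are coerced
  signless <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("input: recording.tif", "geometry:",
               "  youngs_modulus_pa: 1.7e6"), signless)
  cfg2 <- read_run_config(signless)
  expect_equal(attr(cfg2, "geometry_obj")$youngs_modulus_pa, 1.7e6)
  expect_identical(cfg2$input, "recording.tif")
  # the shipped example config is valid
  example <- system.file("extdata", "example_config.yaml",
                         package = "pillarbeat")
  expect_s3_class(read_run_config(example), "run_config")

  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_scale = 3.79), bad)  # typo'd key
  expect_error(read_run_config(bad), "unknown config key")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(geometry = list(length_mm = 12)), bad2)
  expect_error(read_run_config(bad2), "unknown geometry key")
  bad3 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(pixel_scale_um = -1), bad3)
  expect_error(read_run_config(bad3), "positive")
})

test_that("the force pipeline runs end to end and recovers the truth", {
  sim <- simulate_pillar_video(peak_force_n = 20e-6, n_frames = 60,
                               frame_shape = c(96, 160))
  vid_path <- withr::local_tempfile(fileext = ".tif")
  write_video(sim$video, vid_path)
  out <- withr::local_tempdir()
  cfg <- run_config(input = vid_path, output_dir = out, frame_rate_hz = 30)
  res <- run_force_pipeline(cfg)
  expect_lt(abs(res$metrics$max_force_n - 20e-6) / 20e-6, 0.05)
  for (f in c("traces/displacement.csv", "traces/force.csv",
              "metrics/beat_metrics.json", "report/config_echo.yaml",
              "run_log.json")) {
    expect_true(file.exists(file.path(out, f)))
  }
  # every output is referenced in the run log
  log <- jsonlite::read_json(file.path(out, "run_log.json"))
  expect_setequal(basename(unlist(log$outputs)),
                  c("displacement.csv", "force.csv", "beat_metrics.json",
                    "config_echo.yaml"))
})

test_that("pipeline output is deterministic for a fixed config", {
  sim <- simulate_pillar_video(peak_force_n = 10e-6, n_frames = 30,
                               frame_shape = c(64, 96), pillar_radius_px = 10)
  vid_path <- withr::local_tempfile(fileext = ".tif")
  write_video(sim$video, vid_path)
  outs <- replicate(2, {
    out <- withr::local_tempdir()
    run_force_pipeline(run_config(input = vid_path, output_dir = out,
                                  frame_rate_hz = 30))
    readLines(file.path(out, "traces", "displacement.csv"))
  }, simplify = FALSE)
  expect_identical(outs[[1]], outs[[2]])
})

test_that("the calcium pipeline writes features and ROI summaries", {
  a <- simulate_calcium_trace(seed = 1, noise_sd = 3)$trace
  b <- simulate_calcium_trace(seed = 2, noise_sd = 3)$trace
  b$roi_id <- "roi2"
  f_csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(dplyr::bind_rows(a, b), f_csv, row.names = FALSE)
  out <- withr::local_tempdir()
  res <- run_calcium_pipeline(run_config(input = f_csv, output_dir = out))
  expect_identical(nrow(res$roi_summary), 2L)
  expect_true(file.exists(file.path(out, "traces", "features.csv")))
  expect_true(file.exists(file.path(out, "metrics", "roi_summary.csv")))
  # missing input fails with a stage-identified message
  expect_error(run_calcium_pipeline(run_config(output_dir = out)),
               "stage: read")
})

test_that("the demo cohort separates the groups as prescribed", {
  out <- withr::local_tempdir()
  res <- run_demo_cohort(seed = 2, n_per_group = 3, n_roi_per_group = 4,
                         output_dir = out)
  expect_true(file.exists(file.path(out, "report", "comparisons.csv")))
  expect_true(file.exists(file.path(out, "report", "summary.txt")))
  m <- tapply(res$force_samples$max_force_n, res$force_samples$group, mean)
  expect_equal(unname(m["disease"] / m["control"]), 0.5, tolerance = 0.3)
  expect_true(all(c("max_force_n", "amplitude", "time_to_peak_s",
                    "decay80_s") %in% res$comparisons$feature))
})

test_that("the CLI wrapper maps subcommands onto package functions", {
  script <- system.file("scripts", "pillarbeat-cli.R", package = "pillarbeat")
  expect_true(nzchar(script))
  env <- new.env()
  withr::local_options(pillarbeat.cli.no_autorun = TRUE)
  sys.source(script, envir = env)
  out <- withr::local_tempdir()
  withr::with_dir(out, {
    suppressMessages(
      env$cli_main(c("simulate", "--n-frames", "10", "--peak-force", "1e-5",
                     "--out", "simout")))
    expect_true(file.exists(file.path("simout", "synthetic_video.tif")))
    expect_true(file.exists(file.path("simout", "ground_truth.csv")))
  })
})
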