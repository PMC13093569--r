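test_that("dF/F0 normalisation handles canonical cases", {
  t <- seq(0, 5, by = 0.01)
  # constant trace -> identically zero
  flat <- normalize_dff(tibble::tibble(time_s = t, intensity = rep(100, length(t))))
  expect_true(all(flat$dff == 0))
  # baseline 100, peak 150 -> peak dF/F0 = 0.5
  sim <- simulate_calcium_trace(baseline = 100, amplitude = 50, noise_sd = 0,
                                drift_slope = 0)
  nd <- normalize_dff(sim$trace)
  expect_equal(max(nd$dff), 0.5, tolerance = 0.01)
  # pure linear drift detrends away to < 0.01
  drift <- tibble::tibble(time_s = t, intensity = 100 - 2 * t)
  expect_lt(max(abs(normalize_dff(drift)$dff)), 0.01)
  # non-positive baseline is an error
  neg <- tibble::tibble(time_s = t, intensity = rep(-5, length(t)))
  expect_error(normalize_dff(neg), "F0")
})

test_that("trace validation rejects malformed input", {
  expect_error(normalize_dff(tibble::tibble(time_s = c(0, 0.1, 0.1),
                                            intensity = c(1, 2, 3))),
               "strictly increasing")
  expect_error(normalize_dff(tibble::tibble(time_s = c(0, 0.1, 0.3),
                                            intensity = c(1, 2, 3))),
               "jitter")
})

test_that("beat segmentation counts complete windows", {
  sim <- quick_trace(duration_s = 12)
  seg <- segment_beats(normalize_dff(sim$trace))
  expect_gte(nrow(seg), 10)
  expect_lte(nrow(seg), 11)
  expect_equal(unique(round(seg$end_s - seg$start_s, 6)), 1)
  # a flat trace has no windows, with a diagnostic
  flat <- tibble::tibble(time_s = sim$trace$time_s,
                         intensity = rep(100, nrow(sim$trace)))
  seg0 <- segment_beats(normalize_dff(flat))
  expect_identical(nrow(seg0), 0L)
  expect_match(attr(seg0, "diagnostics")$reason, "flat")
  # slower pacing gives proportionally longer windows
  sim2 <- quick_trace(duration_s = 12, pacing_rate_hz = 0.5,
                      rise_time_s = 0.3)
  seg2 <- segment_beats(normalize_dff(sim2$trace), pacing_rate_hz = 0.5)
  expect_equal(unique(round(seg2$end_s - seg2$start_s, 6)), 2)
})

test_that("noiseless features match the generating parameters", {
  sim <- quick_trace(rise_time_s = 0.1, decay_rate = 8, amplitude = 100)
  ft <- transient_features(sim$trace)
  truth <- sim$truth$beats
  expect_true(all(ft$valid))
  expect_equal(mean(ft$amplitude), truth$amplitude_dff[1], tolerance = 0.01)
  expect_equal(mean(ft$time_to_peak_s), truth$time_to_peak_s[1],
               tolerance = 0.05)
  # decay80 within one sample interval of ln(5)/lambda
  expect_lt(abs(mean(ft$decay80_s) - log(5) / 8), 1 / 100)
})

test_that("decay80 is invariant to amplitude scaling", {
  a <- quick_trace(amplitude = 100)
  b <- quick_trace(amplitude = 200, baseline = 100)
  fa <- transient_features(a$trace)
  fb <- transient_features(b$trace)
  expect_equal(mean(fb$decay80_s), mean(fa$decay80_s), tolerance = 0.01)
  expect_equal(mean(fb$amplitude) / mean(fa$amplitude), 2, tolerance = 0.02)
})

test_that("features are invariant to affine intensity rescaling", {
  sim <- quick_trace(noise_sd = 3, seed = 11)
  base <- transient_features(sim$trace)
  scaled <- sim$trace
  scaled$intensity <- 2.7 * scaled$intensity
  fs <- transient_features(scaled)
  expect_equal(fs$amplitude, base$amplitude, tolerance = 1e-8)
  expect_equal(fs$time_to_peak_s, base$time_to_peak_s, tolerance = 1e-8)
  expect_equal(fs$decay80_s, base$decay80_s, tolerance = 1e-8)
  # timing features additionally survive an affine offset
  shifted <- sim$trace
  shifted$intensity <- 1.5 * shifted$intensity + 40
  fsh <- transient_features(shifted)
  expect_equal(fsh$time_to_peak_s, base$time_to_peak_s, tolerance = 1e-6)
  expect_equal(fsh$decay80_s, base$decay80_s, tolerance = 1e-6)
})

test_that("a decay too slow to cross the 20% level flags the beat invalid", {
  # superposed (non-steady-state) transients with an extremely slow decay:
  # within each 1 s window the signal never falls to 20% of its amplitude
  t <- seq(0, 6, by = 0.01)
  x <- numeric(length(t))
  for (stim in 1:4) {
    ph <- t - stim
    x <- x + ifelse(ph < 0, 0,
                    ifelse(ph < 0.1, (1 - cos(pi * ph / 0.1)) / 2,
                           exp(-0.1 * (ph - 0.1))))
  }
  ft <- transient_features(tibble::tibble(time_s = t, intensity = 100 + 100 * x))
  expect_true(nrow(ft) > 0)
  expect_false(any(ft$valid))
  expect_true(all(is.na(ft$decay80_s)))
})

test_that("the optional exponential-fit tau matches 1/lambda", {
  sim <- quick_trace(decay_rate = 8, rise_time_s = 0.1)
  ft <- transient_features(sim$trace, exp_tau = TRUE)
  expect_equal(mean(ft$exp_tau_s), 1 / 8, tolerance = 0.03)
})

test_that("ROI aggregation averages up to 10 consecutive valid beats", {
  sim <- quick_trace()
  ft <- transient_features(sim$trace)
  agg <- aggregate_roi(ft)
  expect_identical(agg$n_beats, 10L)
  expect_equal(agg$amplitude, mean(ft$amplitude[seq_len(10)]))
  # identical beats: the summary equals the single-beat features
  expect_equal(agg$decay80_s, ft$decay80_s[1], tolerance = 0.01)
  # invalid beats are excluded and the count is honest
  ft2 <- ft
  ft2$valid[c(2, 4, 8, 9)] <- FALSE
  agg2 <- aggregate_roi(ft2)
  expect_identical(agg2$n_beats, min(10L, sum(ft2$valid)))
})

test_that("averaging 10 beats shrinks the feature SD by about sqrt(10)", {
  # Monte Carlo over synthetic per-beat feature tables with iid noise
  per_beat_sd <- 0.1
  roi_means <- withr::with_seed(21, vapply(1:200, function(i) {
    feats <- tibble::tibble(
      roi_id = "r", beat = 1:10,
      amplitude = 1 + rnorm(10, 0, per_beat_sd),
      time_to_peak_s = 0.12, decay80_s = 0.23, valid = TRUE)
    aggregate_roi(feats)$amplitude
  }, numeric(1)))
  ratio <- sd(roi_means) / per_beat_sd
  expect_equal(ratio, 1 / sqrt(10), tolerance = 0.2)
})

test_that("multi-ROI tables are processed independently", {
  a <- quick_trace(seed = 1, amplitude = 100)$trace
  b <- quick_trace(seed = 2, amplitude = 60)$trace
  b$roi_id <- "roi2"
  ft <- transient_features(dplyr::bind_rows(a, b))
  agg <- aggregate_roi(ft)
  expect_identical(nrow(agg), 2L)
  expect_equal(agg$amplitude[agg$roi_id == "roi2"] /
                 agg$amplitude[agg$roi_id == "roi1"], 0.6, tolerance = 0.05)
})

test_that("wide and tidy trace files read to the same tidy table", {
  a <- quick_trace(seed = 1)$trace
  b <- quick_trace(seed = 2)$trace
  wide <- tibble::tibble(time_s = a$time_s, roi_a = a$intensity,
                         roi_b = b$intensity)
  f_wide <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, f_wide, row.names = FALSE)
  rd <- read_calcium_traces(f_wide)
  expect_identical(sort(unique(rd$roi_id)), c("roi_a", "roi_b"))
  expect_equal(rd$intensity[rd$roi_id == "roi_a"], a$intensity)
  f_tidy <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(a, f_tidy, row.names = FALSE)
  rt <- read_calcium_traces(f_tidy)
  expect_equal(rt$intensity, a$intensity)
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(read_calcium_traces(empty), "empty|column|input")
})
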