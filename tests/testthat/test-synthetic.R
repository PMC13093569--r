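test_that("video generation is deterministic under a fixed seed", {
  a <- simulate_pillar_video(n_frames = 10, noise_sd = 0.02, texture_seed = 4,
                             seed = 9)
  b <- simulate_pillar_video(n_frames = 10, noise_sd = 0.02, texture_seed = 4,
                             seed = 9)
  expect_identical(a$video$frames, b$video$frames)
  expect_identical(a$truth, b$truth)
})

test_that("zero force gives identical frames up to noise and drift", {
  sim <- simulate_pillar_video(peak_force_n = 0, n_frames = 6)
  expect_true(all(sim$truth$displacement_um == 0))
  for (i in 2:6) {
    expect_equal(sim$video$frames[, , i], sim$video$frames[, , 1],
                 tolerance = 1e-12)
  }
})

test_that("ground-truth plateau deflection matches the beam model", {
  # constant 30 uN load on the default pillar: delta = P/k ~ 99.9 um
  sim <- simulate_pillar_video(peak_force_n = 30e-6, n_frames = 40,
                               frame_shape = c(128, 192),
                               twitch_width_s = 0.99, pacing_rate_hz = 1,
                               frame_rate_hz = 40)
  expect_equal(max(sim$truth$displacement_um), 99.9, tolerance = 1e-3)
})

test_that("ground-truth displacement is exactly force over stiffness", {
  sim <- quick_video()
  k <- bending_stiffness(pillar_geometry())
  expect_equal(sim$truth$displacement_um,
               sim$truth$force_n / k * 1e6, tolerance = 1e-9)
})

test_that("empirical frame noise matches the prescribed noise SD", {
  sim <- simulate_pillar_video(peak_force_n = 0, n_frames = 4,
                               noise_sd = 0.03)
  clean <- simulate_pillar_video(peak_force_n = 0, n_frames = 4)
  resid <- sim$video$frames - clean$video$frames
  expect_equal(sd(resid), 0.03, tolerance = 0.1)  # within 10%, >= 10^4 px
})

test_that("excessive displacement and flat texture are rejected", {
  expect_error(
    simulate_pillar_video(peak_force_n = 200e-6, frame_shape = c(64, 64)),
    "exceeds frame bounds")
  expect_error(simulate_pillar_video(contrast = 0), "flat")
  expect_error(simulate_pillar_video(n_frames = 1), "n_frames")
  expect_error(simulate_pillar_video(frame_rate_hz = 1.5), "twice the pacing")
  expect_error(simulate_pillar_video(peak_force_n = -1e-6), ">= 0")
})

test_that("calcium ground truth uses the closed-form 80%-decay time", {
  sim <- simulate_calcium_trace(noise_sd = 0, drift_slope = 0,
                                amplitude = 100, rise_time_s = 0.1,
                                decay_rate = 8)
  expect_equal(sim$truth$beats$decay80_s[1], log(5) / 8, tolerance = 1e-12)
  expect_equal(sim$truth$beats$decay80_s[1], 0.2012, tolerance = 1e-3)
})

test_that("zero amplitude yields a flat trace at baseline", {
  sim <- simulate_calcium_trace(amplitude = 0, noise_sd = 0, drift_slope = 0)
  expect_true(all(sim$trace$intensity == 100))
})

test_that("a 10 s recording at 1 Hz pacing contains exactly 10 beats", {
  sim <- simulate_calcium_trace(duration_s = 10, noise_sd = 0)
  expect_identical(nrow(sim$truth$beats), 10L)
  # general rule: floor(duration * pacing)
  sim2 <- simulate_calcium_trace(duration_s = 7.6, pacing_rate_hz = 0.5,
                                 rise_time_s = 0.3, noise_sd = 0)
  expect_identical(nrow(sim2$truth$beats), as.integer(floor(7.6 * 0.5)))
})

test_that("transients overlapping the next stimulus raise a recorded warning", {
  expect_warning(
    sim <- simulate_calcium_trace(decay_rate = 1.5, noise_sd = 0),
    "overlaps")
  expect_true(sim$truth$overlap_warning)
  expect_no_warning(simulate_calcium_trace(noise_sd = 0))
})

test_that("trace generation is deterministic and validates its spec", {
  a <- simulate_calcium_trace(seed = 3)
  b <- simulate_calcium_trace(seed = 3)
  expect_identical(a$trace, b$trace)
  expect_error(simulate_calcium_trace(rise_time_s = 1.2), "pacing period")
  expect_error(simulate_calcium_trace(sample_rate_hz = 10), "20 x")
  expect_error(simulate_calcium_trace(baseline = -5), "baseline")
})

test_that("cohorts are reproducible and carry the prescribed effect size", {
  a <- simulate_cohort(3, what = "trace",
                       control = list(amplitude = 100),
                       disease = list(amplitude = 50),
                       seed = 5)
  b <- simulate_cohort(3, what = "trace",
                       control = list(amplitude = 100),
                       disease = list(amplitude = 50),
                       seed = 5)
  expect_identical(a$members$amplitude, b$members$amplitude)
  expect_identical(a$members$recording[[1]]$trace,
                   b$members$recording[[1]]$trace)
  expect_equal(a$prescribed$ratio, 0.5)

  same <- simulate_cohort(2, what = "video", render = FALSE, seed = 1)
  expect_equal(same$prescribed$ratio, 1)
  expect_error(simulate_cohort(1, what = "trace"), "n_per_group")
})

test_that("feature-level force draws mirror the prescribed design", {
  d <- simulate_force_samples(n_per_group = 200, seed = 2)
  m <- tapply(d$force_n, d$group, mean)
  expect_equal(unname(m["disease"] / m["control"]), 0.5, tolerance = 0.05)
  expect_identical(simulate_force_samples(seed = 4),
                   simulate_force_samples(seed = 4))
})
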