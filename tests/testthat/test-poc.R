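test_that("registering a frame against itself gives zero shift and unit peak", {
  tex <- random_texture(64, 64, seed = 3)
  est <- poc_shift(tex, tex)
  expect_equal(est$dx, 0, tolerance = 1e-9)
  expect_equal(est$dy, 0, tolerance = 1e-9)
  expect_equal(est$peak_value, 1, tolerance = 1e-6)
  expect_false(est$low_confidence)
})

test_that("integer circular shifts are recovered exactly", {
  tex <- random_texture(64, 64, seed = 5)
  mov <- fourier_shift(tex, 3, -2)  # integer shift == circular shift
  # without apodisation a circular shift is an exact eigencase of POC
  est <- poc_shift(tex, mov, window = FALSE)
  expect_lt(abs(est$dx - 3), 1e-6)
  expect_lt(abs(est$dy + 2), 1e-6)
  # the windowed default still recovers it to subpixel accuracy
  estw <- poc_shift(tex, mov)
  expect_lt(abs(estw$dx - 3), 0.05)
  expect_lt(abs(estw$dy + 2), 0.05)
})

test_that("subpixel shifts in [-5, 5] px are recovered to < 0.05 px", {
  shifts <- withr::with_seed(11, matrix(runif(24, -5, 5), ncol = 2))
  for (i in seq_len(nrow(shifts))) {
    p <- shifted_pair(100 + i, shifts[i, 1], shifts[i, 2])
    est <- poc_shift(p$ref, p$mov)
    expect_lt(abs(est$dx - shifts[i, 1]), 0.05)
    expect_lt(abs(est$dy - shifts[i, 2]), 0.05)
  }
})

test_that("5%-of-range noise degrades accuracy to no worse than 0.25 px", {
  shifts <- withr::with_seed(12, matrix(runif(16, -5, 5), ncol = 2))
  for (i in seq_len(nrow(shifts))) {
    p <- shifted_pair(200 + i, shifts[i, 1], shifts[i, 2], noise_sd = 0.05)
    est <- poc_shift(p$ref, p$mov)
    expect_lt(abs(est$dx - shifts[i, 1]), 0.25)
    expect_lt(abs(est$dy - shifts[i, 2]), 0.25)
  }
})

test_that("estimate is antisymmetric in the frame order", {
  p <- shifted_pair(31, 2.3, -1.7)
  ab <- poc_shift(p$ref, p$mov)
  ba <- poc_shift(p$mov, p$ref)
  expect_equal(ab$dx, -ba$dx, tolerance = 5e-3)
  expect_equal(ab$dy, -ba$dy, tolerance = 5e-3)
})

test_that("estimate is invariant to positive brightness scaling", {
  p <- shifted_pair(32, 1.8, 0.6)
  base <- poc_shift(p$ref, p$mov)
  scaled <- poc_shift(p$ref, 1.8 * p$mov)
  expect_lt(abs(scaled$dx - base$dx), 1e-6)
  expect_lt(abs(scaled$dy - base$dy), 1e-6)
  scaled2 <- poc_shift(0.4 * p$ref, p$mov)
  expect_lt(abs(scaled2$dx - base$dx), 1e-6)
})

test_that("POC and the brute-force correlation oracle agree within 0.1 px", {
  for (i in 1:10) {
    sh <- withr::with_seed(300 + i, runif(2, -4, 4))
    p <- shifted_pair(400 + i, sh[1], sh[2], n = 64)
    a <- poc_shift(p$ref, p$mov)
    b <- brute_force_shift(p$ref, p$mov, search_radius = 6)
    expect_lt(abs(a$dx - b$dx), 0.1)
    expect_lt(abs(a$dy - b$dy), 0.1)
  }
})

test_that("brute-force oracle recovers known integer shifts exactly", {
  tex <- random_texture(48, 48, seed = 9)
  mov <- fourier_shift(tex, -3, 2)
  est <- brute_force_shift(tex, mov, search_radius = 5, refine = FALSE)
  expect_identical(c(est$dx, est$dy), c(-3, 2))
})

test_that("constant frames and oversized ROIs are rejected", {
  flat <- matrix(1, 32, 32)
  tex <- random_texture(32, 32, seed = 2)
  expect_error(poc_shift(flat, tex), "ill-posed")
  expect_error(poc_shift(tex, tex[1:16, 1:16]), "identical dimensions")
  expect_error(poc_shift(tex, tex, roi = c(1, 1, 8, 8)), "16 x 16")
  expect_error(poc_shift(tex, tex, roi = c(20, 20, 16, 16)), "bounds")
  expect_error(brute_force_shift(tex, tex, search_radius = 20), "search_radius")
})

test_that("tracking identical frames returns an all-zero trace", {
  tex <- random_texture(48, 48, seed = 7)
  v <- video_stack(array(rep(tex, 4), c(48, 48, 4)), 3.79, 30)
  tr <- track_stack(v)
  expect_s3_class(tr, "displacement_trace")
  expect_equal(tr$disp_um, rep(0, 4), tolerance = 1e-8)
  expect_equal(tr$disp_um[1], 0)
})

test_that("tracking recovers the ground-truth deflection of a synthetic video", {
  sim <- quick_video(peak_force_n = 15e-6)
  tr <- track_stack(sim$video)
  err_px <- max(abs(tr$disp_um - sim$truth$displacement_um)) /
    sim$video$pixel_scale_um
  expect_lt(err_px, 0.05)
})

test_that("fixed-reference and cumulative modes agree on rigid motion", {
  sim <- quick_video(peak_force_n = 15e-6, n_frames = 30)
  t1 <- track_stack(sim$video, mode = "cumulative")
  t2 <- track_stack(sim$video, mode = "fixed_reference")
  expect_lt(max(abs(t1$disp_um - t2$disp_um)) / sim$video$pixel_scale_um,
            0.05)
})
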