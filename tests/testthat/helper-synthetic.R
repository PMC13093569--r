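# Shared fixtures, all generated in code at test time.

# a band-limited texture pair with a known subpixel shift
shifted_pair <- function(seed, dx, dy, n = 96, noise_sd = 0) {
  ref <- random_texture(n, n, seed = seed)
  mov <- fourier_shift(ref, dx, dy)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed + 10000L, {
      list(a = matrix(rnorm(n * n, 0, noise_sd), n, n),
           b = matrix(rnorm(n * n, 0, noise_sd), n, n))
    })
    ref <- ref + noise$a
    mov <- mov + noise$b
  }
  list(ref = ref, mov = mov)
}

# a small noiseless pillar video (fast default for unit tests)
quick_video <- function(peak_force_n = 15e-6, n_frames = 45, ...) {
  simulate_pillar_video(peak_force_n = peak_force_n, n_frames = n_frames, ...)
}

# default-condition calcium trace
quick_trace <- function(noise_sd = 0, drift_slope = 0, seed = 1L, ...) {
  simulate_calcium_trace(noise_sd = noise_sd, drift_slope = drift_slope,
                         seed = seed, ...)
}

# exact permutation p value (complete enumeration) for a two-sample
# difference in means -- independent oracle for compare_groups
perm_test_p <- function(a, b) {
  x <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(x), n)
  obs <- abs(mean(a) - mean(b))
  diffs <- apply(idx, 2, function(i) abs(mean(x[i]) - mean(x[-i])))
  mean(diffs >= obs - 1e-12)
}
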