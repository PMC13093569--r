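# Spectral helpers shared by the synthetic generator and the POC tracker.
# All grids follow R's fft() layout: frequency k/N with k = 0, 1, ..., N-1,
# mapped to signed frequencies by wrapping k > N/2 to k - N.

freq_axis <- function(n) {
  k <- seq_len(n) - 1L
  k[k > n / 2] <- k[k > n / 2] - n
  k / n
}

# list(KY, KX): per-pixel signed frequency (cycles/pixel) along rows / columns
freq_grid <- function(nr, nc) {
  list(
    KY = matrix(freq_axis(nr), nr, nc),
    KX = matrix(freq_axis(nc), nr, nc, byrow = TRUE)
  )
}

#' Subpixel translation of an image by Fourier phase shift
#'
#' Translates a real-valued image by (`dx`, `dy`) pixels using the Fourier
#' shift theorem, i.e. band-limited (sinc) resampling of the periodic
#' extension of the image. Non-integer shifts are rendered exactly for the
#' band-limited interpolant, which is what a subpixel tracker must be tested
#' against; integer shifts reduce to circular shifts.
#'
#' @param image Numeric matrix.
#' @param dx,dy Shift in pixels along columns (x) and rows (y). Positive
#'   values move content toward larger x / y.
#' @return The shifted matrix.
#' @examples
#' m <- matrix(rnorm(64), 8, 8)
#' all.equal(fourier_shift(m, 2, 0), m[, c(7, 8, 1:6)])
#' @export
fourier_shift <- function(image, dx, dy) {
  stopifnot(is.matrix(image), is.numeric(image))
  g <- freq_grid(nrow(image), ncol(image))
  ph <- exp(-2i * pi * (g$KY * dy + g$KX * dx))
  Re(fft(fft(image) * ph, inverse = TRUE)) / length(image)
}

# 2-D Hann window (apodization before the FFT suppresses wrap-around edges)
hann2 <- function(nr, nc) {
  wy <- 0.5 * (1 - cos(2 * pi * (seq_len(nr) - 1) / (nr - 1)))
  wx <- 0.5 * (1 - cos(2 * pi * (seq_len(nc) - 1) / (nc - 1)))
  outer(wy, wx)
}

# Isotropic Gaussian low-pass in the frequency domain; cutoff in cycles/pixel
# (Nyquist = 0.5) sets the e-folding scale of the amplitude envelope.
lowpass2 <- function(image, cutoff) {
  g <- freq_grid(nrow(image), ncol(image))
  filt <- exp(-(g$KY^2 + g$KX^2) / (2 * (cutoff / 2)^2))
  Re(fft(fft(image) * filt, inverse = TRUE)) / length(image)
}

#' Seeded band-limited random texture
#'
#' A smooth Gaussian random field rescaled to `[0, 1]`. Band-limiting keeps
#' subpixel Fourier shifts faithful (no ringing), and the random field has a
#' well-conditioned phase spectrum, which keeps registration well-posed. Used
#' for the pillar-head texture in synthetic videos and as a convenient test
#' pattern for the registration functions.
#'
#' @param nr,nc Field dimensions in pixels.
#' @param cutoff Gaussian low-pass cutoff in cycles/pixel (Nyquist = 0.5).
#' @param seed Integer seed (the field is a pure function of its arguments).
#' @return An `nr x nc` matrix with values in `[0, 1]`.
#' @export
random_texture <- function(nr, nc, cutoff = 0.35, seed = 1L) {
  z <- withr::with_seed(seed, matrix(rnorm(nr * nc), nr, nc))
  tx <- lowpass2(z, cutoff)
  rng <- range(tx)
  if (diff(rng) <= 0) abort("degenerate (flat) texture field")
  (tx - rng[1]) / diff(rng)
}
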