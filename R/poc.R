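#' Subpixel image registration by phase-only correlation
#'
#' Estimates the rigid translation mapping `moving` onto `reference` from the
#' phase of the cross-power spectrum. The normalised cross-phase spectrum
#' \deqn{R = \frac{F_m \overline{F_r}}{|F_m \overline{F_r}|}}
#' discards all magnitude information, which makes the estimate invariant to
#' positive intensity scaling (illumination/brightness changes) and
#' concentrates the inverse transform into a single sharp peak at the true
#' translation. The peak of the band-limited correlation surface — the
#' analytic peak model of the method, a 2-D Dirichlet kernel centred on the
#' true shift — is located to subpixel precision by numerical maximisation of
#' the trigonometric polynomial, initialised from a closed-form 3-point fit
#' of the same model (with a parabolic fallback if that fit is degenerate).
#'
#' Both frames are apodised with a Hann window to suppress wrap-around edge
#' artefacts, and the cross-phase spectrum is weighted by an isotropic
#' Gaussian low-pass (`spectral_sigma`, in cycles/pixel) before inversion;
#' high frequencies carry no signal phase once noise dominates, and
#' down-weighting them is what preserves subpixel accuracy on noisy frames.
#' The DC term is removed, so additive offsets are ignored too.
#'
#' Sign convention: the returned `(dx, dy)` is the motion of the content from
#' `reference` to `moving` — content moved by `+dx` pixels along x (columns)
#' and `+dy` along y (rows). Consequently
#' `fourier_shift(reference, dx, dy)` reproduces `moving` for a pure
#' translation, and `poc_shift(b, a)` returns the negated estimate of
#' `poc_shift(a, b)`.
#'
#' @param reference,moving Numeric matrices of identical dimensions.
#' @param roi Optional region of interest `c(x, y, width, height)` in pixels
#'   (1-based corner); both frames are cropped to it before registration.
#'   Must be at least 16 x 16.
#' @param window Apply the Hann window (default `TRUE`).
#' @param spectral_sigma Standard deviation (cycles/pixel, Nyquist = 0.5) of
#'   the Gaussian spectral weight. Default 0.15.
#' @param peak_floor Estimates whose correlation peak falls below this value
#'   are flagged `low_confidence` (not suppressed). Default 0.3.
#' @return A `shift_estimate`: list with `dx`, `dy` (pixels), `peak_value`
#'   (in `[0, 1]`, 1 for identical frames), `low_confidence`, and
#'   `diagnostics` (integer peak, refinement method, window/weight settings).
#' @examples
#' tex <- random_texture(64, 64, seed = 1)
#' est <- poc_shift(tex, fourier_shift(tex, 3, -2))
#' round(c(est$dx, est$dy), 3)  # c(3, -2)
#' @seealso [brute_force_shift()] for the exhaustive cross-correlation
#'   oracle, [track_stack()] for whole-recording tracking.
#' @export
poc_shift <- function(reference, moving, roi = NULL, window = TRUE,
                      spectral_sigma = 0.15, peak_floor = 0.3) {
  stopifnot(is.matrix(reference), is.matrix(moving))
  if (!identical(dim(reference), dim(moving))) {
    abort("`reference` and `moving` must have identical dimensions")
  }
  if (!is.null(roi)) {
    reference <- crop_roi(reference, roi)
    moving <- crop_roi(moving, roi)
  }
  if (sd(reference) == 0 || sd(moving) == 0) {
    abort("ill-posed registration: constant frame (no texture)")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  if (window) {
    w <- hann2(nr, nc)
    reference <- reference * w
    moving <- moving * w
  }
  Fr <- fft(reference)
  Fm <- fft(moving)
  X <- Fm * Conj(Fr)
  M <- Mod(X)
  R <- X / M
  R[M < 1e-15 * max(M)] <- 0 + 0i  # phase undefined at true spectral zeros
  g <- freq_grid(nr, nc)
  W <- exp(-(g$KY^2 + g$KX^2) / (2 * spectral_sigma^2))
  W[1, 1] <- 0
  RW <- R * W
  sw <- sum(W)
  surf <- Re(fft(RW, inverse = TRUE)) / sw
  ipk <- unname(which(surf == max(surf), arr.ind = TRUE)[1, ])
  dy0 <- unwrap_shift(ipk[1], nr)
  dx0 <- unwrap_shift(ipk[2], nc)
  init <- c(
    dx0 + axis_refine(surf, ipk, nc, along = "x"),
    dy0 + axis_refine(surf, ipk, nr, along = "y")
  )
  # maximise the continuous (band-limited) correlation surface
  fn <- function(u) {
    -Re(sum(RW * exp(2i * pi * (g$KY * u[2] + g$KX * u[1])))) / sw
  }
  opt <- tryCatch(
    optim(init, fn, method = "L-BFGS-B",
          lower = c(dx0 - 1, dy0 - 1), upper = c(dx0 + 1, dy0 + 1),
          control = list(factr = 1e4)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    est <- init; peak <- surf[ipk[1], ipk[2]]; method <- "closed_form"
  } else {
    est <- opt$par; peak <- -opt$value; method <- "surface_max"
  }
  structure(
    list(
      dx = est[1], dy = est[2],
      peak_value = min(1, peak),
      low_confidence = peak < peak_floor,
      diagnostics = list(
        integer_peak = c(dx = dx0, dy = dy0),
        refinement = method,
        window = window,
        spectral_sigma = spectral_sigma,
        frame_dim = c(nr, nc)
      )
    ),
    class = "shift_estimate"
  )
}

#' @export
print.shift_estimate <- function(x, ...) {
  cat(sprintf("<shift_estimate> dx = %.4f px, dy = %.4f px, peak = %.3f%s\n",
              x$dx, x$dy, x$peak_value,
              if (x$low_confidence) " [low confidence]" else ""))
  invisible(x)
}

unwrap_shift <- function(idx, n) {
  s <- idx - 1L
  if (s > n / 2) s - n else s
}

# closed-form 3-point fit of the analytic correlation peak model along one
# axis: for a Dirichlet-kernel peak the offset satisfies
# delta = r(+1) / (r(0) + r(+1)) (taking the larger neighbour); degenerate
# configurations fall back to a parabolic fit.
axis_refine <- function(surf, ipk, n, along = c("x", "y")) {
  along <- match.arg(along)
  at <- function(k) {
    if (along == "x") surf[ipk[1], wrap_index(ipk[2] + k, n)]
    else surf[wrap_index(ipk[1] + k, n), ipk[2]]
  }
  r0 <- at(0L); rp <- at(1L); rm <- at(-1L)
  d <- if (abs(rp) >= abs(rm)) {
    if (r0 + rp != 0) rp / (r0 + rp) else NA_real_
  } else {
    if (r0 + rm != 0) -rm / (r0 + rm) else NA_real_
  }
  if (!is.finite(d) || abs(d) > 1) {
    den <- rm - 2 * r0 + rp  # parabolic fallback
    d <- if (is.finite(den) && den < 0) 0.5 * (rm - rp) / den else 0
  }
  max(-0.5, min(0.5, d))
}

wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

crop_roi <- function(frame, roi) {
  if (length(roi) != 4L) abort("`roi` must be c(x, y, width, height)")
  x <- roi[1]; y <- roi[2]; w <- roi[3]; h <- roi[4]
  if (w < 16 || h < 16) abort("ROI must be at least 16 x 16 pixels")
  if (x < 1 || y < 1 || x + w - 1 > ncol(frame) || y + h - 1 > nrow(frame)) {
    abort("ROI exceeds frame bounds")
  }
  frame[y:(y + h - 1), x:(x + w - 1)]
}

#' Exhaustive cross-correlation shift estimate (reference oracle)
#'
#' Brute-force counterpart of [poc_shift()], used as an independent oracle in
#' validation: normalised cross-correlation is evaluated over every integer
#' (circular) shift within `search_radius`, and the integer optimum is then
#' refined by direct numerical maximisation of the correlation between the
#' reference and the band-limited resampled moving frame. No phase
#' normalisation or correlation-surface model is involved, so agreement with
#' [poc_shift()] is a genuine cross-check.
#'
#' Intended for small frames (<= 256 x 256); cost grows with
#' `search_radius^2 * n_pixels`.
#'
#' @inheritParams poc_shift
#' @param search_radius Maximum absolute integer shift searched, pixels.
#' @param refine Refine to subpixel precision (default `TRUE`).
#' @return A `shift_estimate` (with `peak_value` = correlation coefficient).
#' @export
brute_force_shift <- function(reference, moving, search_radius = 8L,
                              refine = TRUE) {
  stopifnot(is.matrix(reference), is.matrix(moving))
  if (!identical(dim(reference), dim(moving))) {
    abort("`reference` and `moving` must have identical dimensions")
  }
  nr <- nrow(reference); nc <- ncol(reference)
  if (2 * search_radius >= min(nr, nc)) {
    abort("`search_radius` exceeds half the frame size")
  }
  rv <- as.vector(reference)
  best <- c(0, 0); best_c <- -Inf
  for (sy in -search_radius:search_radius) {
    ry <- wrap_index(seq_len(nr) + sy, nr)
    for (sx in -search_radius:search_radius) {
      rx <- wrap_index(seq_len(nc) + sx, nc)
      cc <- stats::cor(rv, as.vector(moving[ry, rx]))
      if (cc > best_c) { best_c <- cc; best <- c(sx, sy) }
    }
  }
  est <- as.numeric(best); peak <- best_c
  if (refine) {
    fn <- function(u) -stats::cor(rv, as.vector(fourier_shift(moving, -u[1], -u[2])))
    opt <- tryCatch(
      optim(est, fn, method = "L-BFGS-B",
            lower = est - 1, upper = est + 1, control = list(factr = 1e4)),
      error = function(e) NULL
    )
    if (!is.null(opt)) { est <- opt$par; peak <- -opt$value }
  }
  structure(
    list(dx = est[1], dy = est[2], peak_value = peak, low_confidence = FALSE,
         diagnostics = list(search_radius = search_radius, method = "ncc")),
    class = "shift_estimate"
  )
}

#' Track pillar-head displacement through a video stack
#'
#' Runs [poc_shift()] over the recording and reduces the 2-D shifts to the
#' one-dimensional pillar deflection in micrometres. Two tracking modes are
#' available: `"cumulative"` registers consecutive frame pairs and sums the
#' per-pair shifts (the default; inter-frame motion is small, so each
#' registration stays well inside the search basin, at the cost of slow error
#' accumulation), while `"fixed_reference"` registers every frame against the
#' first (no accumulation, but large excursions must stay well inside the
#' ROI).
#'
#' The 2-D shifts are projected onto `axis`; when `axis` is `NULL` it is
#' estimated as the principal axis of the shift cloud, with its sign chosen
#' so that the dominant transient excursions (contractions) are positive.
#'
#' @param video A [video_stack()].
#' @param mode `"cumulative"` or `"fixed_reference"`.
#' @param roi Optional `c(x, y, width, height)` tracking window.
#' @param axis Optional unit vector `c(x, y)` onto which displacement is
#'   projected. Default: principal axis of the estimated shifts.
#' @param peak_floor Per-pair correlation floor; pairs below it are flagged.
#' @param max_low_confidence_frac Abort if more than this fraction of frame
#'   pairs is low-confidence. Default 0.2.
#' @inheritParams poc_shift
#' @return A tibble of class `displacement_trace` with columns `frame`,
#'   `time_s`, `dx_px`, `dy_px`, `disp_um`, `peak_value`, `low_confidence`;
#'   attributes `pixel_scale_um`, `frame_rate_hz`, `mode`, `axis`. The first
#'   row is the reference frame (zero displacement by definition).
#' @export
track_stack <- function(video, mode = c("cumulative", "fixed_reference"),
                        roi = NULL, axis = NULL, window = TRUE,
                        spectral_sigma = 0.15, peak_floor = 0.3,
                        max_low_confidence_frac = 0.2) {
  stopifnot(inherits(video, "video_stack"))
  mode <- match.arg(mode)
  nf <- n_frames(video)
  dx <- dy <- numeric(nf)
  pk <- c(1, numeric(nf - 1L))
  lowc <- logical(nf)
  for (i in 2:nf) {
    ref_i <- if (mode == "cumulative") i - 1L else 1L
    est <- poc_shift(video$frames[, , ref_i], video$frames[, , i],
                     roi = roi, window = window,
                     spectral_sigma = spectral_sigma, peak_floor = peak_floor)
    if (mode == "cumulative") {
      dx[i] <- dx[i - 1L] + est$dx
      dy[i] <- dy[i - 1L] + est$dy
    } else {
      dx[i] <- est$dx
      dy[i] <- est$dy
    }
    pk[i] <- est$peak_value
    lowc[i] <- est$low_confidence
  }
  frac_low <- mean(lowc[-1])
  if (frac_low > max_low_confidence_frac) {
    abort(sprintf(
      "tracking failed: %.0f%% of frame pairs below the correlation floor %.2f",
      100 * frac_low, peak_floor))
  }
  if (any(lowc)) {
    warn(sprintf("%d low-confidence frame pair(s); see `low_confidence` column",
                 sum(lowc)))
  }
  if (is.null(axis)) {
    axis <- principal_axis(dx, dy)
  } else {
    stopifnot(is.numeric(axis), length(axis) == 2L)
    axis <- axis / sqrt(sum(axis^2))
  }
  disp_px <- dx * axis[1] + dy * axis[2]
  out <- tibble::tibble(
    frame = seq_len(nf),
    time_s = (seq_len(nf) - 1) / video$frame_rate_hz,
    dx_px = dx,
    dy_px = dy,
    disp_um = disp_px * video$pixel_scale_um,
    peak_value = pk,
    low_confidence = lowc
  )
  attr(out, "pixel_scale_um") <- video$pixel_scale_um
  attr(out, "frame_rate_hz") <- video$frame_rate_hz
  attr(out, "mode") <- mode
  attr(out, "axis") <- axis
  class(out) <- c("displacement_trace", class(out))
  out
}

# first principal component of the 2-D shift cloud, signed so that the large
# transient excursions (contractions) project positively
principal_axis <- function(dx, dy) {
  m <- cbind(dx - mean(dx), dy - mean(dy))
  if (all(abs(m) < .Machine$double.eps^0.5)) return(c(1, 0))
  ev <- eigen(crossprod(m) / nrow(m), symmetric = TRUE)$vectors[, 1]
  proj <- dx * ev[1] + dy * ev[2]
  proj <- proj - median(proj)
  if (max(proj) < -min(proj)) ev <- -ev
  ev
}
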