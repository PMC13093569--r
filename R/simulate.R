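# Synthetic recordings with exact ground truth.
#
# The generators emulate the two kinds of recording the analysis consumes:
# (a) a grayscale video of a textured pillar head whose rigid translation is
#     the beam deflection produced by a prescribed force waveform, and
# (b) a paced fluorescence trace built from per-beat transients.
# Ground truth is returned alongside (never embedded in) the recording.

#' Simulate a pillar-deflection video with known ground truth
#'
#' Renders a high-contrast textured disk (the pillar head) on a darker
#' background and translates it rigidly, frame by frame, by the beam
#' deflection \eqn{\delta(t) = P(t)/k} that the prescribed force waveform
#' produces through the cantilever model ([pillar_geometry()]). Translation
#' uses band-limited Fourier resampling, so non-integer pixel shifts are
#' rendered faithfully — the property a subpixel tracker must be tested
#' against. Multiplicative brightness drift and additive Gaussian noise are
#' applied after translation.
#'
#' The force waveform is a paced twitch train: within each pacing period the
#' load rises and falls as \eqn{\sin^2(\pi t/w)} over the twitch width `w`,
#' reaching the prescribed per-beat peak force. Defaults mirror 1 Hz field
#' stimulation recorded at 3.79 um/pixel.
#'
#' @param peak_force_n Peak force per beat in newtons; a scalar or a vector
#'   recycled over beats. May be 0 (no motion).
#' @param n_frames Number of frames (>= 2).
#' @param frame_rate_hz Acquisition rate (must exceed twice the pacing rate).
#' @param frame_shape `c(height, width)` in pixels.
#' @param pixel_scale_um Micrometres per pixel (default 3.79).
#' @param pacing_rate_hz Stimulation rate in Hz (default 1).
#' @param geometry [pillar_geometry()] used to convert force to deflection.
#' @param twitch_width_s Duration of the contraction twitch within each
#'   pacing period, seconds.
#' @param noise_sd Additive Gaussian noise SD, intensity units on the [0, 1]
#'   frame scale.
#' @param brightness_drift Fractional multiplicative brightness change per
#'   frame (e.g. 0.002 brightens each frame by 0.2% over its predecessor).
#' @param displacement_axis Unit vector (x, y) of the pillar motion in the
#'   image plane.
#' @param texture_seed Seed for the pillar texture (determines the scene).
#' @param seed Seed for the noise realisation.
#' @param pillar_radius_px Radius of the textured disk, pixels.
#' @param contrast Texture contrast above the background (0, 1]; a zero
#'   contrast would make registration ill-posed and is rejected.
#' @return A list of class `synthetic_video`:
#'   * `video` — a [video_stack()];
#'   * `truth` — tibble `frame`, `time_s`, `force_n`, `displacement_um`
#'     (exact deflection along `displacement_axis`);
#'   * `params` — all generator parameters, echoed.
#' @examples
#' sim <- simulate_pillar_video(peak_force_n = 25e-6, n_frames = 40)
#' max(sim$truth$displacement_um)  # ~83 um
#' @export
simulate_pillar_video <- function(peak_force_n = 30e-6,
                                  n_frames = 90,
                                  frame_rate_hz = 30,
                                  frame_shape = c(128, 128),
                                  pixel_scale_um = 3.79,
                                  pacing_rate_hz = 1,
                                  geometry = pillar_geometry(),
                                  twitch_width_s = 0.4,
                                  noise_sd = 0,
                                  brightness_drift = 0,
                                  displacement_axis = c(1, 0),
                                  texture_seed = 1L,
                                  seed = 1L,
                                  pillar_radius_px = 16,
                                  contrast = 0.7) {
  if (n_frames < 2) abort("`n_frames` must be >= 2")
  if (frame_rate_hz <= 2 * pacing_rate_hz) {
    abort("`frame_rate_hz` must exceed twice the pacing rate")
  }
  if (any(peak_force_n < 0)) abort("`peak_force_n` must be >= 0")
  if (pixel_scale_um <= 0) abort("`pixel_scale_um` must be positive")
  if (contrast <= 0) {
    abort("degenerate (flat) texture: `contrast` must be positive")
  }
  if (twitch_width_s >= 1 / pacing_rate_hz) {
    abort("`twitch_width_s` must be shorter than the pacing period")
  }
  axis <- displacement_axis / sqrt(sum(displacement_axis^2))

  time_s <- (seq_len(n_frames) - 1) / frame_rate_hz
  force_n <- twitch_train(time_s, peak_force_n, pacing_rate_hz, twitch_width_s)
  disp_um <- deflection_um(force_n, geometry)
  disp_px <- disp_um / pixel_scale_um

  nr <- frame_shape[1]; nc <- frame_shape[2]
  taper <- 4
  max_px <- max(disp_px)
  # centre the disk on the mid-point of its excursion
  centre <- c(nc, nr) / 2 - axis * max_px / 2
  reach <- pillar_radius_px + taper + 4
  lo <- centre + axis * min(disp_px)
  hi <- centre + axis * max_px
  if (any(c(lo, hi) < reach) || hi[1] > nc - reach || hi[2] > nr - reach ||
      lo[1] > nc - reach || lo[2] > nr - reach) {
    abort(sprintf(
      "displacement exceeds frame bounds: peak deflection %.1f px does not fit a %d x %d frame",
      max_px, nr, nc))
  }

  base <- pillar_scene(nr, nc, centre, pillar_radius_px, taper,
                       contrast, texture_seed)
  frames <- array(0, c(nr, nc, n_frames))
  noise <- if (noise_sd > 0) {
    withr::with_seed(seed, array(rnorm(nr * nc * n_frames, 0, noise_sd),
                                 c(nr, nc, n_frames)))
  } else NULL
  for (i in seq_len(n_frames)) {
    f <- fourier_shift(base, disp_px[i] * axis[1], disp_px[i] * axis[2])
    f <- f * (1 + brightness_drift)^(i - 1)
    if (!is.null(noise)) f <- f + noise[, , i]
    frames[, , i] <- f
  }

  truth <- tibble::tibble(frame = seq_len(n_frames), time_s = time_s,
                          force_n = force_n, displacement_um = disp_um)
  structure(
    list(
      video = video_stack(frames, pixel_scale_um, frame_rate_hz),
      truth = truth,
      params = list(
        peak_force_n = peak_force_n, n_frames = n_frames,
        frame_rate_hz = frame_rate_hz, frame_shape = frame_shape,
        pixel_scale_um = pixel_scale_um, pacing_rate_hz = pacing_rate_hz,
        geometry = unclass(geometry), twitch_width_s = twitch_width_s,
        noise_sd = noise_sd, brightness_drift = brightness_drift,
        displacement_axis = axis, texture_seed = texture_seed, seed = seed,
        pillar_radius_px = pillar_radius_px, contrast = contrast
      )
    ),
    class = "synthetic_video"
  )
}

#' @export
print.synthetic_video <- function(x, ...) {
  cat("<synthetic_video>\n  ")
  print(x$video)
  cat(sprintf("  peak force %s uN, peak deflection %.1f um\n",
              paste(signif(unique(x$params$peak_force_n) * 1e6, 3),
                    collapse = "/"),
              max(x$truth$displacement_um)))
  invisible(x)
}

# sin^2 twitch train; peak_force recycled over beats
twitch_train <- function(time_s, peak_force_n, pacing_rate_hz, width_s) {
  period <- 1 / pacing_rate_hz
  beat <- floor(time_s / period)
  peaks <- rep_len(peak_force_n, max(beat) + 1L)[beat + 1L]
  ph <- time_s - beat * period
  ifelse(ph < width_s, peaks * sin(pi * ph / width_s)^2, 0)
}

pillar_scene <- function(nr, nc, centre, radius, taper, contrast, seed,
                         background = 0.15) {
  tex <- random_texture(nr, nc, cutoff = 0.35, seed = seed)
  x <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  y <- matrix(rep(seq_len(nr), nc), nr, nc)
  rr <- sqrt((x - centre[1])^2 + (y - centre[2])^2)
  mask <- ifelse(rr <= radius, 1,
                 ifelse(rr >= radius + taper, 0,
                        0.5 * (1 + cos(pi * (rr - radius) / taper))))
  # gentle final band-limit keeps subpixel resampling of the composite exact
  lowpass2(background + contrast * tex * mask, cutoff = 0.4)
}

#' Simulate a paced calcium-indicator fluorescence trace
#'
#' Builds a fluorescence time series as baseline + per-beat transient +
#' linear drift + Gaussian noise. Each transient rises from the stimulus as
#' a raised cosine over `rise_time_s` to `baseline + amplitude`, then decays
#' as a single exponential `exp(-decay_rate * t)`. Stimuli occur at
#' `0, 1/f, 2/f, ...` for pacing rate `f`, so a recording of `duration_s`
#' seconds contains `floor(duration_s * pacing_rate_hz)` beats.
#'
#' Ground truth records, per beat, the generating amplitude both in intensity
#' units and as \eqn{\Delta F/F_0} against the *instantaneous* baseline
#' `baseline + drift_slope * t` (with additive drift, the baseline at the
#' time of the beat is the denominator a normalisation can actually realise),
#' the analytic onset-to-peak time (onset = 10% amplitude crossing, the
#' measurement origin used by the analysis, since stimulus timestamps are not
#' part of a trace file), the stimulus-to-peak `rise_time_s`, and the
#' 80%-decay time `log(5)/decay_rate`.
#'
#' @param duration_s Recording length, seconds.
#' @param sample_rate_hz Sampling rate (>= 20 x pacing rate). Default 100.
#' @param pacing_rate_hz Pacing rate, Hz (default 1).
#' @param baseline Resting fluorescence intensity (arbitrary units, > 0).
#' @param amplitude Transient amplitude above baseline, intensity units
#'   (>= 0; 0 gives a flat trace).
#' @param rise_time_s Stimulus-to-peak rise time, seconds
#'   (< pacing period).
#' @param decay_rate Exponential decay rate of the falling phase, 1/s.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param drift_slope Linear drift in intensity units per second (negative
#'   for photobleaching).
#' @param roi_id Label stored in the trace table.
#' @param seed Integer seed for the noise realisation.
#' @return A list of class `synthetic_trace`:
#'   * `trace` — tibble `time_s`, `intensity`, `roi_id`;
#'   * `truth` — list with `beats` (per-beat tibble: `beat`, `stim_time_s`,
#'     `onset_time_s`, `amplitude`, `amplitude_dff`, `time_to_peak_s`,
#'     `rise_time_s`, `decay80_s`) and `overlap_warning` (`TRUE` when the
#'     transient has not decayed to under 5% of its amplitude by the next
#'     stimulus);
#'   * `params` — generator parameters, echoed.
#' @examples
#' sim <- simulate_calcium_trace(noise_sd = 0, amplitude = 100,
#'                               rise_time_s = 0.1, decay_rate = 8)
#' sim$truth$beats$decay80_s[1]  # log(5)/8 ~ 0.2012 s
#' @export
simulate_calcium_trace <- function(duration_s = 13,
                                   sample_rate_hz = 100,
                                   pacing_rate_hz = 1,
                                   baseline = 100,
                                   amplitude = 100,
                                   rise_time_s = 0.15,
                                   decay_rate = 7,
                                   noise_sd = 5,
                                   drift_slope = -0.5,
                                   roi_id = "roi1",
                                   seed = 1L) {
  if (baseline <= 0) abort("`baseline` must be positive")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  if (rise_time_s <= 0 || rise_time_s >= 1 / pacing_rate_hz) {
    abort("`rise_time_s` must be positive and shorter than the pacing period")
  }
  if (decay_rate <= 0) abort("`decay_rate` must be positive")
  if (sample_rate_hz < 20 * pacing_rate_hz) {
    abort("`sample_rate_hz` must be at least 20 x the pacing rate")
  }
  period <- 1 / pacing_rate_hz
  time_s <- seq(0, duration_s - 1 / sample_rate_hz, by = 1 / sample_rate_hz)
  ph <- time_s %% period
  shape <- ifelse(ph < rise_time_s,
                  (1 - cos(pi * ph / rise_time_s)) / 2,
                  exp(-decay_rate * (ph - rise_time_s)))
  intensity <- baseline + amplitude * shape + drift_slope * time_s
  if (noise_sd > 0) {
    intensity <- intensity +
      withr::with_seed(seed, rnorm(length(time_s), 0, noise_sd))
  }
  n_beats <- floor(duration_s * pacing_rate_hz)
  stim <- (seq_len(n_beats) - 1) * period
  onset_offset <- rise_time_s * acos(0.8) / pi     # 10% crossing of the rise
  t_peak <- stim + rise_time_s
  inst_baseline <- baseline + drift_slope * t_peak
  residual <- exp(-decay_rate * (period - rise_time_s))
  beats <- tibble::tibble(
    beat = seq_len(n_beats),
    stim_time_s = stim,
    onset_time_s = stim + onset_offset,
    amplitude = amplitude,
    amplitude_dff = amplitude / inst_baseline,
    time_to_peak_s = rise_time_s - onset_offset,
    rise_time_s = rise_time_s,
    decay80_s = log(5) / decay_rate
  )
  overlap <- amplitude > 0 && residual > 0.05
  if (overlap) {
    warn(sprintf(
      "transient overlaps the next stimulus (%.1f%% of amplitude remaining)",
      100 * residual))
  }
  structure(
    list(
      trace = tibble::tibble(time_s = time_s, intensity = intensity,
                             roi_id = roi_id),
      truth = list(beats = beats, overlap_warning = overlap),
      params = list(
        duration_s = duration_s, sample_rate_hz = sample_rate_hz,
        pacing_rate_hz = pacing_rate_hz, baseline = baseline,
        amplitude = amplitude, rise_time_s = rise_time_s,
        decay_rate = decay_rate, noise_sd = noise_sd,
        drift_slope = drift_slope, roi_id = roi_id, seed = seed
      )
    ),
    class = "synthetic_trace"
  )
}

#' @export
print.synthetic_trace <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<synthetic_trace> %g s at %g Hz, %g Hz pacing, %d beats (dF/F0 ~ %.2f)\n",
    p$duration_s, p$sample_rate_hz, p$pacing_rate_hz,
    nrow(x$truth$beats), p$amplitude / p$baseline))
  invisible(x)
}

#' Simulate a two-group cohort of recordings with prescribed effect sizes
#'
#' Draws per-member generator parameters for a control and a disease group
#' and (optionally) renders each recording. The headline magnitude parameter
#' (`peak_force_n` for videos, `amplitude` for traces) varies across members
#' as a truncated Gaussian with coefficient of variation `tissue_cv` around
#' the group mean; trace kinetics (`rise_time_s`, `decay_rate`) vary with
#' half that CV. Group effect sizes are prescribed entirely by the two
#' parameter lists, and sub-seeds are derived deterministically from `seed`,
#' so the same call reproduces the same cohort exactly.
#'
#' @param n_per_group Members per group (>= 2).
#' @param what `"video"` (pillar videos) or `"trace"` (calcium traces).
#' @param control,disease Named lists of generator-parameter overrides for
#'   each group (see [simulate_pillar_video()] / [simulate_calcium_trace()]).
#' @param tissue_cv Between-member coefficient of variation of the headline
#'   magnitude parameter. Default 0.15.
#' @param seed Master seed.
#' @param render If `TRUE` (default for traces) the recordings are generated
#'   and returned in a list-column; if `FALSE` only the drawn parameters and
#'   ground truth summaries are returned (videos are expensive to render).
#' @return A list of class `synthetic_cohort` with `members` (tibble: group,
#'   member id, drawn parameters, and `recording` list-column when rendered)
#'   and `prescribed` (the two group parameter sets and, for the headline
#'   parameter, the prescribed disease/control ratio).
#' @examples
#' coh <- simulate_cohort(3, what = "trace",
#'                        control = list(amplitude = 100),
#'                        disease = list(amplitude = 60),
#'                        render = FALSE, seed = 7)
#' coh$prescribed$ratio  # 0.6
#' @export
simulate_cohort <- function(n_per_group = 5,
                            what = c("video", "trace"),
                            control = list(),
                            disease = list(),
                            tissue_cv = 0.15,
                            seed = 1L,
                            render = (what == "trace")) {
  what <- match.arg(what)
  if (n_per_group < 2) abort("`n_per_group` must be >= 2")
  headline <- if (what == "video") "peak_force_n" else "amplitude"
  defaults <- if (what == "video") {
    formals(simulate_pillar_video)
  } else {
    formals(simulate_calcium_trace)
  }
  base_of <- function(overrides) {
    modifyList(list(), overrides)
  }
  groups <- list(control = base_of(control), disease = base_of(disease))
  mean_of <- function(pars) {
    if (!is.null(pars[[headline]])) pars[[headline]]
    else eval(defaults[[headline]])
  }
  sub_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max - 1L,
                                           2L * n_per_group + 1L))
  rows <- list()
  k <- 0L
  for (g in names(groups)) {
    gmean <- mean_of(groups[[g]])
    for (j in seq_len(n_per_group)) {
      k <- k + 1L
      s <- sub_seeds[k]
      draws <- withr::with_seed(s, rnorm(3))
      magnitude <- gmean * max(0.05, 1 + tissue_cv * draws[1])
      pars <- groups[[g]]
      pars[[headline]] <- magnitude
      pars$seed <- s
      if (what == "trace") {
        rt <- if (!is.null(pars$rise_time_s)) pars$rise_time_s
              else eval(defaults$rise_time_s)
        dr <- if (!is.null(pars$decay_rate)) pars$decay_rate
              else eval(defaults$decay_rate)
        pars$rise_time_s <- rt * max(0.2, 1 + tissue_cv / 2 * draws[2])
        pars$decay_rate <- dr * max(0.2, 1 + tissue_cv / 2 * draws[3])
        pars$roi_id <- sprintf("%s_%02d", g, j)
      } else {
        pars$texture_seed <- s
      }
      rows[[k]] <- tibble::tibble(
        group = g, member = j, !!headline := magnitude,
        params = list(pars)
      )
    }
  }
  members <- dplyr::bind_rows(rows)
  if (render) {
    gen <- if (what == "video") simulate_pillar_video else simulate_calcium_trace
    members$recording <- purrr::map(members$params, ~ do.call(gen, .x))
  }
  structure(
    list(
      members = members,
      prescribed = list(
        what = what,
        control = groups$control, disease = groups$disease,
        headline = headline,
        ratio = mean_of(groups$disease) / mean_of(groups$control),
        tissue_cv = tissue_cv, seed = seed
      )
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %s, %d per group, prescribed %s ratio %.3g, cv %.2f\n",
    x$prescribed$what, nrow(x$members) / 2, x$prescribed$headline,
    x$prescribed$ratio, x$prescribed$tissue_cv))
  invisible(x)
}

#' Draw per-tissue peak-force measurements for a two-group design
#'
#' Feature-level counterpart of [simulate_cohort()] for simulation studies of
#' the statistical harness (type-I error, power): per-tissue true peak forces
#' are Gaussian around the group mean with coefficient of variation
#' `tissue_cv`, and the measured value adds the pipeline's small relative
#' measurement error (`measurement_cv`; end-to-end tracking recovers forces
#' to within a few percent, see the validation suite).
#'
#' @param n_per_group Tissues per group.
#' @param control_mean_n,disease_mean_n Group mean peak force, newtons.
#' @param tissue_cv Between-tissue CV of true force. Default 0.15.
#' @param measurement_cv Relative SD of the measurement step. Default 0.02.
#' @param seed Integer seed.
#' @return Tibble with `group`, `tissue`, `force_n`.
#' @export
simulate_force_samples <- function(n_per_group = 5,
                                   control_mean_n = 30e-6,
                                   disease_mean_n = 15e-6,
                                   tissue_cv = 0.15,
                                   measurement_cv = 0.02,
                                   seed = 1L) {
  if (n_per_group < 2) abort("`n_per_group` must be >= 2")
  withr::with_seed(seed, {
    draw <- function(mean_n, g) {
      true <- pmax(0, rnorm(n_per_group, mean_n, tissue_cv * mean_n))
      meas <- true * (1 + rnorm(n_per_group, 0, measurement_cv))
      tibble::tibble(group = g, tissue = seq_len(n_per_group), force_n = meas)
    }
    dplyr::bind_rows(draw(control_mean_n, "control"),
                     draw(disease_mean_n, "disease"))
  })
}
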