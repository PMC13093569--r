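#' Convert a displacement trace to a force trace
#'
#' Applies the cantilever relation `P(t) = k * delta(t)` with
#' `k = 3EI/L^3` from [pillar_geometry()]. The diastolic (resting)
#' displacement offset — the median of the lowest decile of the trace — is
#' subtracted first, so force is measured relative to the relaxed pillar
#' position; the unsubtracted (absolute) force is kept in `force_raw_n`.
#' The linear beam formula assumes small deflections; a warning is emitted
#' if any deflection exceeds 10% of the pillar length.
#'
#' @param trace A `displacement_trace` from [track_stack()], or any data
#'   frame with `time_s` and `disp_um` columns.
#' @param geometry A [pillar_geometry()].
#' @param baseline `"lowest_decile"` (default: median of the lowest decile
#'   of displacement) or `"none"` (absolute displacement from the reference
#'   frame).
#' @return A tibble of class `force_trace` with `time_s`, `disp_um`,
#'   `force_n` (baseline-subtracted) and `force_raw_n`; attributes carry the
#'   geometry and the baseline displacement used.
#' @examples
#' tr <- tibble::tibble(time_s = 0:9 / 10, disp_um = c(rep(0, 5), rep(100, 5)))
#' max(displacement_to_force(tr)$force_n)  # ~3e-5 N (30 uN)
#' @export
displacement_to_force <- function(trace, geometry = pillar_geometry(),
                                  baseline = c("lowest_decile", "none")) {
  baseline <- match.arg(baseline)
  if (!all(c("time_s", "disp_um") %in% names(trace))) {
    abort("`trace` needs `time_s` and `disp_um` columns")
  }
  if (nrow(trace) < 2) abort("`trace` must have at least 2 rows")
  if (!all(is.finite(trace$disp_um))) abort("non-finite displacement values")
  k <- bending_stiffness(geometry)
  disp <- trace$disp_um
  base_um <- if (baseline == "lowest_decile") {
    median(disp[disp <= quantile(disp, 0.1)])
  } else 0
  if (max(abs(disp)) * 1e-6 > 0.1 * geometry$length_m) {
    warn("deflection exceeds 10% of pillar length; linear beam model is inaccurate")
  }
  out <- tibble::tibble(
    time_s = trace$time_s,
    disp_um = disp,
    force_n = k * (disp - base_um) * 1e-6,
    force_raw_n = k * disp * 1e-6
  )
  attr(out, "geometry") <- geometry
  attr(out, "baseline_um") <- base_um
  class(out) <- c("force_trace", class(out))
  out
}

#' Per-beat contraction metrics from a force trace
#'
#' Segments the recording into pacing-period windows anchored to the
#' contraction phase estimated from the trace itself (no stimulus log is
#' assumed) and reports one force peak per window, their mean, and the
#' single maximum over the recording — the force at maximum pillar
#' deflection. Peaks must exceed a prominence threshold (default
#' `noise_mult` times the baseline noise SD, estimated from first
#' differences of the trace); a quiescent recording yields an explicit
#' "no beats" result rather than zeros.
#'
#' @param force A `force_trace` from [displacement_to_force()] (or a data
#'   frame with `time_s` and `force_n`).
#' @param pacing_rate_hz Pacing rate used to window the trace, Hz.
#' @param noise_mult Prominence threshold in units of baseline noise SD
#'   (default 3).
#' @param min_prominence_n Absolute floor for the prominence threshold, in
#'   newtons (guards the noiseless case, where the estimated noise SD is 0).
#' @return An object of class `beat_metrics`: list with `beats` (tibble:
#'   `beat`, `time_s`, `peak_force_n`), `n_beats`, `mean_peak_force_n`,
#'   `max_force_n`, `baseline_force_n`, and `detected` (`FALSE` for the
#'   explicit no-beats result).
#' @examples
#' sim <- simulate_pillar_video(n_frames = 60)
#' fr <- displacement_to_force(track_stack(sim$video))
#' beat_metrics(fr, pacing_rate_hz = 1)
#' @export
beat_metrics <- function(force, pacing_rate_hz, noise_mult = 3,
                         min_prominence_n = 1e-9) {
  if (!all(c("time_s", "force_n") %in% names(force))) {
    abort("`force` needs `time_s` and `force_n` columns")
  }
  if (pacing_rate_hz <= 0) abort("`pacing_rate_hz` must be positive")
  t <- force$time_s
  f <- force$force_n
  period <- 1 / pacing_rate_hz
  dt <- median(diff(t))
  # baseline noise from the quiescent part of the trace: first differences
  # are insensitive to the slow contractile waveform
  noise_sd <- sd(diff(f)) / sqrt(2)
  prominence <- max(noise_mult * noise_sd, min_prominence_n)
  baseline_n <- median(f[f <= quantile(f, 0.25)])
  rng <- max(f) - baseline_n
  if (!is.finite(rng) || rng < prominence) {
    return(structure(
      list(beats = tibble::tibble(beat = integer(), time_s = numeric(),
                                  peak_force_n = numeric()),
           n_beats = 0L, mean_peak_force_n = NA_real_,
           max_force_n = NA_real_, baseline_force_n = baseline_n,
           detected = FALSE, pacing_rate_hz = pacing_rate_hz),
      class = "beat_metrics"
    ))
  }
  # anchor the window grid to the contraction phase: phase of the global
  # maximum, shifted half a period back
  t_ref <- t[which.max(f)]
  phase0 <- (t_ref - period / 2) %% period
  starts <- seq(t[1] + phase0 - period, max(t), by = period)
  rows <- list()
  for (s in starts) {
    sel <- which(t >= s & t < s + period)
    if (length(sel) < 3) next
    ipl <- which.max(f[sel])
    if (ipl == 1L || ipl == length(sel)) next  # peak clipped at a window edge
    ip <- sel[ipl]
    if (f[ip] - baseline_n < prominence) next
    rows[[length(rows) + 1L]] <- tibble::tibble(
      time_s = t[ip], peak_force_n = f[ip])
  }
  beats <- dplyr::bind_rows(rows)
  if (nrow(beats) == 0L) {
    return(structure(
      list(beats = tibble::tibble(beat = integer(), time_s = numeric(),
                                  peak_force_n = numeric()),
           n_beats = 0L, mean_peak_force_n = NA_real_,
           max_force_n = NA_real_, baseline_force_n = baseline_n,
           detected = FALSE, pacing_rate_hz = pacing_rate_hz),
      class = "beat_metrics"
    ))
  }
  beats <- dplyr::mutate(beats, beat = dplyr::row_number(),
                         .before = "time_s")
  structure(
    list(beats = beats,
         n_beats = nrow(beats),
         mean_peak_force_n = mean(beats$peak_force_n),
         max_force_n = max(beats$peak_force_n),
         baseline_force_n = baseline_n,
         detected = TRUE,
         pacing_rate_hz = pacing_rate_hz),
    class = "beat_metrics"
  )
}

#' @export
print.beat_metrics <- function(x, ...) {
  if (!x$detected) {
    cat("<beat_metrics> no beats detected\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<beat_metrics> %d beats: mean peak %.2f uN, max %.2f uN\n",
    x$n_beats, x$mean_peak_force_n * 1e6, x$max_force_n * 1e6))
  invisible(x)
}

#' @rdname beat_metrics
#' @param x A `beat_metrics` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.beat_metrics <- function(x, ...) {
  x$beats
}

#' @rdname beat_metrics
#' @exportS3Method generics::glance
glance.beat_metrics <- function(x, ...) {
  tibble::tibble(
    n_beats = x$n_beats,
    mean_peak_force_n = x$mean_peak_force_n,
    max_force_n = x$max_force_n,
    baseline_force_n = x$baseline_force_n,
    detected = x$detected
  )
}
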