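#' Pillar geometry for the cantilever-beam force model
#'
#' An EHT strip is suspended between two elastic PDMS pillars; tissue
#' contraction bends the pillars. Each pillar is modelled as a cantilever beam
#' with a concentrated load `P` at its free end, so the tip deflection is
#' \deqn{\delta = \frac{P L^3}{3 E I}, \qquad I = \frac{\pi d^4}{64},}
#' where `L` is the pillar length, `E` the Young's modulus of the PDMS and
#' `d` the pillar diameter (circular cross-section). The derived bending
#' stiffness `k = 3EI/L^3` (N/m) converts measured deflection directly into
#' force.
#'
#' Defaults are the dimensions of the reference pillar platform:
#' `L` = 12 mm, `E` = 1.7 MPa, `d` = 1.2 mm, giving `k` of roughly 0.30 N/m
#' (1 um of tip deflection corresponds to about 0.30 uN).
#'
#' @param length_m Pillar length \eqn{L} in metres.
#' @param youngs_modulus_pa Young's modulus \eqn{E} of the pillar material in
#'   pascals.
#' @param diameter_m Pillar diameter \eqn{d} in metres.
#'
#' @return An object of class `pillar_geometry`: a list with fields
#'   `length_m`, `youngs_modulus_pa`, `diameter_m`, the derived area moment of
#'   inertia `inertia_m4` and bending stiffness `stiffness_n_per_m`.
#' @examples
#' geom <- pillar_geometry()
#' geom$stiffness_n_per_m        # ~0.300 N/m
#' bending_stiffness(geom)
#' @export
pillar_geometry <- function(length_m = 12e-3,
                            youngs_modulus_pa = 1.7e6,
                            diameter_m = 1.2e-3) {
  for (nm in c("length_m", "youngs_modulus_pa", "diameter_m")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive finite number.", nm))
    }
  }
  inertia <- pi * diameter_m^4 / 64
  structure(
    list(
      length_m = length_m,
      youngs_modulus_pa = youngs_modulus_pa,
      diameter_m = diameter_m,
      inertia_m4 = inertia,
      stiffness_n_per_m = 3 * youngs_modulus_pa * inertia / length_m^3
    ),
    class = "pillar_geometry"
  )
}

#' Bending stiffness of a pillar
#'
#' Returns `k = 3EI/L^3` in N/m, the force per unit tip deflection of the
#' cantilever. Pure function of the geometry.
#'
#' @param geometry A [pillar_geometry()] object.
#' @return Bending stiffness in N/m (scalar).
#' @examples
#' bending_stiffness(pillar_geometry())  # ~0.3004
#' @export
bending_stiffness <- function(geometry = pillar_geometry()) {
  stopifnot(inherits(geometry, "pillar_geometry"))
  geometry$stiffness_n_per_m
}

#' Tip deflection produced by a given end load
#'
#' Inverse of the force readout: `delta = P / k` with `k = 3EI/L^3`. Used by
#' the synthetic-video generator to turn a prescribed force waveform into the
#' displacement ground truth.
#'
#' @param force_n Applied end load in newtons (vectorised).
#' @param geometry A [pillar_geometry()] object.
#' @return Deflection in micrometres, same length as `force_n`.
#' @examples
#' deflection_um(30e-6)  # ~99.9 um for the default pillar
#' @export
deflection_um <- function(force_n, geometry = pillar_geometry()) {
  stopifnot(inherits(geometry, "pillar_geometry"), is.numeric(force_n))
  force_n / bending_stiffness(geometry) * 1e6
}

#' @export
print.pillar_geometry <- function(x, ...) {
  cat("<pillar_geometry>\n")
  cat(sprintf("  L = %g mm, E = %g MPa, d = %g mm\n",
              x$length_m * 1e3, x$youngs_modulus_pa / 1e6, x$diameter_m * 1e3))
  cat(sprintf("  I = %.4e m^4,  k = 3EI/L^3 = %.4f N/m\n",
              x$inertia_m4, x$stiffness_n_per_m))
  invisible(x)
}
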