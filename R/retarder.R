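#' Mueller matrix of an ideal linear retarder
#'
#' Builds the 4x4 Mueller matrix of a non-depolarizing linear retarder with
#' retardance `R` and fast-axis orientation `alpha` (both degrees). With
#' `c = cos(2 alpha)` and `s = sin(2 alpha)` the polarization block is the
#' rotation by `R` of the Poincare sphere about the equatorial axis `(c, s, 0)`:
#'
#' \preformatted{
#'   | 1  0              0              0       |
#'   | 0  c^2+s^2 cosR   cs(1-cosR)   -s sinR  |
#'   | 0  cs(1-cosR)     s^2+c^2 cosR  c sinR  |
#'   | 0  s sinR        -c sinR        cosR    |
#' }
#'
#' The sign convention (`m14 = -s sinR`) is fixed so that right-circular input
#' through a retarder at `alpha = 0` emerges with its phasor phase at +90
#' degrees; see the methods vignette.
#'
#' @param R retardance in degrees.
#' @param alpha fast-axis orientation in degrees.
#' @return a 4x4 numeric matrix.
#' @export
#' @examples
#' retarder_mueller(0, 13)            # identity
#' retarder_mueller(180, 0)           # diag(1, 1, -1, -1): half-wave plate
retarder_mueller <- function(R, alpha) {
  if (!is.finite(R) || !is.finite(alpha)) stopf("R and alpha must be finite")
  Rr <- deg2rad(R)
  c2 <- cos(2 * deg2rad(alpha))
  s2 <- sin(2 * deg2rad(alpha))
  cR <- cos(Rr)
  sR <- sin(Rr)
  rbind(c(1, 0, 0, 0),
        c(0, c2^2 + s2^2 * cR, c2 * s2 * (1 - cR), -s2 * sR),
        c(0, c2 * s2 * (1 - cR), s2^2 + c2^2 * cR, c2 * sR),
        c(0, s2 * sR, -c2 * sR, cR))
}

#' Specify a retarder by optical parameters
#'
#' A `retarder_spec` carries retardance and fast-axis orientation, optionally
#' derived from (and checked against) the physical triple birefringence /
#' thickness / wavelength.
#'
#' @param R retardance; degrees unless `unit = "radians"`. May be omitted when
#'   the physical triple is given.
#' @param alpha fast-axis orientation, degrees; folded into `(-90, 90]`.
#' @param delta_n optional birefringence `n_e - n_o` (dimensionless).
#' @param thickness_um optional thickness in micrometres.
#' @param wavelength_nm optional wavelength in nanometres.
#' @param unit unit of `R`: `"degrees"` (default) or `"radians"`.
#' @return an object of class `"retarder_spec"`: a list with elements `R`
#'   (degrees, unwrapped) and `alpha` (degrees), plus the physical triple when
#'   supplied.
#' @export
#' @examples
#' retarder_spec(alpha = 0, delta_n = 0.0017, thickness_um = 50,
#'               wavelength_nm = 808)   # a 37.9 degree collagen-like layer
retarder_spec <- function(R = NULL, alpha, delta_n = NULL, thickness_um = NULL,
                          wavelength_nm = NULL, unit = c("degrees", "radians")) {
  unit <- match.arg(unit)
  phys <- !is.null(delta_n) && !is.null(thickness_um) && !is.null(wavelength_nm)
  if (!is.null(R) && unit == "radians") R <- rad2deg(R)
  if (phys) {
    R_phys <- retardance_from_physical(delta_n, thickness_um, wavelength_nm)
    if (is.null(R)) R <- R_phys
    else if (abs(R - R_phys) > 1e-6)
      stopf("inconsistent spec: R = %.4f deg but 360*delta_n*e/lambda = %.4f deg",
            R, R_phys)
  }
  if (is.null(R)) stopf("either R or the full physical triple must be given")
  if (!is.finite(R) || !is.finite(alpha)) stopf("R and alpha must be finite")
  out <- list(R = R, alpha = fold_orientation(alpha))
  if (phys) out[c("delta_n", "thickness_um", "wavelength_nm")] <-
      list(delta_n, thickness_um, wavelength_nm)
  structure(out, class = "retarder_spec")
}

#' @export
print.retarder_spec <- function(x, ...) {
  cat(sprintf("<retarder_spec> R = %.3f deg, alpha = %.3f deg\n", x$R, x$alpha))
  if (!is.null(x$delta_n))
    cat(sprintf("  delta_n = %g, e = %g um, lambda = %g nm\n",
                x$delta_n, x$thickness_um, x$wavelength_nm))
  invisible(x)
}

#' Retardance of a birefringent slab
#'
#' `R = 360 * delta_n * e / lambda` degrees, i.e. the accumulated phase delay
#' between the fast and slow axes. The value is returned unwrapped and may
#' exceed 360 degrees for thick samples; see [wrap_retardance()].
#'
#' @param delta_n birefringence `n_e - n_o`.
#' @param thickness_um slab thickness in micrometres.
#' @param wavelength_nm wavelength in nanometres.
#' @return retardance in degrees.
#' @export
#' @examples
#' retardance_from_physical(0.0017, 50, 808) # 37.87 degrees
retardance_from_physical <- function(delta_n, thickness_um, wavelength_nm) {
  if (!is.finite(delta_n)) stopf("delta_n must be finite")
  if (!is.finite(thickness_um) || thickness_um <= 0)
    stopf("thickness must be positive")
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0)
    stopf("wavelength must be positive")
  360 * delta_n * thickness_um * 1000 / wavelength_nm
}

#' Wrap an absolute retardance into the measurable range
#'
#' A polarimeter only observes retardance modulo a full wave, and values above
#' half a wave alias onto `360 - R`. The wrapped value therefore lives on
#' `[0, 180]` degrees.
#'
#' @param R_abs absolute (unwrapped) retardance in degrees, non-negative.
#' @return retardance folded into `[0, 180]` degrees.
#' @export
#' @examples
#' wrap_retardance(275.4) # 84.6
wrap_retardance <- function(R_abs) {
  if (any(!is.finite(R_abs)) || any(R_abs < 0))
    stopf("absolute retardance must be finite and non-negative")
  r <- R_abs %% 360
  ifelse(r <= 180, r, 360 - r)
}

#' Double-pass (epi-geometry) retardance correction
#'
#' In reflection imaging the beam traverses the sample twice and picks up a pi
#' dephasing at the mirror, so the retardance measured on `[0, 360]` relates to
#' the single-pass value by `R_exact = 360 - R_measured`. This is an opt-in
#' correction applied after estimation, never baked into the simulators.
#'
#' @param R_measured measured retardance in degrees, on `[0, 360]`.
#' @return corrected retardance in degrees.
#' @export
double_pass_correct <- function(R_measured) {
  if (any(!is.finite(R_measured)) || any(R_measured < 0) || any(R_measured > 360))
    stopf("measured retardance must lie in [0, 360] degrees")
  360 - R_measured
}

#' Mueller matrix of a stack of linear retarders
#'
#' Multiplies the Mueller matrices of successive retarding layers. The first
#' layer in the list is the first one traversed by the light, so the product is
#' `M_N ... M_2 M_1` (each new layer multiplies from the left). Such a stack
#' is in general an elliptical retarder: the equivalent rotation axis of the
#' composite acquires a circular component when the layer axes differ.
#'
#' @param layers a list of [retarder_spec()] objects, or a numeric vector of
#'   retardances (degrees) when `alpha` is given.
#' @param alpha optional numeric vector of orientations (degrees), recycled
#'   against `layers` when `layers` is numeric.
#' @param reverse multiply in reversed traversal order (first layer leftmost);
#'   useful for order-sensitivity studies.
#' @return a 4x4 Mueller matrix.
#' @export
#' @examples
#' # two co-axial quarter-wave layers make a half-wave plate
#' layered_mueller(c(90, 90), alpha = c(10, 10))
layered_mueller <- function(layers, alpha = NULL, reverse = FALSE) {
  if (is.numeric(layers)) {
    if (is.null(alpha)) stopf("alpha is required when layers is a numeric vector")
    n <- max(length(layers), length(alpha))
    R <- rep_len(layers, n)
    a <- rep_len(alpha, n)
    layers <- Map(function(r, aa) retarder_spec(R = r, alpha = aa), R, a)
  }
  if (!length(layers)) stopf("layer list must be non-empty")
  M <- diag(4)
  for (spec in layers) {
    L <- retarder_mueller(spec$R, spec$alpha)
    M <- if (reverse) M %*% L else L %*% M
  }
  M
}
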