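#' Build a Stokes vector from polarization-resolved intensities
#'
#' Assembles `(S0, S1, S2, S3)` from the six canonical analyzer readings.
#' The basis is right-handed, detector view: `S1 = I_H - I_V`,
#' `S2 = I_45 - I_135`, `S3 = I_RCP - I_LCP`.
#'
#' @param I0,I45,I90,I135 linear analyzer intensities at 0, 45, 90, 135
#'   degrees (arbitrary units, non-negative).
#' @param I_RCP,I_LCP right and left circular analyzer intensities.
#' @return numeric length-4 Stokes vector `c(S0, S1, S2, S3)` with
#'   `S0 = I0 + I90`.
#' @seealso [intensities_from_stokes()] for the inverse linear readout.
#' @export
#' @examples
#' stokes_from_intensities(1, 0.5, 0, 0.5, 0.5, 0.5) # pure horizontal light
stokes_from_intensities <- function(I0, I45, I90, I135, I_RCP, I_LCP) {
  vals <- c(I0, I45, I90, I135, I_RCP, I_LCP)
  if (any(!is.finite(vals))) stopf("intensities must be finite")
  if (any(vals < 0)) stopf("negative intensity is not a valid analyzer reading")
  c(S0 = I0 + I90, S1 = I0 - I90, S2 = I45 - I135, S3 = I_RCP - I_LCP)
}

#' Linear analyzer intensities implied by a Stokes vector
#'
#' Projects a Stokes vector onto ideal linear analyzers at 0, 90, 45 and 135
#' degrees: `I_theta = (S0 + S1 cos 2theta + S2 sin 2theta) / 2`. Partially or
#' unphysically polarized vectors are accepted; the result may then contain
#' negative "intensities", which is flagged via the `"unphysical"` attribute
#' rather than rejected.
#'
#' @param S numeric length-4 Stokes vector.
#' @return named vector `c(I0, I90, I45, I135)`.
#' @export
intensities_from_stokes <- function(S) {
  stopifnot(length(S) == 4)
  out <- c(I0   = (S[[1]] + S[[2]]) / 2,
           I90  = (S[[1]] - S[[2]]) / 2,
           I45  = (S[[1]] + S[[3]]) / 2,
           I135 = (S[[1]] - S[[3]]) / 2)
  if (any(out < 0)) attr(out, "unphysical") <- TRUE
  out
}

#' Propagate a Stokes vector through a Mueller matrix
#'
#' @param M a 4x4 Mueller matrix.
#' @param S numeric length-4 input Stokes vector.
#' @return the output Stokes vector `M %*% S` as a plain numeric vector.
#' @export
#' @examples
#' propagate(retarder_mueller(180, 0), c(1, 0, 0, 1)) # half-wave plate flips RCP
propagate <- function(M, S) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4)))
    stopf("M must be a 4x4 matrix")
  stopifnot(length(S) == 4)
  drop(M %*% as.numeric(S))
}

#' Degree of polarization of a Stokes vector
#'
#' @param S numeric length-4 Stokes vector with `S0 > 0`.
#' @return `sqrt(S1^2 + S2^2 + S3^2) / S0`. Values slightly above 1 occur for
#'   noisy experimental vectors and are returned as-is.
#' @export
degree_of_polarization <- function(S) {
  stopifnot(length(S) == 4)
  if (S[[1]] <= 0) stopf("S0 must be positive")
  sqrt(S[[2]]^2 + S[[3]]^2 + S[[4]]^2) / S[[1]]
}
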