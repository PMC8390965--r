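#' Ideal polarization state analyzer (PSA) projections
#'
#' Rows are the analyzer Stokes (projection) vectors for H, V, 45-degree and
#' right-circular analysis, each `0.5 * (1, q)` with `q` the unit Poincare
#' vector of the analyzed state, so that an analyzer applied to a Stokes
#' vector yields a detected intensity.
#'
#' @return a 4x4 matrix with rows named `H`, `V`, `45`, `RCP`.
#' @export
psa_states <- function() {
  A <- 0.5 * rbind(H = c(1, 1, 0, 0), V = c(1, -1, 0, 0),
                   `45` = c(1, 0, 1, 0), RCP = c(1, 0, 0, 1))
  colnames(A) <- c("S0", "S1", "S2", "S3")
  A
}

#' Polarimeter instrument model
#'
#' Bundles the generator states `W` (4 Stokes columns), the analyzer
#' projections `A` (4 rows) and an optional per-element Gaussian noise model
#' `sigma` (a 4x4 matrix of standard deviations on the m00-normalized Mueller
#' scale). A complete polarimeter needs both `W` and `A` invertible; the
#' conditioning of each is reported by [condition_number()].
#'
#' @param W 4x4 matrix of input Stokes vectors as columns.
#' @param A 4x4 matrix of analyzer projection vectors as rows.
#' @param sigma optional 4x4 matrix of element noise SDs (`sigma[1,1]` is
#'   forced to 0: m00 defines the normalization). Use [air_sigma()] for the
#'   bundled experimental air noise level.
#' @return an object of class `"instrument_model"`.
#' @export
instrument_model <- function(W = psg_states(), A = psa_states(), sigma = NULL) {
  stopifnot(is.matrix(W), all(dim(W) == 4), is.matrix(A), all(dim(A) == 4))
  if (!is.null(sigma)) {
    stopifnot(is.matrix(sigma), all(dim(sigma) == 4))
    if (any(sigma < 0)) stopf("noise SDs must be non-negative")
    sigma[1, 1] <- 0
  }
  if (!is.finite(condition_number(W)))
    warning("PSG state matrix W is singular; reconstruction will fail")
  if (!is.finite(condition_number(t(A))))
    warning("PSA projection matrix A is singular; reconstruction will fail")
  structure(list(W = W, A = A, sigma = sigma), class = "instrument_model")
}

#' @export
print.instrument_model <- function(x, ...) {
  cat("<instrument_model>\n")
  cat(sprintf("  condition number: PSG %.3f, PSA %.3f\n",
              condition_number(x$W), condition_number(t(x$A))))
  cat("  noise:", if (is.null(x$sigma)) "none" else
    sprintf("per-element Gaussian, max SD %.3g", max(x$sigma)), "\n")
  invisible(x)
}

#' Condition number of a polarimeter state set
#'
#' The 2-norm condition number of the matrix whose columns are the four
#' generated (or analyzed) Stokes states. It bounds the noise amplification
#' of the Mueller-matrix reconstruction; the ideal H/V/45/RCP set gives 3.23.
#'
#' @param states a 4x4 matrix of Stokes columns.
#' @return the condition number; `Inf` for a rank-deficient set.
#' @export
#' @examples
#' condition_number(psg_states())
condition_number <- function(states) {
  stopifnot(is.matrix(states), all(dim(states) == 4))
  d <- svd(states, nu = 0, nv = 0)$d
  if (min(d) <= max(d) * 1e-12) return(Inf)
  max(d) / min(d)
}

#' Simulate a 16-channel polarimetric measurement
#'
#' Projects a Mueller image through the instrument: for input state `p` and
#' analyzer `a` the detected intensity is `I[a, p] = A[a, ] %*% M(x, y) %*%
#' W[, p]`. When the instrument carries a noise model, a fresh Gaussian error
#' matrix is added to each pixel's Mueller matrix before projection.
#'
#' @param img a `mueller_image` or 4x4 matrix.
#' @param inst an [instrument_model()].
#' @param seed optional integer seed for the noise draws (the caller's RNG
#'   state is restored afterwards).
#' @return an object of class `"intensity_stack"`: array `c(h, w, 4, 4)`
#'   indexed `[ , , analyzer, input]` with dimnames from the instrument.
#' @export
simulate_measurement <- function(img, inst = instrument_model(), seed = NULL) {
  img <- as_mueller_image(img)
  d <- dim(img)
  flat <- mm_flatten(img)
  if (!is.null(inst$sigma)) {
    flat <- with_seed(seed, {
      n <- nrow(flat)
      noise <- matrix(rnorm(n * 16L, 0, rep(as.numeric(inst$sigma), each = n)),
                      n, 16)
      flat + noise
    })
  }
  # I = A M W per pixel; vec(I) = (t(W) %x% A) vec(M)
  Tm <- t(inst$W) %x% inst$A
  I_flat <- flat %*% t(Tm)
  out <- array(I_flat, c(d[1], d[2], 4, 4))
  dimnames(out) <- list(NULL, NULL, rownames(inst$A), colnames(inst$W))
  structure(out, class = "intensity_stack", instrument = inst)
}

#' Reconstruct a Mueller image from 16 measured intensities
#'
#' Inverts the projection of [simulate_measurement()]: per pixel,
#' `M = solve(A) %*% I %*% solve(W)` with `I` the 4x4 intensity matrix
#' indexed (analyzer, input).
#'
#' @param I an `intensity_stack` (or bare `c(h, w, 4, 4)` array indexed
#'   `[ , , analyzer, input]`).
#' @param inst the [instrument_model()] describing the acquisition.
#' @return a `mueller_image`.
#' @export
reconstruct_mueller <- function(I, inst = instrument_model()) {
  if (!(is.array(I) && length(dim(I)) == 4 && all(dim(I)[3:4] == 4)))
    stopf("I must be an h x w x 4 x 4 intensity stack")
  if (!is.finite(condition_number(inst$W)))
    stopf("PSG state matrix W is singular")
  if (!is.finite(condition_number(t(inst$A))))
    stopf("PSA projection matrix A is singular")
  d <- dim(I)
  flat <- matrix(as.numeric(I), d[1] * d[2], 16)
  Tinv <- solve(t(inst$W)) %x% solve(inst$A)
  mm_unflatten(flat %*% t(Tinv), d[1], d[2])
}

#' Remove the microscope polarimetric fingerprint
#'
#' The raw measurement of sample plus microscope relates to the sample alone
#' by right-multiplication with the inverse of the microscope-only Mueller
#' image: `M_sample(x, y) = M_mes(x, y) %*% solve(M_mu(x, y))`, applied per
#' pixel. Pixels where the fingerprint is numerically singular are masked
#' (set to `NA`) and counted, never fatal.
#'
#' @param M_mes measured `mueller_image` (sample + microscope).
#' @param M_mu microscope-only `mueller_image` (a single matrix is recycled
#'   over all pixels).
#' @return a `mueller_image` with attribute `n_masked` giving the number of
#'   singular pixels.
#' @export
correct_microscope <- function(M_mes, M_mu) {
  M_mes <- as_mueller_image(M_mes)
  d <- dim(M_mes)
  single <- FALSE
  if (is.matrix(M_mu)) { single <- TRUE } else M_mu <- as_mueller_image(M_mu)
  if (!single && !all(dim(M_mu)[1:2] == d[1:2]))
    stopf("fingerprint image dimensions do not match the measurement")
  out <- array(NA_real_, d)
  n_masked <- 0L
  inv_single <- if (single) tryCatch(solve(M_mu), error = function(e) NULL)
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      inv <- if (single) inv_single else
        tryCatch(solve(pixel_matrix(M_mu, i, j)), error = function(e) NULL)
      if (is.null(inv) || any(!is.finite(inv))) { n_masked <- n_masked + 1L; next }
      out[i, j, , ] <- pixel_matrix(M_mes, i, j) %*% inv
    }
  }
  if (n_masked > 0)
    warning(sprintf("%d pixel(s) with singular microscope fingerprint masked",
                    n_masked))
  res <- mueller_image(out)
  attr(res, "n_masked") <- n_masked
  res
}
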