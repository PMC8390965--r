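#' Diattenuation of a Mueller matrix
#'
#' The diattenuation vector of an m00-normalized matrix is its first row
#' `(m01, m02, m03)`; its modulus `D = sqrt(m01^2 + m02^2 + m03^2)` measures
#' polarization-dependent transmission, 0 for a pure retarder or depolarizer
#' and 1 for an ideal polarizer.
#'
#' @param M a 4x4 Mueller matrix with `m00 > 0` (normalized internally).
#' @return scalar diattenuation.
#' @export
#' @examples
#' diattenuation(retarder_mueller(60, 30)) # 0
diattenuation <- function(M) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) stopf("M must be 4x4")
  if (!is.finite(M[1, 1]) || M[1, 1] <= 0) stopf("m00 must be positive")
  M <- M / M[1, 1]
  sqrt(sum(M[1, 2:4]^2))
}

#' Depolarization index of a Mueller matrix
#'
#' `P_d = sqrt((sum_ij m_ij^2 - m00^2) / (3 m00^2))`: 1 for any
#' non-depolarizing matrix, 0 for the total depolarizer `diag(1, 0, 0, 0)`.
#' Noisy experimental matrices can slightly exceed 1.
#'
#' @param M a 4x4 Mueller matrix with `m00 != 0`.
#' @return scalar depolarization index.
#' @export
depolarization_index <- function(M) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) stopf("M must be 4x4")
  if (M[1, 1] == 0) stopf("m00 must be nonzero")
  sqrt((sum(M^2) - M[1, 1]^2) / (3 * M[1, 1]^2))
}

#' Lu-Chipman polar decomposition
#'
#' Factors a Mueller matrix as `M = M_delta %*% M_R %*% M_D` (depolarizer x
#' retarder x diattenuator, in that fixed order) and extracts the scalar
#' polarimetric parameters:
#' * `D` — diattenuation, from the first row;
#' * `R` — total retardance in degrees, `acos((tr(M_R) - 2) / 2)` on `[0, 180]`;
#' * `alpha_R` — fast-axis orientation in degrees on `(-90, 90]`, from the
#'   two-argument arctangent of the retardance-vector components `(r1, r2)`;
#' * `P_d` — depolarization index of the input matrix.
#'
#' The sequence is the canonical one: build `M_D` from the diattenuation
#' vector, form `M' = M %*% solve(M_D)`, obtain the depolarizer block from the
#' eigen-decomposition of `m' m'^T` (with the sign of `det m'`), and set
#' `M_R = solve(M_delta) %*% M'`. The retardance vector is read from the
#' antisymmetric part of the rotation block, `r_i = sum_jk e_ijk (M_R)_jk /
#' (2 sin R)`; within `half_wave_tol` of `R = 180` degrees the antisymmetric
#' part vanishes and the symmetric-part fallback `r_i^2 = (1 + (M_R)_ii) / 2`
#' is used (orientation signs from the off-diagonal elements).
#'
#' @param M a 4x4 Mueller matrix, `m00 > 0`; normalized internally.
#' @param half_wave_tol angular tolerance (degrees) around `R = 0` and
#'   `R = 180` below which the antisymmetric extraction is abandoned.
#' @return an object of class `"lc_result"`: list with `M_delta`, `M_R`,
#'   `M_D`, `D`, `R`, `alpha_R`, `P_d`, the retardance vector `r`, and `flag`
#'   (`"ok"`, `"retardance_degenerate"` or `"singular"`). For a singular
#'   depolarizer block the scalar parameters are `NaN` and `flag` is set.
#' @references Lu, S.-Y. and Chipman, R. A. (1996) Interpretation of Mueller
#'   matrices based on polar decomposition, J. Opt. Soc. Am. A 13, 1106-1113.
#' @export
#' @examples
#' fit <- lc_decompose(retarder_mueller(60, 30))
#' c(fit$R, fit$alpha_R) # 60, 30
lc_decompose <- function(M, half_wave_tol = 1e-5) {
  if (!is.matrix(M) || any(dim(M) != c(4, 4))) stopf("M must be 4x4")
  if (!is.finite(M[1, 1]) || M[1, 1] <= 0) stopf("m00 must be positive")
  M <- M / M[1, 1]
  Pd <- depolarization_index(M)

  Dv <- M[1, 2:4]
  D <- sqrt(sum(Dv^2))
  if (D >= 1) {
    # singular diattenuator: limiting formula M_D = 0.5 * (outer structure);
    # the retarder/depolarizer split is then undefined
    Dh <- Dv / D
    MD <- 0.5 * rbind(c(1, Dh), cbind(Dh, Dh %o% Dh))
    return(structure(list(M_delta = diag(4), M_R = diag(4), M_D = MD,
                          D = D, R = NaN, alpha_R = NaN, P_d = Pd,
                          r = rep(NaN, 3), flag = "singular"),
                     class = "lc_result"))
  }
  if (D < 1e-14) {
    MD <- diag(4)
  } else {
    Dh <- Dv / D
    a <- sqrt(1 - D^2)
    mD <- a * diag(3) + (1 - a) * (Dh %o% Dh)
    MD <- rbind(c(1, Dv), cbind(Dv, mD))
  }
  Mp <- M %*% solve(MD)
  mp <- Mp[2:4, 2:4]

  G <- mp %*% t(mp)
  ev <- eigen(G, symmetric = TRUE)
  sl <- sqrt(pmax(ev$values, 0))
  A <- G + (sl[1] * sl[2] + sl[2] * sl[3] + sl[3] * sl[1]) * diag(3)
  B <- (sl[1] + sl[2] + sl[3]) * G + sl[1] * sl[2] * sl[3] * diag(3)
  if (abs(det(A)) < 1e-300) {
    return(structure(list(M_delta = NA, M_R = NA, M_D = MD, D = D,
                          R = NaN, alpha_R = NaN, P_d = Pd, r = rep(NaN, 3),
                          flag = "singular"),
                     class = "lc_result"))
  }
  mDelta <- solve(A, B)
  if (det(mp) < 0) mDelta <- -mDelta
  Mdelta <- rbind(c(1, 0, 0, 0), cbind(Mp[2:4, 1], mDelta))
  mR <- solve(mDelta, mp)
  MR <- rbind(c(1, 0, 0, 0), cbind(c(0, 0, 0), mR))

  tr <- sum(diag(mR))
  R <- rad2deg(acos(min(max((tr - 1) / 2, -1), 1)))
  sR <- sin(deg2rad(R))
  flag <- "ok"
  if (sR > sin(deg2rad(half_wave_tol))) {
    r <- c(mR[2, 3] - mR[3, 2], mR[3, 1] - mR[1, 3], mR[1, 2] - mR[2, 1]) /
      (2 * sR)
  } else if (R > 90) {
    # near half wave: mR ~ 2 r r^T - I; signs up to a global flip (physical
    # degeneracy: a half-wave plate at alpha equals one at alpha + 90)
    r <- sqrt(pmax((1 + diag(mR)) / 2, 0))
    if (mR[1, 2] + mR[2, 1] < 0) r[2] <- -r[2]
    if (mR[1, 3] + mR[3, 1] < 0) r[3] <- -r[3]
    flag <- "retardance_degenerate"
  } else {
    r <- rep(NaN, 3) # R ~ 0: orientation undefined
    flag <- "retardance_degenerate"
  }
  alpha <- if (all(is.finite(r[1:2])) && (r[1] != 0 || r[2] != 0))
    fold_orientation(rad2deg(0.5 * atan2(r[2], r[1]))) else NaN

  structure(list(M_delta = Mdelta, M_R = MR, M_D = MD, D = D, R = R,
                 alpha_R = alpha, P_d = Pd, r = r, flag = flag),
            class = "lc_result")
}

#' @export
print.lc_result <- function(x, ...) {
  cat("<lc_result> Lu-Chipman polar decomposition\n")
  cat(sprintf("  D = %.4f   R = %.2f deg   alpha_R = %.2f deg   P_d = %.4f\n",
              x$D, x$R, x$alpha_R, x$P_d))
  if (x$flag != "ok") cat("  flag:", x$flag, "\n")
  invisible(x)
}

#' Per-pixel Lu-Chipman parameter maps
#'
#' Runs [lc_decompose()] at every pixel of a Mueller image and returns the
#' scalar maps. Orientation is only physical where there is signal: pixels with
#' both `D` and `R` below their thresholds get their orientation masked
#' (conventionally coded black when rendered). Isolated degenerate or singular
#' pixels are flagged, never fatal.
#'
#' @param img a `mueller_image` (or single 4x4 matrix).
#' @param signal_threshold named vector `c(D = ..., R = ...)`: orientation is
#'   masked where `D < D-threshold` **and** `R < R-threshold` (degrees).
#'   Defaults to the air-level noise floor `c(D = 0.02, R = 2)`.
#' @return an object of class `"lc_image"`: list of matrices `D`, `R`,
#'   `alpha_R`, `P_d`, logical `orientation_mask` (TRUE = untrustworthy) and
#'   character `flag`.
#' @export
lc_image <- function(img, signal_threshold = c(D = 0.02, R = 2)) {
  img <- as_mueller_image(img)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  D <- R <- A <- P <- matrix(NA_real_, h, w)
  flag <- matrix("ok", h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      fit <- tryCatch(lc_decompose(pixel_matrix(img, i, j)), error = function(e) NULL)
      if (is.null(fit)) { flag[i, j] <- "error"; next }
      D[i, j] <- fit$D; R[i, j] <- fit$R
      A[i, j] <- fit$alpha_R; P[i, j] <- fit$P_d
      flag[i, j] <- fit$flag
    }
  }
  mask <- (D < signal_threshold[["D"]] & R < signal_threshold[["R"]]) |
    !is.finite(A)
  mask[is.na(mask)] <- TRUE
  structure(list(D = D, R = R, alpha_R = A, P_d = P,
                 orientation_mask = mask, flag = flag,
                 signal_threshold = signal_threshold),
            class = "lc_image")
}

#' @export
print.lc_image <- function(x, ...) {
  cat(sprintf("<lc_image> %d x %d pixels\n", nrow(x$D), ncol(x$D)))
  cat(sprintf("  mean D = %.4f, mean R = %.2f deg, mean P_d = %.4f, %d orientation-masked px\n",
              mean(x$D, na.rm = TRUE), mean(x$R, na.rm = TRUE),
              mean(x$P_d, na.rm = TRUE), sum(x$orientation_mask)))
  invisible(x)
}
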