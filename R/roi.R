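#' Region-of-interest summary table
#'
#' Summarizes per-pixel parameter maps over named ROIs: pixel count, mean and
#' SD per parameter, restricted to finite (unmasked) pixels. Orientation
#' parameters (names starting with `alpha`) additionally get a doubled-angle
#' circular mean, which is immune to the +/-90 degree wrap of the orientation
#' axis; the plain mean is kept alongside for comparison with conventional
#' tables.
#'
#' @param maps named list of numeric matrices, all the same size.
#' @param rois named list of ROIs: each either a logical matrix or a
#'   rectangle `c(row1, row2, col1, col2)`.
#' @return a data frame of class `"roi_table"` with columns `roi`,
#'   `parameter`, `n`, `mean`, `sd`, `circ_mean`.
#' @export
#' @examples
#' maps <- list(R = matrix(60, 4, 4), alpha_R = matrix(30, 4, 4))
#' roi_summarize(maps, list(all = c(1, 4, 1, 4)))
roi_summarize <- function(maps, rois) {
  stopifnot(is.list(maps), length(maps) > 0, is.list(rois), length(rois) > 0)
  dims <- dim(maps[[1]])
  if (is.null(names(rois))) names(rois) <- paste0("roi", seq_along(rois))
  rows <- list()
  for (rn in names(rois)) {
    roi <- rois[[rn]]
    if (is.numeric(roi) && length(roi) == 4) {
      if (roi[1] < 1 || roi[2] > dims[1] || roi[3] < 1 || roi[4] > dims[2] ||
          roi[1] > roi[2] || roi[3] > roi[4])
        stopf("ROI '%s' is outside the image bounds", rn)
      mask <- matrix(FALSE, dims[1], dims[2])
      mask[roi[1]:roi[2], roi[3]:roi[4]] <- TRUE
    } else if (is.logical(roi) && identical(dim(roi), dims)) {
      mask <- roi
    } else stopf("ROI '%s' must be a logical mask or c(row1, row2, col1, col2)", rn)
    if (!any(mask)) stopf("ROI '%s' is empty", rn)
    for (pn in names(maps)) {
      v <- maps[[pn]][mask]
      v <- v[is.finite(v)]
      circ <- NA_real_
      if (startsWith(pn, "alpha") && length(v))
        circ <- circular_orientation_mean(v)
      rows[[length(rows) + 1]] <- data.frame(
        roi = rn, parameter = pn, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        sd = if (length(v) > 1) sd(v) else if (length(v) == 1) 0 else NA_real_,
        circ_mean = circ, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("roi_table", "data.frame")
  out
}

#' Doubled-angle circular mean of orientations
#'
#' Orientation angles live on a 180-degree periodic axis, so the mean is taken
#' on the doubled angles: `atan2(mean sin 2a, mean cos 2a) / 2`, folded into
#' `(-90, 90]`. Avoids the wrap bias of plain averaging near +/-90 degrees.
#'
#' @param alpha orientations in degrees.
#' @return the circular mean orientation in degrees.
#' @export
#' @examples
#' circular_orientation_mean(c(89, -89)) # 90, not 0
circular_orientation_mean <- function(alpha) {
  a2 <- deg2rad(2 * alpha)
  fold_orientation(rad2deg(atan2(mean(sin(a2)), mean(cos(a2))) / 2))
}

#' Rotation-series statistics for a fiber measurement
#'
#' For a series of estimates taken at successive physical sample rotations,
#' reports the mean and SD of the retardance (which should be invariant under
#' rotation) and of the successive orientation differences
#' `delta_alpha[i] = alpha[i + 1] - alpha[i]` (which should equal the applied
#' rotation step). Orientations are expected unwrapped along the series.
#'
#' @param R retardance values (degrees), one per rotation.
#' @param alpha orientation values (degrees, unwrapped), one per rotation.
#' @return list with `mean_R`, `sd_R`, `delta_alpha`, `mean_delta_alpha`,
#'   `sd_delta_alpha`.
#' @export
rotation_series_summary <- function(R, alpha) {
  stopifnot(length(R) == length(alpha), length(R) >= 2)
  dalpha <- diff(alpha)
  list(mean_R = mean(R), sd_R = sd(R),
       delta_alpha = dalpha,
       mean_delta_alpha = mean(dalpha), sd_delta_alpha = sd(dalpha))
}

#' Write an ROI table as CSV, rounded at report precision
#'
#' Angles at 1 decimal place, dimensionless parameters at 3, rounding half
#' away from zero (the convention of printed polarimetry tables).
#'
#' @param tab an [roi_summarize()] table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_roi_csv <- function(tab, path) {
  out <- tab
  ang <- grepl("^(R|alpha|phi)", out$parameter)
  for (col in c("mean", "sd", "circ_mean")) {
    out[[col]] <- ifelse(ang, round_half_away(out[[col]], 1),
                         round_half_away(out[[col]], 3))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
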