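#' Ideal polarization state generator (PSG) states
#'
#' The four canonical input Stokes vectors used throughout: linear horizontal
#' (H), linear vertical (V), linear +45 degrees, and right circular (RCP),
#' as the columns of a 4x4 matrix.
#'
#' @return a 4x4 matrix with columns named `H`, `V`, `45`, `RCP`.
#' @export
psg_states <- function() {
  W <- cbind(H = c(1, 1, 0, 0), V = c(1, -1, 0, 0),
             `45` = c(1, 0, 1, 0), RCP = c(1, 0, 0, 1))
  rownames(W) <- c("S0", "S1", "S2", "S3")
  W
}

#' Phasor transform configuration
#'
#' The phasor transform projects the polarization-resolved intensity signal
#' `I_theta` onto a single Fourier frequency `harmonic / period`. The default
#' analyzer set is `theta = 0, 45, 90, 135` degrees with period 180 degrees
#' (the natural period of a linear analyzer) and the first harmonic.
#'
#' @param theta analyzer angles in degrees, each within `[0, period)`.
#' @param period modulation period in degrees.
#' @param harmonic Fourier harmonic, a positive integer.
#' @return an object of class `"phasor_config"`.
#' @export
phasor_config <- function(theta = c(0, 45, 90, 135), period = 180,
                          harmonic = 1L) {
  if (any(theta < 0 | theta >= period))
    stopf("analyzer angles must lie within [0, period)")
  if (harmonic < 1) stopf("harmonic must be >= 1")
  structure(list(theta = theta, period = period, harmonic = as.integer(harmonic)),
            class = "phasor_config")
}

#' Polarization-resolved intensity stack from a Mueller image
#'
#' For each input state `p` the output Stokes image is `S_out = M(x, y) w_p`;
#' the linear analyzer intensities are then
#' `I_theta = (S0 + S1 cos 2theta + S2 sin 2theta) / 2`, i.e. a virtual
#' rotation of a linear analyzer behind the sample. The circular intensity
#' (`S0`, `S3` combination) is deliberately omitted from the stack.
#'
#' @param img a `mueller_image` or single 4x4 matrix.
#' @param input_states 4x4 matrix of input Stokes vectors as columns
#'   (default [psg_states()]; experimentally calibrated states are accepted).
#' @param theta analyzer angles in degrees.
#' @param dop_tol tolerance on the degree of polarization of the input states.
#' @return an object of class `"polarization_stack"`: array
#'   `c(h, w, n_states, n_theta)` with dimnames on the state and theta axes.
#' @export
#' @examples
#' stk <- polarization_stack_from_mueller(diag(4))
#' stk[1, 1, "H", ] # 1, 0.5, 0, 0.5 at theta = 0, 45, 90, 135
polarization_stack_from_mueller <- function(img, input_states = psg_states(),
                                            theta = c(0, 45, 90, 135),
                                            dop_tol = 1e-6) {
  img <- as_mueller_image(img)
  if (!is.matrix(input_states) || nrow(input_states) != 4)
    stopf("input_states must be a 4 x n matrix of Stokes columns")
  np <- ncol(input_states)
  pn <- colnames(input_states)
  if (is.null(pn)) pn <- paste0("p", seq_len(np))
  for (p in seq_len(np)) {
    wp <- input_states[, p]
    if (wp[1] <= 0) stopf("input state %s has non-positive S0", pn[p])
    if (degree_of_polarization(wp) > 1 + dop_tol)
      warning(sprintf("input state %s has degree of polarization > 1", pn[p]))
  }
  d <- dim(img)
  h <- d[1]; w <- d[2]
  flat <- mm_flatten(img)                       # N x 16, vec(M) col-major
  out <- array(NA_real_, c(h, w, np, length(theta)),
               dimnames = list(NULL, NULL, pn, format(theta, trim = TRUE)))
  th <- deg2rad(theta)
  for (p in seq_len(np)) {
    wp <- input_states[, p]
    # S_out component k = sum_j M[k, j] w_j; element (k, j) is flat col k + 4(j-1)
    S0 <- flat[, 1] * wp[1] + flat[, 5] * wp[2] + flat[, 9] * wp[3] + flat[, 13] * wp[4]
    S1 <- flat[, 2] * wp[1] + flat[, 6] * wp[2] + flat[, 10] * wp[3] + flat[, 14] * wp[4]
    S2 <- flat[, 3] * wp[1] + flat[, 7] * wp[2] + flat[, 11] * wp[3] + flat[, 15] * wp[4]
    for (t in seq_along(th)) {
      out[, , p, t] <- 0.5 * (S0 + S1 * cos(2 * th[t]) + S2 * sin(2 * th[t]))
    }
  }
  structure(out, class = "polarization_stack", theta = theta)
}

#' Single-frequency phasor transform of a polarization stack
#'
#' Per pixel and input channel, the phasor coordinates are the normalized
#' first Fourier coefficients of the analyzer modulation:
#' `g = sum_theta I cos(2 pi h theta / period) / sum_theta I` and likewise
#' with sine for `s`. The modulation is `M = sqrt(g^2 + s^2)` (at most 0.5 for
#' physical states under the default configuration) and the phase is
#' `phi = atan2(s, g)`. Pixels whose total intensity is not positive are
#' masked (`NA`), not errors.
#'
#' @param stack a `polarization_stack`.
#' @param config a [phasor_config()]; its `theta` must match the stack.
#' @return an object of class `"phasor_field"`: list with arrays `g` and `s`
#'   of dimension `c(h, w, n_channels)` (dimnames on the channel axis) and the
#'   configuration.
#' @export
phasor_transform <- function(stack, config = phasor_config()) {
  if (!inherits(stack, "polarization_stack"))
    stopf("stack must be a polarization_stack")
  theta <- attr(stack, "theta")
  if (length(theta) != length(config$theta) ||
      any(abs(theta - config$theta) > 1e-9))
    stopf("config analyzer angles do not match the stack")
  d <- dim(stack)
  w_ang <- 2 * pi * config$harmonic * theta / config$period
  cw <- cos(w_ang); sw <- sin(w_ang)
  g <- s <- array(NA_real_, d[c(1, 2, 3)],
                  dimnames = list(NULL, NULL, dimnames(stack)[[3]]))
  for (p in seq_len(d[3])) {
    tot <- num_g <- num_s <- matrix(0, d[1], d[2])
    for (t in seq_along(theta)) {
      I <- stack[, , p, t]
      tot <- tot + I
      num_g <- num_g + I * cw[t]
      num_s <- num_s + I * sw[t]
    }
    ok <- is.finite(tot) & tot > 0
    gp <- sp <- matrix(NA_real_, d[1], d[2])
    gp[ok] <- num_g[ok] / tot[ok]
    sp[ok] <- num_s[ok] / tot[ok]
    g[, , p] <- gp
    s[, , p] <- sp
  }
  structure(list(g = g, s = s, config = config,
                 channels = dimnames(stack)[[3]]),
            class = "phasor_field")
}

#' @export
print.phasor_field <- function(x, ...) {
  d <- dim(x$g)
  cat(sprintf("<phasor_field> %d x %d pixels, channels: %s\n",
              d[1], d[2], paste(x$channels, collapse = ", ")))
  for (ch in x$channels) {
    cat(sprintf("  %-6s mean (g, s) = (%7.4f, %7.4f)\n", ch,
                mean(x$g[, , ch], na.rm = TRUE), mean(x$s[, , ch], na.rm = TRUE)))
  }
  invisible(x)
}

#' Phasor modulation and phase of one channel
#'
#' @param field a `phasor_field`.
#' @param channel channel name (e.g. `"H"`, `"RCP"`).
#' @return a matrix: `phasor_modulation` gives `sqrt(g^2 + s^2)`,
#'   `phasor_phase` gives `atan2(s, g)` in degrees on `(-180, 180]`.
#' @export
phasor_modulation <- function(field, channel) {
  ch <- field_channel(field, channel)
  sqrt(ch$g^2 + ch$s^2)
}

#' @rdname phasor_modulation
#' @export
phasor_phase <- function(field, channel) {
  ch <- field_channel(field, channel)
  rad2deg(atan2(ch$s, ch$g))
}

field_channel <- function(field, channel) {
  if (!inherits(field, "phasor_field")) stopf("not a phasor_field")
  if (!channel %in% field$channels)
    stopf("channel '%s' not present (have: %s)", channel,
          paste(field$channels, collapse = ", "))
  d <- dim(field$g)
  g <- field$g[, , channel, drop = FALSE]
  s <- field$s[, , channel, drop = FALSE]
  dim(g) <- dim(s) <- d[1:2]
  list(g = g, s = s)
}

#' Merge the linear-input phasor channels
#'
#' Averages the H, V and 45-degree input channels into a single `"linear"`
#' channel after de-rotating each phasor by twice its input azimuth (H: 0, 45:
#' 90, V: 180 degrees in phase), so that contributions from an aligned fast
#' axis coincide. For air every de-rotated channel maps to `(0.5, 0)`; for a
#' half-wave retarder the H-channel `phi = 4 alpha` signature survives the
#' average.
#'
#' @param field a `phasor_field` containing channels `H`, `V` and `45`.
#' @return the field with an extra `"linear"` channel appended.
#' @export
merge_linear_phasors <- function(field) {
  need <- c("H", "V", "45")
  if (!all(need %in% field$channels))
    stopf("merge requires channels H, V and 45")
  azim <- c(H = 0, V = 90, `45` = 45)
  d <- dim(field$g)
  zsum <- matrix(0 + 0i, d[1], d[2])
  for (ch in need) {
    z <- complex(real = field$g[, , ch], imaginary = field$s[, , ch])
    if (any(!is.finite(z))) stopf("channel %s contains masked pixels", ch)
    zsum <- zsum + z * exp(-1i * deg2rad(2 * azim[[ch]]))
  }
  zbar <- zsum / length(need)
  g <- array(c(field$g, Re(zbar)), c(d[1], d[2], d[3] + 1))
  s <- array(c(field$s, Im(zbar)), c(d[1], d[2], d[3] + 1))
  channels <- c(field$channels, "linear")
  dimnames(g) <- dimnames(s) <- list(NULL, NULL, channels)
  structure(list(g = g, s = s, config = field$config, channels = channels),
            class = "phasor_field")
}

#' Fast-axis orientation from the RCP phasor phase
#'
#' For a birefringent sample the right-circular-input phasor phase encodes the
#' fast-axis orientation as `alpha_R = phi / 2 - 45` degrees, with `phi`
#' expressed on the branch window `(-90, 270]`.
#'
#' @param phi RCP phasor phase in degrees (any branch; remapped internally).
#' @return orientation in degrees on `(-90, 90]`; `NA` for non-finite input.
#' @export
#' @examples
#' alpha_from_rcp_phase(90)  # 0
#' alpha_from_rcp_phase(180) # 45
alpha_from_rcp_phase <- function(phi) {
  phi <- ((phi + 90) %% 360) - 90 # (-90, 270]
  phi[!is.na(phi) & phi == -90] <- 270
  fold_orientation(phi / 2 - 45)
}

#' Retardance from the RCP phasor modulation
#'
#' The RCP modulation of a linear retarder is `sin(R) / 2`, independent of the
#' fast-axis orientation, so `R = asin(2 M)` on the low branch (`R < 90`) and
#' `R = 180 - asin(2 M)` on the high branch; the branch is decided from the
#' linear-input phasor, see [branch_from_h_phasor()].
#'
#' @param M phasor modulation, in `[0, 0.5 + tol]`; clipped to 0.5.
#' @param branch `"low"`, `"high"` or `"boundary"` (recycled against `M`).
#' @param tol tolerance above 0.5 before an input is rejected.
#' @return retardance in degrees.
#' @export
#' @examples
#' retardance_from_rcp_modulation(0.25, "low")  # 30
#' retardance_from_rcp_modulation(0.25, "high") # 150
retardance_from_rcp_modulation <- function(M, branch, tol = 1e-6) {
  if (any(is.finite(M) & (M < 0 | M > 0.5 + tol)))
    stopf("modulation must lie in [0, 0.5 + tol]")
  M <- pmin(M, 0.5)
  branch <- rep_len(branch, length(M))
  base <- rad2deg(asin(2 * M))
  out <- ifelse(branch == "low", base,
                ifelse(branch == "high", 180 - base,
                       ifelse(branch == "boundary", 90, NA_real_)))
  out[!is.finite(M)] <- NA_real_
  out
}

#' Retardance branch from the H-input phasor
#'
#' On the H (horizontal linear input) phasor plot, retarders with `R < 90`
#' degrees fall inside the circle of center `(0.25, 0)` and radius 0.25, while
#' `R > 90` falls outside it but inside the physical circle of radius 0.5
#' about the origin; at `R = 90` the phasor lies on the small circle exactly.
#' The classification uses the distance `d = sqrt((g - 0.25)^2 + s^2)` with a
#' configurable boundary band.
#'
#' @param g,s H-channel phasor coordinates (vectors or matrices).
#' @param epsilon boundary band half-width on `d`, in `(g, s)` units.
#' @param physical_tol slack on the radius-0.5 physicality check.
#' @return character array: `"low"`, `"high"`, `"boundary"` or
#'   `"undetermined"`.
#' @export
branch_from_h_phasor <- function(g, s, epsilon = 0.005, physical_tol = 0.05) {
  d <- sqrt((g - 0.25)^2 + s^2)
  rad <- sqrt(g^2 + s^2)
  out <- rep("undetermined", length(d))
  out[!is.na(d) & d < 0.25 - epsilon] <- "low"
  out[!is.na(d) & abs(d - 0.25) <= epsilon] <- "boundary"
  out[!is.na(d) & d > 0.25 + epsilon & rad <= 0.5 + physical_tol] <- "high"
  dim(out) <- dim(d)
  out
}

#' Retardance and orientation maps from a phasor field
#'
#' The model-free readout chain: per pixel, the retardance branch is decided
#' from the linear-input phasor circles, the retardance from the RCP
#' modulation ([retardance_from_rcp_modulation()]) and the orientation from
#' the RCP phase ([alpha_from_rcp_phase()]). Pixels whose RCP modulation is
#' below `noise_floor_M` are indistinguishable from air and returned as
#' `"undetermined"` with `NA` parameters.
#'
#' The branch statistic is the deviation `d - 0.25` from the H-channel circle
#' `(0.25, 0)`; where the 45-degree channel is available the deviation from
#' its rotated circle `(0, 0.25)` is computed too and the larger-magnitude of
#' the two decides. This removes the blind spot of the H-only rule for fast
#' axes near 0 or 90 degrees, where the H phasor stays pinned to `(0.5, 0)`
#' regardless of retardance (and, symmetrically, the 45-channel rule is blind
#' near +/-45). A pixel is `"boundary"` (reported as `R = 90`) only when both
#' deviations vanish within `boundary_tol`.
#'
#' @param field a `phasor_field` with at least the `H` and `RCP` channels.
#' @param noise_floor_M modulation below which a pixel is treated as air.
#' @param boundary_tol numerical half-width of the `R = 90` boundary set.
#' @param physical_tol slack on the radius-0.5 physicality check; pixels whose
#'   H phasor falls further out are `"undetermined"`.
#' @return an object of class `"phasor_map"`: list of matrices `R` (degrees),
#'   `alpha_R` (degrees), character `branch`, `M` and `phi` (RCP modulation
#'   and phase).
#' @export
#' @examples
#' img <- mueller_image(retarder_mueller(120, -10))
#' fld <- phasor_transform(polarization_stack_from_mueller(img))
#' pm <- phasor_parameter_images(fld)
#' c(pm$R, pm$alpha_R, pm$branch) # 120, -10, high
phasor_parameter_images <- function(field, noise_floor_M = 0.05,
                                    boundary_tol = 1e-9, physical_tol = 0.05) {
  need <- c("H", "RCP")
  if (!all(need %in% field$channels))
    stopf("phasor parameter maps require the H and RCP channels")
  H <- field_channel(field, "H")
  Mr <- phasor_modulation(field, "RCP")
  phir <- phasor_phase(field, "RCP")

  devH <- sqrt((H$g - 0.25)^2 + H$s^2) - 0.25
  dev <- devH
  if ("45" %in% field$channels) {
    c45 <- field_channel(field, "45")
    dev45 <- sqrt(c45$g^2 + (c45$s - 0.25)^2) - 0.25
    use45 <- !is.na(dev45) & (is.na(devH) | abs(dev45) > abs(devH))
    dev[use45] <- dev45[use45]
  }
  radH <- sqrt(H$g^2 + H$s^2)

  branch <- matrix("undetermined", nrow(Mr), ncol(Mr))
  ok <- is.finite(dev) & is.finite(radH) & radH <= 0.5 + physical_tol
  branch[ok & dev < -boundary_tol] <- "low"
  branch[ok & dev > boundary_tol] <- "high"
  branch[ok & abs(dev) <= boundary_tol] <- "boundary"

  air <- !is.finite(Mr) | Mr < noise_floor_M
  branch[air] <- "undetermined"

  Mclip <- pmin(Mr, 0.5) # noisy pixels may poke just above the physical bound
  base <- rad2deg(asin(2 * Mclip))
  R <- ifelse(branch == "low", base,
              ifelse(branch == "high", 180 - base,
                     ifelse(branch == "boundary", 90, NA_real_)))
  alpha <- alpha_from_rcp_phase(phir)
  alpha[branch == "undetermined"] <- NA_real_
  R[branch == "undetermined"] <- NA_real_
  dim(R) <- dim(alpha) <- dim(Mr)

  structure(list(R = R, alpha_R = alpha, branch = branch, M = Mr, phi = phir,
                 noise_floor_M = noise_floor_M),
            class = "phasor_map")
}

#' @export
print.phasor_map <- function(x, ...) {
  cat(sprintf("<phasor_map> %d x %d pixels, %d undetermined\n",
              nrow(x$R), ncol(x$R), sum(x$branch == "undetermined")))
  if (any(is.finite(x$R)))
    cat(sprintf("  mean R = %.2f deg, mean alpha_R = %.2f deg\n",
                mean(x$R, na.rm = TRUE), mean(x$alpha_R, na.rm = TRUE)))
  invisible(x)
}

#' Two-dimensional phasor histogram
#'
#' Bins the `(g, s)` coordinates of one channel over the unmasked pixels of an
#' optional region of interest. The conventional rendering codes the counts
#' from red (highest bin) to blue (lowest); see [plot.phasor_histogram()].
#'
#' @param field a `phasor_field`.
#' @param channel channel to histogram.
#' @param roi_mask optional logical matrix selecting pixels.
#' @param bins number of bins per axis.
#' @param limits plot-range limits, default `c(-0.5, 0.5)` on both axes.
#' @return an object of class `"phasor_histogram"`: list with `counts`
#'   (bins x bins, g along rows), bin `breaks`, and the total pixel count.
#' @export
phasor_histogram <- function(field, channel = "RCP", roi_mask = NULL,
                             bins = 256, limits = c(-0.5, 0.5)) {
  ch <- field_channel(field, channel)
  g <- ch$g; s <- ch$s
  if (!is.null(roi_mask)) {
    if (!identical(dim(roi_mask), dim(g)))
      stopf("roi_mask dimensions do not match the field")
    if (!any(roi_mask)) stopf("empty ROI")
    g <- g[roi_mask]; s <- s[roi_mask]
  }
  keep <- is.finite(g) & is.finite(s)
  g <- g[keep]; s <- s[keep]
  breaks <- seq(limits[1], limits[2], length.out = bins + 1)
  gi <- pmin(pmax(findInterval(g, breaks, rightmost.closed = TRUE), 1L), bins)
  si <- pmin(pmax(findInterval(s, breaks, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0L, bins, bins)
  tab <- table(factor(gi, levels = seq_len(bins)),
               factor(si, levels = seq_len(bins)))
  counts[] <- as.integer(tab)
  structure(list(counts = counts, breaks = breaks, n = length(g),
                 channel = channel),
            class = "phasor_histogram")
}

#' Plot a phasor histogram
#'
#' Renders the 2D bin counts with the conventional red-to-blue colormap
#' (red = densest) over the `[-0.5, 0.5]^2` phasor plane.
#'
#' @param x a `phasor_histogram`.
#' @param ncol number of colors in the ramp.
#' @param ... passed to [graphics::image()].
#' @return the input, invisibly.
#' @export
plot.phasor_histogram <- function(x, ncol = 64, ...) {
  pal <- colorRampPalette(c("blue", "cyan", "yellow", "red"))(ncol)
  z <- x$counts
  z[z == 0] <- NA
  mid <- (x$breaks[-1] + x$breaks[-length(x$breaks)]) / 2
  image(mid, mid, z, col = pal, xlab = "g", ylab = "s",
        main = sprintf("phasor plot (%s input)", x$channel), ...)
  box()
  invisible(x)
}

#' Gate definition helpers for phasor-space segmentation
#'
#' @param center numeric length-2 `(g, s)` center of the disc.
#' @param radius disc radius, positive.
#' @return a gate object understood by [phasor_gate_segment()].
#' @export
gate_disc <- function(center, radius) {
  if (radius <= 0) stopf("degenerate gate: radius must be positive")
  structure(list(type = "disc", center = center, radius = radius),
            class = "phasor_gate")
}

#' @rdname gate_disc
#' @param g,s polygon vertex coordinates (closed implicitly).
#' @export
gate_polygon <- function(g, s) {
  if (length(g) < 3 || length(g) != length(s))
    stopf("degenerate gate: polygon needs >= 3 vertices")
  area <- abs(sum(g * c(s[-1], s[1]) - c(g[-1], g[1]) * s)) / 2
  if (area <= 0) stopf("degenerate gate: polygon has zero area")
  structure(list(type = "polygon", g = g, s = s), class = "phasor_gate")
}

#' Segment an image by gating in phasor space
#'
#' Maps a region of phasor space back onto the image: the returned mask is
#' TRUE for pixels whose `(g, s)` point of the requested channel falls inside
#' the gate. This is the direct segmentation read-out of the phasor plot: two
#' materials with separated phasor clusters are split by two gates.
#'
#' @param field a `phasor_field`.
#' @param gate a [gate_disc()] or [gate_polygon()].
#' @param channel channel whose phasor coordinates are gated.
#' @return a logical matrix, `NA`-masked pixels are `FALSE`.
#' @export
phasor_gate_segment <- function(field, gate, channel = "RCP") {
  if (!inherits(gate, "phasor_gate")) stopf("gate must be a phasor_gate")
  ch <- field_channel(field, channel)
  g <- ch$g; s <- ch$s
  inside <- matrix(FALSE, nrow(g), ncol(g))
  ok <- is.finite(g) & is.finite(s)
  if (gate$type == "disc") {
    inside[ok] <- (g[ok] - gate$center[1])^2 + (s[ok] - gate$center[2])^2 <=
      gate$radius^2
  } else {
    if (!requireNamespace("mgcv", quietly = TRUE))
      stopf("polygon gates require the mgcv package")
    bnd <- list(x = c(gate$g, gate$g[1]), y = c(gate$s, gate$s[1]))
    inside[ok] <- mgcv::in.out(cbind(bnd$x, bnd$y), cbind(g[ok], s[ok]))
  }
  inside
}
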