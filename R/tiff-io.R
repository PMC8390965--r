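#' Write matrices as an uncompressed float32 multi-page TIFF
#'
#' Minimal IEEE-float TIFF writer (little-endian, one strip per page,
#' SampleFormat = 3). Written because Mueller elements are signed and can
#' exceed 1 in magnitude, which integer-normalized TIFF writers clamp. Files
#' read back bit-exactly (at float32 precision) with [tiff::readTIFF()].
#'
#' @param planes a matrix or list of matrices (pages), all numeric.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_float_tiff <- function(planes, path) {
  if (is.matrix(planes)) planes <- list(planes)
  if (!length(planes)) stopf("no planes to write")
  con <- file(path, "wb")
  on.exit(close(con))
  wB <- function(x, size) writeBin(as.integer(x), con, size = size,
                                   endian = "little")
  writeChar("II", con, eos = NULL)
  wB(42L, 2)
  n <- length(planes)
  entries <- 10L
  pos <- 8
  offs <- vector("list", n)
  for (i in seq_len(n)) {
    h <- nrow(planes[[i]]); w <- ncol(planes[[i]])
    offs[[i]] <- list(data = pos, ifd = pos + 4 * h * w, h = h, w = w)
    pos <- offs[[i]]$ifd + 2 + entries * 12 + 4
  }
  wB(offs[[1]]$ifd, 4)
  tag <- function(id, type, count, value) {
    wB(id, 2); wB(type, 2); wB(count, 4); wB(value, 4)
  }
  for (i in seq_len(n)) {
    o <- offs[[i]]
    writeBin(as.numeric(t(planes[[i]])), con, size = 4, endian = "little")
    wB(entries, 2)
    tag(256, 3, 1, o$w)            # ImageWidth
    tag(257, 3, 1, o$h)            # ImageLength
    tag(258, 3, 1, 32)             # BitsPerSample
    tag(259, 3, 1, 1)              # Compression: none
    tag(262, 3, 1, 1)              # Photometric: BlackIsZero
    tag(273, 4, 1, o$data)         # StripOffsets
    tag(277, 3, 1, 1)              # SamplesPerPixel
    tag(278, 3, 1, o$h)            # RowsPerStrip
    tag(279, 4, 1, 4 * o$h * o$w)  # StripByteCounts
    tag(339, 3, 1, 3)              # SampleFormat: IEEE float
    wB(if (i < n) offs[[i + 1]]$ifd else 0L, 4)
  }
  invisible(path)
}

#' Write a Mueller image as a 16-plane float32 TIFF
#'
#' Planes are ordered `m00, m01, ..., m33` (row-major element order). A JSON
#' sidecar `<path>.json` records the plane order, normalization and package
#' version so the file is self-describing.
#'
#' @param img a `mueller_image` or 4x4 matrix.
#' @param path output TIFF path.
#' @param sidecar write the JSON sidecar (default TRUE).
#' @return the path, invisibly.
#' @export
write_mueller_tiff <- function(img, path, sidecar = TRUE) {
  img <- as_mueller_image(img)
  planes <- vector("list", 16)
  k <- 0
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1
    planes[[k]] <- matrix(img[, , i, j], dim(img)[1], dim(img)[2])
  }
  write_float_tiff(planes, path)
  if (sidecar) {
    meta <- list(format = "mueller_image",
                 plane_order = "row-major",
                 planes = paste0("m", rep(0:3, each = 4), rep(0:3, 4)),
                 normalized = attr(img, "normalized"),
                 pixel_size_um = attr(img, "pixel_size_um"),
                 convention = "transmission",
                 package = paste0("mmphasor ", as.character(packageVersion("mmphasor"))))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a Mueller image from a 16-plane TIFF
#'
#' Expects one float plane per Mueller element. The plane order is taken from
#' the `plane_order` argument, else from the JSON sidecar, else assumed
#' row-major (`m00, m01, ..., m33`); `"column-major"` transposes the element
#' indexing on load. Non-finite planes mask the affected pixels. A negative
#' first plane triggers a plane-order warning (m00 must be positive), not an
#' error.
#'
#' @param path TIFF path.
#' @param plane_order `"row-major"`, `"column-major"`, or `NULL` to use the
#'   sidecar/default.
#' @return a `mueller_image`.
#' @export
read_mueller_tiff <- function(path, plane_order = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  planes <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(planes)) planes <- list(planes)
  if (length(planes) != 16)
    stopf("expected 16 planes (m00..m33), found %d", length(planes))
  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- tryCatch(jsonlite::read_json(sidecar), error = function(e) NULL)
  if (is.null(plane_order))
    plane_order <- if (!is.null(meta$plane_order)) meta$plane_order else "row-major"
  if (!plane_order %in% c("row-major", "column-major"))
    stopf("unknown plane order '%s'", plane_order)
  h <- nrow(planes[[1]]); w <- ncol(planes[[1]])
  a <- array(NA_real_, c(h, w, 4, 4))
  k <- 0
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1
    if (plane_order == "row-major") a[, , i, j] <- planes[[k]]
    else a[, , j, i] <- planes[[k]]
  }
  if (any(is.finite(a[, , 1, 1]) & a[, , 1, 1] < 0))
    warning("negative m00 pixels: check the declared plane order")
  normalized <- if (!is.null(meta$normalized)) meta$normalized else NA
  mueller_image(a, normalized = if (is.logical(normalized)) normalized else NA)
}

#' Write scalar parameter maps as single-plane float32 TIFFs
#'
#' @param map a numeric matrix (e.g. a retardance map).
#' @param path output TIFF path.
#' @return the path, invisibly.
#' @export
write_map_tiff <- function(map, path) {
  stopifnot(is.matrix(map))
  map[!is.finite(map)] <- NaN
  write_float_tiff(map, path)
}
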