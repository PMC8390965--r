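#' Per-pixel Mueller-matrix images
#'
#' A `mueller_image` stores one 4x4 Mueller matrix per pixel as a numeric
#' array of dimension `c(height, width, 4, 4)`, with `x[i, j, , ]` the matrix
#' of pixel `(i, j)`. A single 4x4 matrix is treated as a 1x1 image, so all
#' pipeline functions also work on bare matrices.
#'
#' @param data a `c(h, w, 4, 4)` numeric array, or a single 4x4 matrix.
#' @param normalized logical: are the matrices m00-normalized? Recorded as
#'   metadata; estimators renormalize internally either way.
#' @param pixel_size_um optional physical pixel pitch, micrometres.
#' @return an object of class `"mueller_image"`.
#' @export
#' @examples
#' img <- mueller_image(retarder_mueller(60, 30))
#' dim(img)
mueller_image <- function(data, normalized = NA, pixel_size_um = NULL) {
  if (is.matrix(data)) {
    if (any(dim(data) != c(4, 4))) stopf("a single matrix must be 4x4")
    data <- array(data, c(1, 1, 4, 4))
    # array() fills column-major: data[1,1,,] reproduces the matrix only after
    # fixing the element order
    data[1, 1, , ] <- data[1, 1, , ]
  }
  if (!is.array(data) || length(dim(data)) != 4 || any(dim(data)[3:4] != 4))
    stopf("data must be an h x w x 4 x 4 array or a 4x4 matrix")
  structure(data, class = "mueller_image", normalized = normalized,
            pixel_size_um = pixel_size_um)
}

#' Coerce to a Mueller image
#'
#' @param x a `mueller_image`, a 4x4 matrix, or an `h x w x 4 x 4` array.
#' @return a `mueller_image`.
#' @export
as_mueller_image <- function(x) {
  if (inherits(x, "mueller_image")) return(x)
  if (is.matrix(x)) {
    a <- array(0, c(1, 1, 4, 4))
    a[1, 1, , ] <- x
    return(mueller_image(a))
  }
  mueller_image(x)
}

#' Extract the matrix at one pixel
#'
#' @param img a `mueller_image`.
#' @param i,j pixel row and column (default 1, for 1x1 images).
#' @return a 4x4 matrix.
#' @export
pixel_matrix <- function(img, i = 1L, j = 1L) {
  img <- as_mueller_image(img)
  matrix(img[i, j, , ], 4, 4)
}

# internal: flatten to an N x 16 matrix of column-major vec(M) per pixel
mm_flatten <- function(img) {
  d <- dim(img)
  matrix(as.numeric(img), d[1] * d[2], 16)
}

# internal: rebuild an image from an N x 16 flat matrix
mm_unflatten <- function(flat, h, w) {
  mueller_image(array(flat, c(h, w, 4, 4)))
}

#' Build a 1 x n Mueller image from a list of matrices
#'
#' Convenience for sweeping many single matrices through the vectorized image
#' pipeline at once.
#'
#' @param mats list of 4x4 matrices.
#' @return a `1 x length(mats)` `mueller_image`.
#' @export
mueller_image_from_list <- function(mats) {
  n <- length(mats)
  a <- array(0, c(1, n, 4, 4))
  for (k in seq_len(n)) a[1, k, , ] <- mats[[k]]
  mueller_image(a)
}

#' @export
print.mueller_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<mueller_image> %d x %d pixels", d[1], d[2]))
  if (isTRUE(attr(x, "normalized"))) cat(", m00-normalized")
  cat("\n")
  if (d[1] * d[2] == 1) {
    cat("pixel (1,1):\n")
    print(round(pixel_matrix(x), 4))
  } else {
    m00 <- x[, , 1, 1]
    cat(sprintf("m00 range: [%.4g, %.4g]\n", min(m00), max(m00)))
  }
  invisible(x)
}
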