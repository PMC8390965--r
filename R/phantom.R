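#' Synthetic phantom scene specification
#'
#' Describes one of the reference scenes used to exercise the estimators. All
#' scenes are built from ideal elements plus, optionally, per-element Gaussian
#' noise at the bundled experimental air level ([air_sigma()]):
#'
#' * `"air"` — identity matrix plus noise at every pixel.
#' * `"film_on_air"` — a uniform retarder rectangle (defaults: the measured
#'   transparent-film parameters, `R = 55.5`, `alpha = -85.7`) surrounded by
#'   air.
#' * `"layered_fibers"` — a stack of `n_layers` identical retarders
#'   (`R1` each, default the 50-um collagen-like layer at 37.87 degrees)
#'   rotated by `layer_step` from one layer to the next (0, 10, 20, ...
#'   degrees), filling the image.
#' * `"rotated_fiber"` — a horizontal fiber band (retarder) on air, with the
#'   whole-scene fast axis rotated by `rotation` degrees; emulates physical
#'   rotation of a uniform fiber, which changes only its axis.
#' * `"striped_myosin"` — vertical stripes of alternating fast-axis
#'   orientation (defaults -20 / +20 degrees), emulating antiparallel
#'   fiber bundles.
#'
#' @param scene scene name, see above.
#' @param size image size `c(height, width)` in pixels.
#' @param seed integer seed for the noise draws; recorded in the output.
#' @param noise logical: add per-element Gaussian noise?
#' @param sigma 4x4 SD matrix for the noise (default [air_sigma()]).
#' @param film_R,film_alpha film retardance / orientation (degrees).
#' @param n_layers,R1,layer_step layered-fiber parameters (degrees).
#' @param layer_noise apply independent noise draws to each layer matrix
#'   before multiplication (layered scene only); when `FALSE` a single draw is
#'   added to the layer product.
#' @param fiber_R,fiber_alpha fiber retardance / base orientation (degrees).
#' @param rotation whole-scene fast-axis rotation (degrees).
#' @param stripe_alphas two orientations for the striped scene (degrees).
#' @param stripe_period stripe period in pixels.
#' @return an object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(scene = c("air", "film_on_air", "layered_fibers",
                                   "rotated_fiber", "striped_myosin"),
                         size = c(256, 256), seed = 1L, noise = TRUE,
                         sigma = air_sigma(),
                         film_R = 55.5, film_alpha = -85.7,
                         n_layers = 4L, R1 = 37.87, layer_step = 10,
                         layer_noise = TRUE,
                         fiber_R = 60, fiber_alpha = -20, rotation = 0,
                         stripe_alphas = c(-20, 20), stripe_period = 16L) {
  scene <- match.arg(scene)
  stopifnot(length(size) == 2, all(size >= 1))
  structure(list(scene = scene, size = as.integer(size), seed = as.integer(seed),
                 noise = isTRUE(noise), sigma = sigma,
                 film_R = film_R, film_alpha = film_alpha,
                 n_layers = as.integer(n_layers), R1 = R1,
                 layer_step = layer_step, layer_noise = isTRUE(layer_noise),
                 fiber_R = fiber_R, fiber_alpha = fiber_alpha,
                 rotation = rotation, stripe_alphas = stripe_alphas,
                 stripe_period = as.integer(stripe_period)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom scene
#'
#' Builds the Mueller image described by a [phantom_spec()] together with its
#' ground truth: per-pixel retardance, fast-axis orientation (`NA` over air)
#' and region label. Noise is reproducible bit-for-bit given `(seed, size)`.
#'
#' For the layered scene the per-pixel truth `R` is the rotation angle of the
#' composite polarization block (the equivalent-retarder value); the simple
#' layer sum `n_layers * R1` is also recorded in the spec echo.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `"phantom"`: list with `mueller`
#'   (a `mueller_image`), `truth` (list of matrices `R`, `alpha_R`, `region`)
#'   and the `spec` echo.
#' @export
#' @examples
#' ph <- make_phantom(phantom_spec("film_on_air", size = c(8, 8), noise = FALSE))
#' table(ph$truth$region)
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$size[1]; w <- spec$size[2]
  R <- matrix(0, h, w)
  alpha <- matrix(NA_real_, h, w)
  region <- matrix("air", h, w)
  base <- array(0, c(h, w, 4, 4))
  for (k in 1:4) base[, , k, k] <- 1 # air = identity everywhere

  fill <- function(mask, M, Rval, aval, label) {
    for (i in 1:4) for (j in 1:4) {
      plane <- base[, , i, j]
      plane[mask] <- M[i, j]
      base[, , i, j] <<- plane
    }
    R[mask] <<- Rval; alpha[mask] <<- aval; region[mask] <<- label
  }

  layered_truth_R <- NULL
  switch(spec$scene,
    air = NULL,
    film_on_air = {
      rows <- seq(floor(h / 4) + 1, ceiling(3 * h / 4))
      cols <- seq(floor(w / 4) + 1, ceiling(3 * w / 4))
      mask <- matrix(FALSE, h, w); mask[rows, cols] <- TRUE
      fill(mask, retarder_mueller(spec$film_R, spec$film_alpha),
           spec$film_R, fold_orientation(spec$film_alpha), "film")
    },
    layered_fibers = {
      alphas <- (seq_len(spec$n_layers) - 1) * spec$layer_step
      M <- layered_mueller(rep(spec$R1, spec$n_layers), alphas)
      layered_truth_R <- rad2deg(acos(min(max((sum(diag(M[2:4, 2:4])) - 1) / 2,
                                              -1), 1)))
      mask <- matrix(TRUE, h, w)
      fill(mask, M, layered_truth_R, NA_real_, "fiber")
    },
    rotated_fiber = {
      a <- fold_orientation(spec$fiber_alpha + spec$rotation)
      rows <- seq(floor(h / 3) + 1, ceiling(2 * h / 3))
      mask <- matrix(FALSE, h, w); mask[rows, ] <- TRUE
      fill(mask, retarder_mueller(spec$fiber_R, a), spec$fiber_R, a, "fiber")
    },
    striped_myosin = {
      stripe <- ((col(matrix(0, h, w)) - 1) %/% spec$stripe_period) %% 2
      for (k in 0:1) {
        a <- fold_orientation(spec$stripe_alphas[k + 1])
        fill(stripe == k, retarder_mueller(spec$fiber_R, a),
             spec$fiber_R, a, sprintf("stripe_%+d", round(a)))
      }
    })

  if (spec$noise) {
    base <- with_seed(spec$seed, {
      if (spec$scene == "layered_fibers" && spec$layer_noise) {
        # independent error matrix per layer and pixel, then the layer product
        alphas <- (seq_len(spec$n_layers) - 1) * spec$layer_step
        flat <- matrix(0, h * w, 16)
        flat[, c(1, 6, 11, 16)] <- 1 # identity start
        for (k in seq_len(spec$n_layers)) {
          L <- retarder_mueller(spec$R1, alphas[k])
          n <- h * w
          Lnoisy <- matrix(rep(as.numeric(L), each = n), n, 16) +
            matrix(rnorm(n * 16L, 0, rep(as.numeric(spec$sigma), each = n)), n, 16)
          # per-pixel product newM = Lnoisy %*% M
          out <- matrix(0, n, 16)
          for (cj in 1:4) for (ri in 1:4) {
            acc <- 0
            for (kk in 1:4) acc <- acc +
                Lnoisy[, ri + 4 * (kk - 1)] * flat[, kk + 4 * (cj - 1)]
            out[, ri + 4 * (cj - 1)] <- acc
          }
          flat <- out
        }
        array(flat, c(h, w, 4, 4))
      } else {
        n <- h * w
        flat <- matrix(as.numeric(base), n, 16) +
          matrix(rnorm(n * 16L, 0, rep(as.numeric(spec$sigma), each = n)), n, 16)
        array(flat, c(h, w, 4, 4))
      }
    })
  }

  structure(list(mueller = mueller_image(base, normalized = TRUE),
                 truth = list(R = R, alpha_R = alpha, region = region),
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> scene '%s', %d x %d px, seed %d, noise %s\n",
              x$spec$scene, x$spec$size[1], x$spec$size[2], x$spec$seed,
              if (x$spec$noise) "on" else "off"))
  cat("  regions:", paste(sprintf("%s (%d px)", names(table(x$truth$region)),
                                  table(x$truth$region)), collapse = ", "), "\n")
  invisible(x)
}
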