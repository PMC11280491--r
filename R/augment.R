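# Data augmentation: photometric operations act on the image only, geometric
# operations are applied identically to image and mask (bilinear resampling
# for the image, nearest-neighbour for the mask so labels stay binary).

#' Augmentation specification
#'
#' Photometric parameters (`brightness`, `gamma`, `noise_sigma`) perturb
#' intensities only; geometric parameters (`scale`, `mirror`, `rotate_deg`,
#' `translate`, `elastic_*`) move pixels in image and mask jointly. Ranges
#' are sampled uniformly using `seed`, so an augmentation is a deterministic
#' function of (sample, spec). The defaults are mild perturbations typical
#' for radiograph training pipelines; magnitudes are configuration, not
#' claims about any particular dataset.
#'
#' @param brightness additive intensity range, e.g. `c(-0.1, 0.1)`.
#' @param gamma gamma-correction exponent range, strictly positive.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param scale isotropic zoom range about the canvas centre, strictly
#'   positive.
#' @param mirror logical; if `TRUE` the sample is flipped left-right
#'   (deterministically, so applying it twice is the identity).
#' @param rotate_deg rotation range in degrees about the canvas centre.
#' @param translate translation range in pixels, applied to rows and columns
#'   independently.
#' @param elastic_alpha,elastic_sigma amplitude (pixels) and smoothing of an
#'   elastic displacement field; `elastic_alpha = 0` disables it.
#' @param seed integer seed for the sampled magnitudes.
#' @return object of class `augment_spec`.
#' @export
augment_spec <- function(brightness = c(0, 0), gamma = c(1, 1),
                         noise_sigma = 0, scale = c(1, 1), mirror = FALSE,
                         rotate_deg = c(0, 0), translate = c(0, 0),
                         elastic_alpha = 0, elastic_sigma = 8, seed = 1L) {
  stopifnot(all(gamma > 0), all(scale > 0), noise_sigma >= 0,
            elastic_alpha >= 0, elastic_sigma > 0)
  structure(list(brightness = brightness, gamma = gamma,
                 noise_sigma = noise_sigma, scale = scale,
                 mirror = isTRUE(mirror), rotate_deg = rotate_deg,
                 translate = translate, elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, seed = as.integer(seed)),
            class = "augment_spec")
}

# Bilinear lookup of matrix `m` at fractional (row, col) vectors (0-based);
# zero outside the grid.
warp_bilinear_mat <- function(m, sr, sc) {
  H <- nrow(m); W <- ncol(m)
  r0 <- floor(sr); c0 <- floor(sc)
  ar <- sr - r0; ac <- sc - c0
  g <- function(ri, ci) {
    ok <- ri >= 0 & ri < H & ci >= 0 & ci < W
    v <- numeric(length(ri))
    v[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
    v
  }
  (1 - ar) * (1 - ac) * g(r0, c0) + ar * (1 - ac) * g(r0 + 1, c0) +
    (1 - ar) * ac * g(r0, c0 + 1) + ar * ac * g(r0 + 1, c0 + 1)
}

warp_nearest_mat <- function(m, sr, sc) {
  H <- nrow(m); W <- ncol(m)
  ri <- round(sr); ci <- round(sc)
  ok <- ri >= 0 & ri < H & ci >= 0 & ci < W
  v <- numeric(length(ri))
  v[ok] <- m[cbind(ri[ok] + 1, ci[ok] + 1)]
  v
}

#' Apply an augmentation to a sample
#'
#' @param sample an `image_sample`.
#' @param spec an [augment_spec()].
#' @return augmented `image_sample`; the mask stays binary.
#' @export
augment <- function(sample, spec) {
  stopifnot(inherits(sample, "image_sample"), inherits(spec, "augment_spec"))
  H <- dim(sample$mask)[1]; W <- dim(sample$mask)[2]
  with_seed(spec$seed, {
    bright <- runif(1, spec$brightness[1], spec$brightness[2])
    gam <- runif(1, spec$gamma[1], spec$gamma[2])
    sc <- runif(1, spec$scale[1], spec$scale[2])
    th <- runif(1, spec$rotate_deg[1], spec$rotate_deg[2]) * pi / 180
    tr <- runif(1, spec$translate[1], spec$translate[2])
    tc <- runif(1, spec$translate[1], spec$translate[2])

    img <- sample$image
    msk <- sample$mask

    geom <- spec$mirror || sc != 1 || th != 0 || tr != 0 || tc != 0 ||
      spec$elastic_alpha > 0
    if (geom) {
      ctr <- c((H - 1) / 2, (W - 1) / 2)
      rr <- matrix(seq_len(H) - 1, H, W) - ctr[1]
      cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE) - ctr[2]
      # inverse map: rotate by -theta, divide by scale, undo translation
      sr <- (cos(th) * rr + sin(th) * cc) / sc + ctr[1] - tr
      scl <- (-sin(th) * rr + cos(th) * cc) / sc + ctr[2] - tc
      if (spec$mirror) scl <- (W - 1) - scl
      if (spec$elastic_alpha > 0) {
        smooth_field <- function() {
          f <- matrix(rnorm(H * W), H, W)
          for (i in seq_len(max(1L, round(spec$elastic_sigma / 2)))) f <- blur3(f)
          f / max(abs(f), 1e-8)
        }
        sr <- sr + spec$elastic_alpha * smooth_field()
        scl <- scl + spec$elastic_alpha * smooth_field()
      }
      img <- array(vapply(1:3, function(ch)
        warp_bilinear_mat(sample$image[, , ch], as.numeric(sr), as.numeric(scl)),
        numeric(H * W)), dim = c(H, W, 3))
      msk <- matrix(as.integer(warp_nearest_mat(sample$mask,
                                                as.numeric(sr),
                                                as.numeric(scl))), H, W)
    }
    # photometric (image only)
    img <- img + bright
    img <- pmin(pmax(img, 0), 1)^gam
    if (spec$noise_sigma > 0) {
      nz <- matrix(rnorm(H * W, sd = spec$noise_sigma), H, W)
      img <- img + array(rep(nz, 3), dim = dim(img)) # same noise per channel
    }
    img <- pmin(pmax(img, 0), 1)
    image_sample(img, msk, id = sample$id)
  })
}
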