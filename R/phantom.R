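# Synthetic dental phantom generator.
#
# Panoramic radiographs are hard to segment because tooth roots and jawbone
# have similar radiodensity (low contrast near the root), adjacent teeth
# overlap in projection, and scatter adds noise. The phantom emulates exactly
# those failure modes on a controllable canvas: elongated capsule-shaped
# "teeth" (bright crown, low-contrast root), optional forced overlaps,
# blurred edges, and additive Gaussian noise. Coordinates are (row, col),
# 0-based at the top-left, throughout the package.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

#' Phantom generator configuration
#'
#' @param canvas integer `(height, width)`, both at least 16.
#' @param n_teeth number of tooth shapes to draw.
#' @param contrast_gap mean intensity difference, in `[0,1]`, between the
#'   root portion of a tooth and the surrounding background. Small values
#'   emulate the ambiguous root/bone boundary of real radiographs.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param overlap_prob probability that a tooth is shifted onto its left
#'   neighbour, producing the projection overlaps seen in panoramic images.
#' @param seed integer seed; the generator is a pure function of the config.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(canvas = c(320L, 640L), n_teeth = 8L,
                           contrast_gap = 0.12, noise_sigma = 0.03,
                           overlap_prob = 0.3, seed = 1L) {
  canvas <- as.integer(canvas)
  stopifnot(length(canvas) == 2, all(canvas >= 16),
            n_teeth >= 0,
            contrast_gap >= 0, contrast_gap <= 1,
            noise_sigma >= 0,
            overlap_prob >= 0, overlap_prob <= 1)
  structure(list(canvas = canvas, n_teeth = as.integer(n_teeth),
                 contrast_gap = contrast_gap, noise_sigma = noise_sigma,
                 overlap_prob = overlap_prob, seed = as.integer(seed)),
            class = "phantom_config")
}

# Soft coverage of a capsule (segment with radius) over the pixel grid.
# Returns values in [0,1]; `edge` is the width of the smooth falloff band.
capsule_alpha <- function(rr, cc, p0, p1, radius, edge = 1.5) {
  dr <- p1[1] - p0[1]; dc <- p1[2] - p0[2]
  len2 <- dr * dr + dc * dc
  if (len2 < 1e-12) {
    d <- sqrt((rr - p0[1])^2 + (cc - p0[2])^2)
  } else {
    t <- pmin(pmax(((rr - p0[1]) * dr + (cc - p0[2]) * dc) / len2, 0), 1)
    d <- sqrt((rr - (p0[1] + t * dr))^2 + (cc - (p0[2] + t * dc))^2)
  }
  pmin(pmax(0.5 - (d - radius) / edge, 0), 1)
}

blur3 <- function(m) {
  k <- c(0.25, 0.5, 0.25)
  H <- nrow(m); W <- ncol(m)
  pad_r <- rbind(m[1, , drop = FALSE], m, m[H, , drop = FALSE])
  v <- k[1] * pad_r[1:H, ] + k[2] * pad_r[2:(H + 1), ] + k[3] * pad_r[3:(H + 2), ]
  pad_c <- cbind(v[, 1, drop = FALSE], v, v[, W, drop = FALSE])
  k[1] * pad_c[, 1:W] + k[2] * pad_c[, 2:(W + 1)] + k[3] * pad_c[, 3:(W + 2)]
}

#' Generate a synthetic dental phantom
#'
#' Deterministic in the config (including its seed). Teeth are drawn as a
#' crown capsule plus one or two slanted root capsules with smoothly blurred
#' edges; the crown carries extra brightness while the root sits only
#' `contrast_gap` above the background, reproducing the low-contrast
#' radicular boundary. The ground-truth mask is the union of all tooth
#' shapes.
#'
#' @param config a [phantom_config()].
#' @return an `image_sample`: list with `$image` (`H x W x 3`, values in
#'   `[0,1]`, all channels identical), `$mask` (`H x W` matrix of 0/1) and
#'   `$id`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  H <- config$canvas[1]; W <- config$canvas[2]
  n <- config$n_teeth
  with_seed(config$seed, {
    rr <- matrix(seq_len(H) - 1, H, W)
    cc <- matrix(seq_len(W) - 1, H, W, byrow = TRUE)
    # smooth bone-like background
    ph <- runif(4, 0, 2 * pi)
    bg <- 0.35 +
      0.04 * cos(2 * pi * rr / H + ph[1]) * cos(2 * pi * cc / W + ph[2]) +
      0.03 * sin(2 * pi * 2 * cc / W + ph[3]) * cos(2 * pi * 2 * rr / H + ph[4])
    delta <- matrix(0, H, W)   # tooth brightness above background
    mask <- matrix(0L, H, W)
    if (n > 0) {
      margin <- 0.07 * W
      usable <- W - 2 * margin
      sw <- usable / n
      rc <- 0.42 * sw                       # crown radius
      if (rc < 2.2 || 2.2 * rc > 0.8 * H)
        stop("phantom placement failure: canvas ", H, "x", W,
             " too small for ", n, " teeth")
      crown_len <- 0.22 * H
      root_len <- 0.20 * H
      prev_c <- -Inf
      for (i in seq_len(n)) {
        centre_c <- margin + (i - 0.5) * sw + runif(1, -0.08, 0.08) * sw
        if (i > 1 && runif(1) < config$overlap_prob) {
          # pull onto the left neighbour until the crowns overlap
          centre_c <- min(centre_c, prev_c + 1.6 * rc)
        }
        prev_c <- centre_c
        arch <- 0.06 * H * sin(pi * centre_c / W)
        top_r <- 0.30 * H + arch + runif(1, -0.02, 0.02) * H
        mid_r <- top_r + crown_len
        # crown
        a_crown <- capsule_alpha(rr, cc, c(top_r, centre_c), c(mid_r, centre_c), rc)
        # 1 or 2 roots, slanted
        n_roots <- if (runif(1) < 0.5) 2L else 1L
        a_root <- matrix(0, H, W)
        slants <- if (n_roots == 2L) c(-0.35, 0.35) else runif(1, -0.15, 0.15)
        for (s in slants) {
          p0 <- c(mid_r - 0.2 * rc, centre_c + s * rc)
          p1 <- c(mid_r + root_len, centre_c + s * root_len * 1.2)
          a_root <- pmax(a_root, capsule_alpha(rr, cc, p0, p1, 0.45 * rc))
        }
        alpha <- pmax(a_crown, a_root)
        tooth_delta <- alpha * config$contrast_gap + a_crown * 0.25
        delta <- pmax(delta, tooth_delta)
        mask[alpha >= 0.5] <- 1L
      }
    }
    img <- blur3(bg + delta)
    if (config$noise_sigma > 0)
      img <- img + matrix(rnorm(H * W, sd = config$noise_sigma), H, W)
    img <- pmin(pmax(img, 0), 1)
    image_sample(array(rep(img, 3), dim = c(H, W, 3)), mask,
                 id = sprintf("phantom_%08d", config$seed))
  })
}

#' Construct and validate an image/mask sample
#'
#' @param image `H x W x 3` numeric array with values in `[0,1]`.
#' @param mask `H x W` matrix containing only 0 and 1.
#' @param id character identifier.
#' @return list of class `image_sample`.
#' @export
image_sample <- function(image, mask, id = "sample") {
  if (is.matrix(image)) image <- array(rep(image, 3), dim = c(dim(image), 3))
  stopifnot(length(dim(image)) == 3, dim(image)[3] == 3)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!identical(dim(image)[1:2], dim(mask)))
    stop("image (", paste(dim(image)[1:2], collapse = "x"),
         ") and mask (", paste(dim(mask), collapse = "x"),
         ") have different spatial dimensions")
  if (!all(mask %in% c(0L, 1L))) stop("mask must be binary (0/1)")
  structure(list(image = image, mask = mask, id = as.character(id)),
            class = "image_sample")
}

#' Write samples to disk as PNG pairs with a CSV manifest
#'
#' Images are stored as 8-bit 3-channel PNGs, masks as 8-bit single-channel
#' PNGs with values in `{0, 255}`. The manifest (`manifest.csv`) has columns
#' `id,image_path,mask_path` with paths relative to `directory`.
#'
#' @param samples list of `image_sample` objects.
#' @param directory output directory (created if needed).
#' @return the manifest as a data.frame, invisibly written to
#'   `directory/manifest.csv`.
#' @export
write_dataset <- function(samples, directory) {
  dir.create(file.path(directory, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(directory, "masks"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  rows <- lapply(samples, function(s) {
    ip <- file.path("images", paste0(s$id, ".png"))
    mp <- file.path("masks", paste0(s$id, ".png"))
    write_png(s$image, file.path(directory, ip))
    write_png(s$mask, file.path(directory, mp)) # 1 -> 255
    data.frame(id = s$id, image_path = ip, mask_path = mp)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(directory, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read an image/mask PNG pair
#'
#' The image is scaled to `[0,1]` and replicated to three channels if stored
#' as grayscale; the mask is collapsed to a single channel and binarised at
#' threshold 127 (values > 127 map to 1).
#'
#' @param image_path,mask_path PNG file paths.
#' @param id identifier; defaults to the image file name.
#' @return an `image_sample`.
#' @export
read_sample <- function(image_path, mask_path,
                        id = tools::file_path_sans_ext(basename(image_path))) {
  img <- read_png(image_path)
  msk <- read_png(mask_path)
  if (!identical(dim(img)[1:2], dim(msk)[1:2]))
    stop("shape mismatch: image is ", paste(dim(img)[1:2], collapse = "x"),
         " but mask is ", paste(dim(msk)[1:2], collapse = "x"))
  if (dim(img)[3] == 1L) img <- img[, , c(1, 1, 1), drop = FALSE]
  if (dim(img)[3] == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] == 2L) img <- img[, , c(1, 1, 1), drop = FALSE]
  mask <- (msk[, , 1] > 127) * 1L
  image_sample(img / 255, mask, id = id)
}

#' Load a dataset written by [write_dataset()]
#' @param directory dataset directory containing `manifest.csv`.
#' @return list of `image_sample` objects.
#' @export
read_dataset <- function(directory) {
  manifest <- read.csv(file.path(directory, "manifest.csv"),
                       stringsAsFactors = FALSE)
  lapply(seq_len(nrow(manifest)), function(i) {
    read_sample(file.path(directory, manifest$image_path[i]),
                file.path(directory, manifest$mask_path[i]),
                id = manifest$id[i])
  })
}

#' Deterministic train/validation split
#'
#' Shuffles with the given seed and splits so that the two parts are
#' disjoint and exhaustive; with `ratio = 0.9` and 2000 samples this yields
#' the conventional 1800/200 partition.
#'
#' @param samples list (or vector of ids).
#' @param ratio fraction assigned to the training part, in `(0,1)`.
#' @param seed integer seed.
#' @return list with elements `train` and `val`.
#' @export
split_dataset <- function(samples, ratio = 0.9, seed = 1L) {
  n <- length(samples)
  if (n == 0) stop("cannot split an empty dataset")
  stopifnot(ratio > 0, ratio < 1)
  with_seed(seed, {
    ord <- sample.int(n)
    n_train <- floor(n * ratio + 0.5)
    n_train <- min(max(n_train, 0L), n)
    list(train = samples[sort(ord[seq_len(n_train)])],
         val = samples[sort(ord[setdiff(seq_len(n), seq_len(n_train))])])
  })
}
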