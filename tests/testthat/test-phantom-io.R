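# phantom generation, PNG round trips, dataset IO, splits, augmentation

test_that("phantom generation is deterministic and honours the config", {
  cfg <- phantom_config(canvas = c(64, 128), n_teeth = 5, seed = 11)
  a <- generate_phantom(cfg)
  b <- generate_phantom(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_equal(dim(a$image), c(64, 128, 3))
  expect_true(all(a$image >= 0 & a$image <= 1))
  expect_true(all(a$mask %in% c(0L, 1L)))
  # tri-channel input: all channels identical at generation time
  expect_identical(a$image[, , 1], a$image[, , 2])
  expect_identical(a$image[, , 1], a$image[, , 3])
  # empty case
  z <- generate_phantom(phantom_config(canvas = c(32, 32), n_teeth = 0, seed = 1))
  expect_true(all(z$mask == 0L))
  # different seeds give different phantoms
  c2 <- generate_phantom(phantom_config(canvas = c(64, 128), n_teeth = 5, seed = 12))
  expect_false(identical(a$mask, c2$mask))
})

test_that("forced overlaps merge connected components", {
  s <- generate_phantom(phantom_config(canvas = c(64, 128), n_teeth = 8,
                                       overlap_prob = 1, seed = 3))
  expect_lt(oracle_components(s$mask), 8)
  # and with no overlaps, teeth stay separate
  s0 <- generate_phantom(phantom_config(canvas = c(64, 128), n_teeth = 4,
                                        overlap_prob = 0, seed = 3))
  expect_equal(oracle_components(s0$mask), 4)
})

test_that("root-region contrast respects the configured gap", {
  for (gap in c(0.05, 0.2)) {
    cfg <- phantom_config(canvas = c(96, 192), n_teeth = 6, contrast_gap = gap,
                          noise_sigma = 0.02, seed = 5)
    s <- generate_phantom(cfg)
    img <- s$image[, , 1]
    # root region: bottom 30% of the mask's row span (crowns are higher up
    # and carry extra brightness, so they must be excluded)
    rows <- which(rowSums(s$mask) > 0)
    cut <- min(rows) + 0.7 * (max(rows) - min(rows))
    root <- s$mask
    root[seq_len(nrow(root)) <= cut, ] <- 0L
    # 3-pixel background collar around the whole mask
    pad <- s$mask
    for (i in 1:3) {
      grown <- pad
      grown[-1, ] <- pmax(grown[-1, ], pad[-nrow(pad), ])
      grown[-nrow(pad), ] <- pmax(grown[-nrow(pad), ], pad[-1, ])
      grown[, -1] <- pmax(grown[, -1], pad[, -ncol(pad)])
      grown[, -ncol(pad)] <- pmax(grown[, -ncol(pad)], pad[, -1])
      pad <- grown
    }
    collar <- pad == 1 & s$mask == 0
    diff <- abs(mean(img[root == 1]) - mean(img[collar]))
    expect_lte(diff, gap + 2 * cfg$noise_sigma)
  }
})

test_that("phantom placement fails loudly when the canvas is too small", {
  expect_error(generate_phantom(phantom_config(canvas = c(16, 16), n_teeth = 12,
                                               seed = 1)),
               "placement failure")
})

test_that("PNG round trip is lossless for images and masks", {
  tmp <- withr::local_tempdir()
  s <- generate_phantom(phantom_config(canvas = c(32, 48), n_teeth = 2, seed = 2))
  p <- file.path(tmp, "img.png")
  write_png(s$image, p)
  back <- read_png(p)
  expect_equal(dim(back), c(32, 48, 3))
  expect_equal(back / 255, s$image, tolerance = 1 / 254) # 8-bit quantisation
  # masks round-trip exactly ({0,1} -> {0,255} -> {0,1})
  mp <- file.path(tmp, "mask.png")
  write_png(s$mask, mp)
  mv <- read_png(mp)
  expect_true(all(mv %in% c(0L, 255L)))
  expect_identical((mv[, , 1] > 127) * 1L, s$mask * 1L)
})

test_that("PNG codec agrees with an independent decoder (Pillow)", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  img <- array(runif(20 * 30 * 3), c(20, 30, 3))
  p <- file.path(tmp, "x.png")
  write_png(img, p)
  py <- sprintf(paste0(
    "from PIL import Image; import numpy as np; ",
    "a = np.asarray(Image.open(%s)); ",
    "print(a.shape); print(int(a.astype('int64').sum()))"),
    shQuote(p))
  out <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  expect_equal(out[1], "(20, 30, 3)")
  expect_equal(as.numeric(out[2]), sum(round(img * 255)))
  # and read back a PIL-written PNG (exercises third-party filter choices)
  q <- file.path(tmp, "y.png")
  py2 <- sprintf(paste0(
    "from PIL import Image; import numpy as np; ",
    "rng = np.random.default_rng(0); ",
    "a = rng.integers(0, 256, (13, 17, 3), dtype='uint8'); ",
    "Image.fromarray(a).save(%s); print(int(a.astype('int64').sum()))"),
    shQuote(q))
  out2 <- system2("python", c("-c", shQuote(py2)), stdout = TRUE)
  back <- read_png(q)
  expect_equal(sum(back), as.numeric(out2[1]))
})

test_that("write_dataset / read_sample round trip with manifest", {
  tmp <- withr::local_tempdir()
  samples <- lapply(1:10, function(i)
    generate_phantom(phantom_config(canvas = c(32, 64), n_teeth = 2, seed = i)))
  man <- write_dataset(samples, tmp)
  expect_equal(nrow(man), 10)
  expect_equal(length(list.files(file.path(tmp, "images"))), 10)
  expect_equal(length(list.files(file.path(tmp, "masks"))), 10)
  s <- read_sample(file.path(tmp, man$image_path[1]),
                   file.path(tmp, man$mask_path[1]))
  expect_identical(s$mask, samples[[1]]$mask)
  expect_equal(dim(s$image), dim(samples[[1]]$image))
  back <- read_dataset(tmp)
  expect_equal(length(back), 10)
  expect_identical(back[[3]]$mask, samples[[3]]$mask)
})

test_that("read_sample conventions: scaling, replication, threshold, errors", {
  tmp <- withr::local_tempdir()
  # grayscale image file replicated to 3 channels
  g <- matrix(runif(20 * 24), 20, 24)
  write_png(g, file.path(tmp, "g.png"))
  m <- matrix(0L, 20, 24); m[4:10, 5:9] <- 1L
  write_png(m, file.path(tmp, "m.png"))
  s <- read_sample(file.path(tmp, "g.png"), file.path(tmp, "m.png"))
  expect_equal(dim(s$image), c(20, 24, 3))
  expect_identical(s$image[, , 1], s$image[, , 3])
  expect_true(all(s$image >= 0 & s$image <= 1))
  # mask value 128 maps to 1, 127 maps to 0
  mm <- matrix(c(128, 127, 255, 0) / 255, 2, 2)
  write_png(mm, file.path(tmp, "mm.png"))
  write_png(matrix(0.5, 2, 2), file.path(tmp, "i2.png"))
  s2 <- read_sample(file.path(tmp, "i2.png"), file.path(tmp, "mm.png"))
  expect_identical(s2$mask, matrix(c(1L, 0L, 1L, 0L), 2, 2))
  # shape mismatch names both shapes
  write_png(matrix(0.5, 8, 8), file.path(tmp, "i3.png"))
  expect_error(read_sample(file.path(tmp, "i3.png"), file.path(tmp, "m.png")),
               "8x8.*20x24")
})

test_that("split_dataset partitions deterministically", {
  ids <- sprintf("im%04d", 1:2000)
  sp <- split_dataset(ids, 0.9, seed = 4)
  expect_equal(length(sp$train), 1800)
  expect_equal(length(sp$val), 200)
  sp2 <- split_dataset(ids, 0.9, seed = 4)
  expect_identical(sp, sp2)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), ids)
  sp3 <- split_dataset(as.list(1:10), 0.9, seed = 1)
  expect_equal(lengths(list(sp3$train, sp3$val)), c(9L, 1L))
  expect_error(split_dataset(list(), 0.9, 1), "empty")
})

test_that("augmentation: identity, involution, label safety", {
  s <- generate_phantom(phantom_config(canvas = c(48, 64), n_teeth = 3, seed = 6))
  ident <- augment_spec() # all-identity defaults
  expect_equal(augment(s, ident)$image, s$image, tolerance = 1e-12)
  expect_identical(augment(s, ident)$mask, s$mask)
  # mirror twice = identity
  mir <- augment_spec(mirror = TRUE)
  expect_equal(augment(augment(s, mir), mir)$image, s$image, tolerance = 1e-12)
  expect_identical(augment(augment(s, mir), mir)$mask, s$mask)
  # photometric ops never touch the mask; masks stay binary under any spec
  set.seed(31)
  for (i in 1:20) {
    sp <- augment_spec(brightness = c(-0.2, 0.2), gamma = c(0.7, 1.4),
                       noise_sigma = runif(1, 0, 0.1), seed = i)
    a <- augment(s, sp)
    expect_identical(a$mask, s$mask) # photometric only
    spg <- augment_spec(scale = c(0.8, 1.2), rotate_deg = c(-10, 10),
                        translate = c(-4, 4), elastic_alpha = runif(1, 0, 2),
                        mirror = i %% 2 == 0, seed = i)
    g <- augment(s, spg)
    expect_true(all(g$mask %in% c(0L, 1L)))
    expect_equal(dim(g$image), dim(s$image))
  }
  # geometric ops change image and mask consistently (scale grows the mask)
  up <- augment(s, augment_spec(scale = c(1.5, 1.5), seed = 1))
  expect_gt(sum(up$mask), sum(s$mask))
})
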