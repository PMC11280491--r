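# Adaptive deformable pathway: stem -> four stages of DCNv3-based base
# blocks with inter-stage downsampling, emitting a stride-4/8/16/32 pyramid.
#
# The DCNv3 operator computes, for every output pixel p and group g,
#   y_g(p) = W_g * sum_k m_gk(p) * x_g(p + p_k + dp_gk(p))
# where the K base offsets p_k form a fixed 3x3 grid, the per-pixel offsets
# dp and modulation logits are predicted by 3x3 convolutions over the block
# input, and the modulation weights m_gk are softmax-normalised over k within
# each group. Fractional sampling uses bilinear interpolation with zero
# padding outside the grid.

base_grid <- function(K) {
  s <- as.integer(round(sqrt(K)))
  if (s * s != K) stop("points K must be a perfect square (3x3 grid default)")
  half <- (s - 1) / 2
  rbind(rep(seq(-half, half), each = s), rep(seq(-half, half), times = s))
}

#' Bilinearly sample a feature map at a fractional location
#'
#' Zero padding outside the grid. Coordinates are (row, col), 0-based.
#'
#' @param feature `C x H x W` array.
#' @param location numeric `(row, col)`, possibly fractional.
#' @return numeric vector of length `C`.
#' @export
bilinear_sample <- function(feature, location) {
  stopifnot(length(dim(feature)) == 3, all(is.finite(location)))
  C <- dim(feature)[1]; H <- dim(feature)[2]; W <- dim(feature)[3]
  r <- location[1]; cl <- location[2]
  r0 <- floor(r); c0 <- floor(cl)
  ar <- r - r0; ac <- cl - c0
  acc <- numeric(C)
  for (q in list(c(0, 0, (1 - ar) * (1 - ac)), c(1, 0, ar * (1 - ac)),
                 c(0, 1, (1 - ar) * ac), c(1, 1, ar * ac))) {
    rr <- r0 + q[1]; cc <- c0 + q[2]
    if (rr >= 0 && rr < H && cc >= 0 && cc < W && q[3] != 0)
      acc <- acc + q[3] * feature[, rr + 1, cc + 1]
  }
  acc
}

#' Sampling specification for the deformable operator
#'
#' Carries the fixed base grid together with explicit per-pixel offsets and
#' modulation logits; the learned block predicts these fields itself, while
#' tests and oracles can supply them directly.
#'
#' @param groups number of aggregation groups G (channels must divide by G).
#' @param points sampled points K per group (perfect square; default 9).
#' @param offsets `2*G*K x H x W` array of (row, col) displacements, channel
#'   layout `d + 2*(k + K*g)` (0-based), or `NULL` for zero offsets.
#' @param modulation_logits `G*K x H x W` array, channel layout `k + K*g`,
#'   or `NULL` for equal logits (uniform weights 1/K after softmax).
#' @return object of class `sampling_spec`.
#' @export
sampling_spec <- function(groups = 4L, points = 9L, offsets = NULL,
                          modulation_logits = NULL) {
  stopifnot(groups >= 1, points >= 1)
  structure(list(groups = as.integer(groups), points = as.integer(points),
                 base_offsets = base_grid(points), offsets = offsets,
                 modulation_logits = modulation_logits),
            class = "sampling_spec")
}

softmax_groups <- function(logits, G, K) {
  # softmax over k within each group, per pixel
  d <- dim(logits)
  m <- array(logits, dim = c(K, G * d[2] * d[3]))
  m <- exp(sweep(m, 2, apply(m, 2, max), "-"))
  m <- sweep(m, 2, colSums(m), "/")
  array(m, dim = d)
}

#' Deformable convolution v3 on explicit sampling fields
#'
#' Functional form used by tests and oracles: output pixel
#' `y(p) = sum_g sum_k w_g m_gk x_g(p + p_k + dp_gk)` with modulation
#' weights softmaxed over k within each group and bilinear fractional
#' sampling.
#'
#' @param feature `C x H x W` array; `C` must be divisible by `spec$groups`.
#' @param projection list of G per-group projection matrices (`C/G x C/G`),
#'   or `NULL` for identity projections.
#' @param spec a [sampling_spec()].
#' @return `C x H x W` array.
#' @export
dcn_v3 <- function(feature, projection = NULL, spec = sampling_spec()) {
  d <- dim(feature)
  C <- d[1]; H <- d[2]; W <- d[3]
  G <- spec$groups; K <- spec$points
  if (C %% G != 0)
    stop("channels (", C, ") not divisible by groups (", G, ")")
  off <- spec$offsets %||% array(0, dim = c(2 * G * K, H, W))
  logits <- spec$modulation_logits %||% array(0, dim = c(G * K, H, W))
  m <- softmax_groups(logits, G, K)
  y <- cpp_dcn_fwd(feature, off, m, spec$base_offsets, G)
  if (!is.null(projection)) {
    Cg <- C / G
    Y <- matrix(y, nrow = C)
    for (g in seq_len(G)) {
      idx <- (g - 1) * Cg + seq_len(Cg)
      Y[idx, ] <- projection[[g]] %*% Y[idx, ]
    }
    y <- array(Y, dim = d)
  }
  y
}

# Learned DCNv3 module: 3x3 conv predictors for offsets and modulation
# logits, softmax over k, compiled sampling core, per-group projection.
nn_dcn <- function(C, G = 4L, K = 9L) {
  if (C %% G != 0) stop("channels (", C, ") not divisible by groups (", G, ")")
  Cg <- C %/% G
  off_pred <- nn_conv2d(C, 2L * G * K, 3L, init_gain = 0.02) # near-zero offsets at init
  mod_pred <- nn_conv2d(C, G * K, 3L, init_gain = 0.02)
  proj <- lapply(seq_len(G), function(g) nn_pixlin(Cg, Cg))
  pk <- base_grid(K)
  m <- list(off_pred = off_pred, mod_pred = mod_pred, proj = proj,
            G = G, K = K, C = C)
  m$fwd <- function(x) {
    off <- off_pred$fwd(x)
    logits <- mod_pred$fwd(x)
    # grouped softmax over k (works on tsr via reshape ops)
    d <- dim(vals(logits))
    lg <- as_tsr(logits)
    lg2 <- record(tsr(array(lg$v, dim = c(K, G * d[2] * d[3]))), list(lg),
                  function(dy) list(array(dy, dim = d)))
    mm <- as_tsr(op_softmax1(lg2))
    flatdim <- dim(mm$v)
    mm3 <- record(tsr(array(mm$v, dim = d)), list(mm),
                  function(dy) list(array(dy, dim = flatdim)))
    s <- op_dcn_core(x, off, mm3, pk, G)
    parts <- lapply(seq_len(G), function(g) {
      idx <- (g - 1) * Cg + seq_len(Cg)
      proj[[g]]$fwd(op_slice_c(s, idx))
    })
    op_concat_c(parts)
  }
  m
}

# Base block: out = LN( MLP( LN(DCN(f)) + f ) + LN(DCN(f)) ), with optional
# per-channel feature scaling on the MLP branch and DropPath (training only).
nn_base_block <- function(C, G = 4L, K = 9L, droppath = 0,
                          use_layer_scale = TRUE, mlp_ratio = 4) {
  dcn <- nn_dcn(C, G, K)
  ln1 <- nn_layernorm(C)
  ln2 <- nn_layernorm(C)
  mlp <- nn_mlp(C, mlp_ratio)
  scale <- if (use_layer_scale) param(rep(1, C)) else NULL
  m <- list(dcn = dcn, ln1 = ln1, ln2 = ln2, mlp = mlp, scale = scale,
            droppath = droppath)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    a <- ln1$fwd(dcn$fwd(x))          # LN(DCN(f))
    br <- mlp$fwd(op_add(a, x))       # MLP(LN(DCN(f)) + f)
    if (!is.null(scale)) br <- op_channel_affine(br, scale)
    br <- op_droppath(br, droppath)
    ln2$fwd(op_add(br, a))
  }
  m
}

# Stem: two stride-2 3x3 convolutions with layer normalisation and GELU;
# output stride 4.
nn_adaptive_stem <- function(cout) {
  mid <- max(1L, cout %/% 2L)
  c1 <- nn_conv2d(3L, mid, 3L, stride = 2L, pad = 1L)
  n1 <- nn_layernorm(mid)
  c2 <- nn_conv2d(mid, cout, 3L, stride = 2L, pad = 1L)
  n2 <- nn_layernorm(cout)
  m <- list(c1 = c1, n1 = n1, c2 = c2, n2 = n2)
  m$fwd <- function(x) n2$fwd(c2$fwd(op_gelu(n1$fwd(c1$fwd(x)))))
  m
}

#' Build the adaptive deformable encoder pathway
#'
#' Stem (stride 4) followed by four stages of DCNv3 base blocks; each stage
#' output is one pyramid level (strides 4, 8, 16, 32), with a stride-2
#' downsampling convolution between stages. DropPath rates scale linearly
#' with block depth up to `droppath_rate`.
#'
#' @param channels integer vector of 4 stage widths (non-decreasing).
#' @param depths integer vector of 4 stage depths (base blocks per stage).
#' @param groups,points DCNv3 aggregation groups G and sampled points K.
#' @param droppath_rate maximal stochastic-depth rate.
#' @param mlp_ratio hidden expansion of the per-pixel MLP.
#' @return module with `$fwd(image)` returning a list of 4 feature maps;
#'   `image` is a `3 x H x W` array (H, W divisible by 32).
#' @export
deformable_pathway <- function(channels = c(64L, 128L, 256L, 512L),
                               depths = c(2L, 2L, 2L, 2L), groups = 4L,
                               points = 9L, droppath_rate = 0.1,
                               mlp_ratio = 4) {
  stopifnot(length(channels) == 4, length(depths) == 4,
            !is.unsorted(channels))
  total <- sum(depths)
  rates <- if (total > 1) seq(0, droppath_rate, length.out = total) else 0
  bi <- 0L
  stages <- list()
  downs <- list()
  stem <- nn_adaptive_stem(channels[1])
  for (s in 1:4) {
    blocks <- list()
    for (b in seq_len(depths[s])) {
      bi <- bi + 1L
      blocks[[b]] <- nn_base_block(channels[s], groups, points,
                                   droppath = rates[bi], mlp_ratio = mlp_ratio)
    }
    stages[[s]] <- blocks
    if (s < 4)
      downs[[s]] <- nn_conv2d(channels[s], channels[s + 1], 3L, stride = 2L,
                              pad = 1L)
  }
  m <- list(stem = stem, stages = stages, downs = downs, channels = channels,
            depths = depths)
  m$fwd <- function(x) {
    f <- stem$fwd(x)
    pyr <- vector("list", 4)
    for (s in 1:4) {
      for (blk in stages[[s]]) f <- blk$fwd(f)
      pyr[[s]] <- f
      if (s < 4) f <- downs[[s]]$fwd(f)
    }
    pyr
  }
  m
}
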