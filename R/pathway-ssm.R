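# State-space pathway: 7x7/stride-2 stem, then four units of
# {stride-2 subsampling -> TSMamba block}, each unit output projected to the
# channel width of the matching deformable-pathway level.
#
# The sequence core is a selective scan: a causal linear recurrence
#   h_t = exp(delta_t * A) .* h_{t-1} + delta_t * B_t * x_t,   y_t = C_t . h_t
# computed per channel with h_0 = 0, where delta, B and C are produced per
# timestep by learned projections of the input (input-dependent selectivity)
# and A is a learned negative decay. The tri-directional module (ToM) runs
# the scan over forward-raster, reverse-raster and transposed-raster
# flattenings of the 2-D grid and sums the three results.

#' Explicit selective-scan parameters
#'
#' @param A `C x N` state decay matrix (usually negative).
#' @param delta `C x T` positive step sizes.
#' @param B,C_out `N x T` input and output maps per timestep.
#' @return object of class `scan_params`.
#' @export
scan_params <- function(A, delta, B, C_out) {
  stopifnot(nrow(B) == ncol(A), all(dim(B) == dim(C_out)),
            nrow(delta) == nrow(A))
  structure(list(A = A, delta = delta, B = B, C_out = C_out),
            class = "scan_params")
}

#' Selective scan over a sequence of channel vectors
#'
#' @param x_seq `C x T` matrix (one column per timestep).
#' @param params a [scan_params()] with matching dimensions.
#' @return `C x T` matrix of outputs.
#' @export
selective_scan <- function(x_seq, params) {
  x_seq <- as.matrix(x_seq)
  if (ncol(x_seq) == 0) stop("selective_scan: empty sequence")
  stopifnot(inherits(params, "scan_params"),
            nrow(params$delta) == nrow(x_seq),
            ncol(params$delta) == ncol(x_seq),
            ncol(params$B) == ncol(x_seq))
  cpp_scan_fwd(x_seq, params$delta, params$A, params$B, params$C_out, FALSE)$y
}

# Learned Mamba layer on a (C, T) sequence tensor: input-dependent delta
# (positivity via softplus), B, C projections, state decay A = -exp(A_log),
# and a multiplicative SiLU gate branch.
nn_mamba <- function(C, N = 16L) {
  wd <- nn_pixseq_lin(C, C)
  wb <- nn_pixseq_lin(C, N)
  wc <- nn_pixseq_lin(C, N)
  wz <- nn_pixseq_lin(C, C)
  a_log <- param(matrix(log(seq(1, N) / 2 + 0.5), C, N, byrow = TRUE))
  d_bias <- param(rep(-1, C)) # softplus(-1) ~ 0.31 initial step
  m <- list(wd = wd, wb = wb, wc = wc, wz = wz, a_log = a_log, d_bias = d_bias)
  m$fwd <- function(x) { # x: tsr (C,T)
    x <- as_tsr(x)
    delta <- op_softplus(op_seq_bias(wd$fwd(x), d_bias))
    B <- wb$fwd(x)
    Cc <- wc$fwd(x)
    A <- op_neg_exp(a_log)
    y <- op_scan_core(x, delta, A, B, Cc)
    op_mul(y, op_silu(wz$fwd(x)))
  }
  m
}

# Linear map applied to every column of a (C, T) matrix.
nn_pixseq_lin <- function(cin, cout, bias = TRUE) {
  w <- param(matrix(he_init(cin, cout * cin), cout, cin))
  b <- if (bias) param(numeric(cout)) else NULL
  m <- list(w = w, b = b)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    xv <- x$v
    Y <- w$v %*% xv
    if (!is.null(b)) Y <- Y + b$v
    out <- tsr(Y)
    record(out, list(x, w, b), function(dy) {
      list(crossprod(w$v, dy), tcrossprod(dy, xv),
           if (is.null(b)) NULL else rowSums(dy))
    })
  }
  m
}

op_seq_bias <- function(x, b) {
  x <- as_tsr(x)
  out <- tsr(x$v + b$v)
  record(out, list(x, b), function(dy) list(dy, rowSums(dy)))
}

# Pixel orderings for the three scan directions of a (C,H,W) map. Values are
# indices into the column-major (h fastest) pixel order.
tom_orders <- function(H, W) {
  colmaj <- seq_len(H * W)
  # forward raster: row by row, left to right (w fastest)
  fwd <- as.integer(t(matrix(colmaj, H, W)))
  list(forward = fwd, reverse = rev(fwd), slice = colmaj)
}

#' Gated spatial convolution (GSC) module
#'
#' `gsc(f) = f + C3x3( C3x3(f) * C1x1(f) )`, the inner branches each with
#' layer normalisation and GELU, multiplied elementwise as a gate, and the
#' outer 3x3 convolution feeding a residual connection.
#'
#' @param C channel count.
#' @return module with `$fwd(x)`.
#' @export
nn_gsc <- function(C) {
  c3 <- nn_conv2d(C, C, 3L)
  n3 <- nn_layernorm(C)
  c1 <- nn_conv2d(C, C, 1L, pad = 0L)
  n1 <- nn_layernorm(C)
  co <- nn_conv2d(C, C, 3L)
  m <- list(c3 = c3, n3 = n3, c1 = c1, n1 = n1, co = co)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    b3 <- op_gelu(n3$fwd(c3$fwd(x)))
    b1 <- op_gelu(n1$fwd(c1$fwd(x)))
    op_add(x, co$fwd(op_mul(b3, b1)))
  }
  m
}

#' Tri-directional Mamba (ToM) module
#'
#' Flattens a `C x H x W` map into forward-raster, reverse-raster and
#' transposed-raster (column-major "slice") sequences, runs a selective scan
#' over each (independent parameters per direction unless `shared`), maps
#' each result back to the grid in its own ordering, and sums the three.
#'
#' @param C channels; `N` state dimension; `shared` share scan parameters
#'   across directions; `delta_fn` optional test hook replacing the scan
#'   (e.g. `identity`).
#' @return module with `$fwd(x)`.
#' @export
nn_tom <- function(C, N = 16L, shared = FALSE, delta_fn = NULL) {
  scan1 <- nn_mamba(C, N)
  scan2 <- if (shared) scan1 else nn_mamba(C, N)
  scan3 <- if (shared) scan1 else nn_mamba(C, N)
  m <- list(scan1 = scan1, scan2 = scan2, scan3 = scan3)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    d <- dim(x$v)
    H <- d[2]; W <- d[3]
    ords <- tom_orders(H, W)
    run <- function(scan, ord) {
      seqx <- op_flatten_seq(x, ord)
      y <- if (is.null(delta_fn)) scan$fwd(seqx) else {
        r <- delta_fn(vals(seqx))
        if (is_tsr(seqx) && tape_active()) record(tsr(r), list(seqx), function(dy) list(dy)) else tsr(r)
      }
      op_unflatten_seq(y, ord, H, W)
    }
    op_add(op_add(run(scan1, ords$forward), run(scan2, ords$reverse)),
           run(scan3, ords$slice))
  }
  m
}

#' TSMamba block
#'
#' With `g = GSC(f)` and `u = LN(g) + g`, computes
#' `out = MLP(LN(ToM(u) + ToM(LN(u))))`; the two ToM applications share one
#' module. `gsc_fn`, `tom_fn` and `mlp_fn` are test hooks that replace the
#' corresponding sub-module by an arbitrary function (e.g. `identity`).
#'
#' @param C channels; `N` scan state dimension; `mlp_ratio` MLP expansion.
#' @return module with `$fwd(x)`.
#' @export
nn_tsmamba <- function(C, N = 16L, mlp_ratio = 4, gsc_fn = NULL,
                       tom_fn = NULL, mlp_fn = NULL) {
  gsc <- nn_gsc(C)
  tom <- nn_tom(C, N)
  ln1 <- nn_layernorm(C)
  ln2 <- nn_layernorm(C)
  ln3 <- nn_layernorm(C)
  mlp <- nn_mlp(C, mlp_ratio)
  gf <- gsc_fn %||% gsc$fwd
  tf <- tom_fn %||% tom$fwd
  mf <- mlp_fn %||% mlp$fwd
  m <- list(gsc = gsc, tom = tom, ln1 = ln1, ln2 = ln2, ln3 = ln3, mlp = mlp)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    g <- gf(x)
    u <- op_add(ln1$fwd(g), g)
    v <- tf(u)
    mf(ln3$fwd(op_add(v, tf(ln2$fwd(u)))))
  }
  m
}

#' State-space pathway stem
#'
#' A 7x7 convolution with padding 3 and stride 2 producing `cout` channels at
#' half resolution.
#'
#' @param cout output channels (default 48).
#' @return module with `$fwd(image)`; exposes `$conv` for introspection of
#'   kernel/padding/stride.
#' @export
nn_ssm_stem <- function(cout = 48L) {
  conv <- nn_conv2d(3L, cout, 7L, stride = 2L, pad = 3L)
  nrm <- nn_layernorm(cout)
  m <- list(conv = conv, nrm = nrm,
            kernel = 7L, pad = 3L, stride = 2L)
  m$fwd <- function(x) op_gelu(nrm$fwd(conv$fwd(x)))
  m
}

#' Build the state-space encoder pathway
#'
#' Stem (stride 2, `stem_channels` wide) followed by four units of
#' {stride-2 subsampling convolution with channel doubling -> TSMamba
#' block}; each unit output is projected by a 1x1 convolution to the width
#' of the matching deformable-pathway level, so the two pyramids are
#' channel-aligned at strides 4, 8, 16 and 32.
#'
#' @param channels target pyramid widths (the deformable stage widths).
#' @param stem_channels stem width (default 48).
#' @param state_dim scan state dimension N.
#' @param mlp_ratio MLP expansion inside TSMamba blocks.
#' @return module with `$fwd(image)` returning a list of 4 feature maps.
#' @export
ssm_pathway <- function(channels = c(64L, 128L, 256L, 512L),
                        stem_channels = 48L, state_dim = 16L, mlp_ratio = 4) {
  stopifnot(length(channels) == 4)
  stem <- nn_ssm_stem(stem_channels)
  widths <- stem_channels * 2L^(1:4)
  subs <- list(); blocks <- list(); projs <- list()
  prev <- stem_channels
  for (s in 1:4) {
    subs[[s]] <- nn_conv2d(prev, widths[s], 3L, stride = 2L, pad = 1L)
    blocks[[s]] <- nn_tsmamba(widths[s], N = state_dim, mlp_ratio = mlp_ratio)
    projs[[s]] <- nn_pixlin(widths[s], channels[s])
    prev <- widths[s]
  }
  m <- list(stem = stem, subs = subs, blocks = blocks, projs = projs,
            channels = channels, widths = widths)
  m$fwd <- function(x) {
    f <- stem$fwd(x)
    pyr <- vector("list", 4)
    for (s in 1:4) {
      f <- subs[[s]]$fwd(f)
      f <- blocks[[s]]$fwd(f)
      pyr[[s]] <- projs[[s]]$fwd(f)
    }
    pyr
  }
  m
}
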