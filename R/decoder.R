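# Hierarchical convergence decoder (HCD). Starting from the SEM output at
# stride 32, four resolution levels of {transposed-convolution upsampling ->
# TAFI fusion with the two encoder skip features -> refinement convolution}
# recover full resolution; the head is a pair of learned x2 upsamplings and
# a 1x1 convolution to a single-channel logit map.
#
# TAFI gates the two skip features with a sigmoid of summed local (pointwise
# bottleneck) and global (pooled) attention, takes the convex combination
# X*g + Y*(1-g), and concatenates the decoder stream.

#' Local attention module (pointwise bottleneck)
#'
#' `BN(Conv1x1(ReLU(BN(Conv1x1(x)))))` with a channel bottleneck `C/ratio`;
#' purely per-pixel, no spatial mixing.
#'
#' @param C channels; `ratio` bottleneck reduction.
#' @return module with `$fwd(x)`.
#' @export
nn_local_attention <- function(C, ratio = 4L) {
  mid <- max(1L, C %/% ratio)
  c1 <- nn_pixlin(C, mid)
  b1 <- nn_batchnorm(mid)
  c2 <- nn_pixlin(mid, C)
  b2 <- nn_batchnorm(C)
  m <- list(c1 = c1, b1 = b1, c2 = c2, b2 = b2)
  m$fwd <- function(x) b2$fwd(c2$fwd(op_relu(b1$fwd(c1$fwd(x)))))
  m
}

#' Global attention module (pooled bottleneck)
#'
#' Global average pool to 1x1, the same conv stack as the local branch, then
#' broadcast back over the grid; the output is spatially constant.
#'
#' @inheritParams nn_local_attention
#' @return module with `$fwd(x)`.
#' @export
nn_global_attention <- function(C, ratio = 4L) {
  att <- nn_local_attention(C, ratio)
  m <- list(att = att)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    d <- dim(x$v)
    op_broadcast_hw(att$fwd(op_global_avgpool(x)), d[2], d[3])
  }
  m
}

#' Triplet attentional feature integration (TAFI)
#'
#' With `s = X + Y`, gate `g = sigmoid(LoAtt(s) + GlAtt(s))`, the module
#' returns `Cat(X*g + Y*(1-g), f)` — a pixelwise convex combination of the
#' two encoder skip features concatenated with the decoder stream.
#'
#' @param C channel width of X and Y; `ratio` attention bottleneck.
#' @return module whose `$fwd(X, Y, f, gate = NULL)` accepts an optional
#'   gate override (array in `(0,1)`) as a test hook; `f = NULL` omits the
#'   concatenation.
#' @export
nn_tafi <- function(C, ratio = 4L) {
  lo <- nn_local_attention(C, ratio)
  gl <- nn_global_attention(C, ratio)
  m <- list(lo = lo, gl = gl)
  m$fwd <- function(X, Y, f = NULL, gate = NULL) {
    X <- as_tsr(X); Y <- as_tsr(Y)
    if (!identical(dim(X$v), dim(Y$v)))
      stop("tafi: skip features disagree in shape (",
           paste(dim(X$v), collapse = "x"), " vs ",
           paste(dim(Y$v), collapse = "x"), ")")
    g <- if (is.null(gate)) {
      s <- op_add(X, Y)
      op_sigmoid(op_add(lo$fwd(s), gl$fwd(s)))
    } else as_tsr(gate)
    fused <- op_add(op_mul(X, g), op_mul(Y, op_const_add(op_const_mul(g, -1), 1)))
    if (is.null(f)) fused else op_concat_c(list(fused, as_tsr(f)))
  }
  m
}

#' Build the hierarchical convergence decoder
#'
#' @param enc_channels encoder pyramid widths (strides 4, 8, 16, 32).
#' @param dec_channels decoder widths deepest-first `(d4, d3, d2, d1)`.
#' @param head_channels width of the full-resolution head stages.
#' @param attention_ratio TAFI attention bottleneck.
#' @param disable_tafi integer vector of TAFI site indices (1 = deepest
#'   fusion site at stride 16, 3 = shallowest at stride 4) where gated
#'   fusion is replaced by plain concatenation of `X`, `Y` and `f`.
#' @return module with `$fwd(pyr_x, pyr_y, sem_out)` mapping the two
#'   encoder pyramids and the stride-32 SEM output to full-resolution
#'   single-channel logits; `$tafi` lists the three fusion modules.
#' @export
hcd_decoder <- function(enc_channels = c(64L, 128L, 256L, 512L),
                        dec_channels = c(256L, 128L, 64L, 32L),
                        head_channels = 16L, attention_ratio = 4L,
                        disable_tafi = integer(0)) {
  stopifnot(length(enc_channels) == 4, length(dec_channels) == 4)
  d4 <- dec_channels[1]
  refine4 <- nn_conv2d(d4, d4, 3L)
  nrm4 <- nn_layernorm(d4)
  ups <- list(); tafis <- list(); refines <- list(); nrms <- list()
  # level l = 1..3 walks strides 16, 8, 4 consuming encoder levels 3, 2, 1
  for (l in 1:3) {
    enc_l <- enc_channels[4 - l]
    din <- if (l == 1) d4 else dec_channels[l]
    dout <- dec_channels[l + 1]
    ups[[l]] <- nn_convt2d(din, dout)
    tafis[[l]] <- nn_tafi(enc_l, attention_ratio)
    cin <- if (l %in% disable_tafi) 2L * enc_l + dout else enc_l + dout
    refines[[l]] <- nn_conv2d(cin, dout, 3L)
    nrms[[l]] <- nn_layernorm(dout)
  }
  up_h1 <- nn_convt2d(dec_channels[4], head_channels)
  nrm_h <- nn_layernorm(head_channels)
  up_h2 <- nn_convt2d(head_channels, head_channels)
  head <- nn_conv2d(head_channels, 1L, 1L, pad = 0L)
  m <- list(refine4 = refine4, nrm4 = nrm4, ups = ups, tafi = tafis,
            refines = refines, nrms = nrms, up_h1 = up_h1, nrm_h = nrm_h,
            up_h2 = up_h2, head = head, disable_tafi = disable_tafi,
            enc_channels = enc_channels, dec_channels = dec_channels)
  m$fwd <- function(pyr_x, pyr_y, sem_out) {
    f <- op_gelu(nrm4$fwd(refine4$fwd(as_tsr(sem_out))))
    for (l in 1:3) {
      f <- ups[[l]]$fwd(f)
      X <- as_tsr(pyr_x[[4 - l]]); Y <- as_tsr(pyr_y[[4 - l]])
      if (!identical(dim(X$v)[2:3], dim(vals(f))[2:3]))
        stop("hcd: pyramid level ", 4 - l, " misaligned with decoder stream (",
             paste(dim(X$v)[2:3], collapse = "x"), " vs ",
             paste(dim(vals(f))[2:3], collapse = "x"), ")")
      f <- if (l %in% disable_tafi) op_concat_c(list(X, Y, f))
           else tafis[[l]]$fwd(X, Y, f)
      f <- op_gelu(nrms[[l]]$fwd(refines[[l]]$fwd(f)))
    }
    f <- op_gelu(nrm_h$fwd(up_h1$fwd(f)))
    head$fwd(up_h2$fwd(f))
  }
  m
}
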