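# Semantic enhancement module (SEM): fuses the two deepest encoder outputs
# with a 7x7 Conv-BN-ReLU block, then enriches the fused map through two
# parallel branches — a per-pixel MLP for global channel mixing and a
# learnable visual codebook (LVC) that soft-assigns every pixel to K learned
# codewords and turns the weighted squared residuals into a sigmoid gate —
# and concatenates the branch outputs.

#' Learnable visual codebook
#'
#' @param C channel width of the fused feature map.
#' @param K number of codewords.
#' @param negate_distance if `TRUE` the assignment logits are
#'   `-alpha_k * ||x - mu_k||^2` (far pixels get small weight, the
#'   convention of visual-center encoders); if `FALSE` (default) the logits
#'   are `+alpha_k * ||x - mu_k||^2`, following the printed soft-assignment
#'   form literally.
#' @return module with `$fwd(x)`, `$mu`, `$alpha`, `$conv`.
#' @export
nn_lvc <- function(C, K = 64L, negate_distance = FALSE) {
  mu <- param(matrix(rnorm(C * K, sd = 0.5), C, K))
  alpha <- param(rep(0.05, K))
  gate <- nn_pixlin(C, C)
  m <- list(mu = mu, alpha = alpha, conv = gate, K = K,
            negate_distance = negate_distance)
  m$fwd <- function(x) {
    x <- as_tsr(x)
    d <- dim(x$v)
    P <- d[2] * d[3]
    xm <- tsr_reshape(x, c(d[1], P))
    # squared distances d2[k,p] = sum_c (x - mu_k)^2, via the expansion
    # ||x||^2 - 2 mu'x + ||mu||^2 so everything stays in matrix ops
    x2 <- op_colsum(op_square(xm))                        # (1,P)
    mu2 <- op_rowsum_t(op_square(mu))                     # (K,1)
    cross <- op_matmul(op_transpose(mu), xm)              # (K,P)
    d2 <- op_add_rc(op_const_mul(cross, -2), mu2, x2)     # (K,P)
    sgn <- if (negate_distance) -1 else 1
    logits <- op_scale_rows(d2, alpha, sgn)
    w <- op_softmax1(logits)                              # (K,P), sums to 1
    # r[c,p] = sum_k w[k,p] (x[c,p]-mu[c,k])^2
    #        = x^2 - 2 x .* (mu w) + (mu^2 w)   (since sum_k w = 1)
    muw <- op_matmul(mu, w)                               # (C,P)
    mu2w <- op_matmul(op_square(mu), w)
    r <- op_add(op_sub(op_square(xm), op_const_mul(op_mul(xm, muw), 2)), mu2w)
    r3 <- tsr_reshape(r, d)
    g <- op_sigmoid(gate$fwd(r3))
    op_add(x, op_mul(x, g))
  }
  m
}

# reshape that keeps gradients flowing (values are shared column-major)
tsr_reshape <- function(x, newdim) {
  x <- as_tsr(x)
  old <- dim(x$v) %||% length(x$v)
  v <- x$v
  dim(v) <- newdim
  out <- tsr(v)
  record(out, list(x), function(dy) {
    dim(dy) <- old
    list(dy)
  })
}

op_transpose <- function(x) {
  x <- as_tsr(x)
  out <- tsr(t(x$v))
  record(out, list(x), function(dy) list(t(dy)))
}

op_colsum <- function(x) { # (C,P) -> (1,P)
  x <- as_tsr(x)
  d <- dim(x$v)
  out <- tsr(matrix(colSums(x$v), 1, d[2]))
  record(out, list(x), function(dy)
    list(matrix(rep(dy, each = d[1]), d[1], d[2])))
}

op_rowsum_t <- function(x) { # (C,K) -> (K,1)
  x <- as_tsr(x)
  d <- dim(x$v)
  out <- tsr(matrix(colSums(x$v), d[2], 1))
  record(out, list(x), function(dy)
    list(matrix(rep(as.numeric(dy), each = d[1]), d[1], d[2])))
}

# y = x + rowvec (K,1) + colvec (1,P)
op_add_rc <- function(x, rv, cv) {
  x <- as_tsr(x); rv <- as_tsr(rv); cv <- as_tsr(cv)
  d <- dim(x$v)
  out <- tsr(sweep(sweep(x$v, 1, as.numeric(rv$v), "+"), 2, as.numeric(cv$v), "+"))
  record(out, list(x, rv, cv), function(dy)
    list(dy, matrix(rowSums(dy), d[1], 1), matrix(colSums(dy), 1, d[2])))
}

# y[k,p] = sgn * alpha[k] * x[k,p]
op_scale_rows <- function(x, alpha, sgn = 1) {
  x <- as_tsr(x)
  xv <- x$v
  av <- as.numeric(alpha$v)
  out <- tsr(sgn * xv * av)
  record(out, list(x, alpha), function(dy)
    list(sgn * dy * av, sgn * rowSums(dy * xv)))
}

#' Reference (loop) form of the learnable-codebook gating
#'
#' Computes the per-pixel soft assignment and weighted squared-residual
#' response with explicit loops over pixels and codewords — the functional
#' contract of the LVC branch given explicit codebook values. Used as the
#' specification of `nn_lvc`; tests compare the module against an
#' independently written oracle.
#'
#' @param F_in `C x H x W` array.
#' @param mu `C x K` codeword matrix, `alpha` length-K scales.
#' @param conv_w `C x C` matrix and `conv_b` length-C bias of the 1x1
#'   integration convolution.
#' @param negate_distance see [nn_lvc()].
#' @return `C x H x W` array `F_in + F_in * sigmoid(conv(r))`.
#' @export
lvc_encode <- function(F_in, mu, alpha, conv_w, conv_b = numeric(nrow(mu)),
                       negate_distance = FALSE) {
  d <- dim(F_in)
  X <- matrix(F_in, nrow = d[1])
  K <- ncol(mu)
  sgn <- if (negate_distance) -1 else 1
  d2 <- sapply(seq_len(ncol(X)), function(p) {
    colSums((X[, p] - mu)^2)
  })
  d2 <- matrix(d2, nrow = K)
  logits <- sgn * d2 * alpha
  w <- exp(sweep(logits, 2, apply(logits, 2, max), "-"))
  w <- sweep(w, 2, colSums(w), "/")
  r <- X^2 - 2 * X * (mu %*% w) + (mu^2 %*% w)
  g <- 1 / (1 + exp(-(conv_w %*% r + conv_b)))
  array(X + X * g, dim = d)
}

#' Build the semantic enhancement module
#'
#' @param cx,cy channel widths of the two deepest encoder outputs.
#' @param fused fused width after the 7x7 Conv-BN-ReLU block.
#' @param cout output width (a 1x1 projection maps the concatenated
#'   branches, `2 * fused` channels, to the decoder's deepest width).
#' @param codewords codebook size K.
#' @param mlp_ratio expansion of the global MLP branch.
#' @param negate_distance see [nn_lvc()].
#' @param use_mlp,use_lvc ablation hooks; disabling a branch drops it from
#'   the concatenation.
#' @return module with `$fwd(X, Y)`; also exposes `$cbr`, `$mlp`, `$lvc`.
#' @export
sem_module <- function(cx, cy, fused = 256L, cout = 256L, codewords = 64L,
                       mlp_ratio = 2, negate_distance = FALSE,
                       use_mlp = TRUE, use_lvc = TRUE) {
  conv <- nn_conv2d(cx + cy, fused, 7L, pad = 3L)
  bn <- nn_batchnorm(fused)
  mlp <- nn_mlp(fused, mlp_ratio)
  lvc <- nn_lvc(fused, codewords, negate_distance)
  nb <- sum(use_mlp, use_lvc)
  if (nb == 0) stop("sem_module: at least one branch must be enabled")
  proj <- nn_pixlin(nb * fused, cout)
  cbr <- list(conv = conv, bn = bn)
  cbr$fwd <- function(X, Y) op_relu(bn$fwd(conv$fwd(op_concat_c(list(X, Y)))))
  mlpb <- list(mlp = mlp)
  mlpb$fwd <- function(f) op_add(f, mlp$fwd(f)) # residual global branch
  m <- list(cbr = cbr, mlp_branch = mlpb, lvc = lvc, proj = proj,
            fused = fused, cout = cout)
  m$fwd <- function(X, Y) {
    f <- cbr$fwd(X, Y)
    parts <- list()
    if (use_mlp) parts <- c(parts, list(mlpb$fwd(f)))
    if (use_lvc) parts <- c(parts, list(lvc$fwd(f)))
    proj$fwd(op_concat_c(parts))
  }
  m
}
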