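#' @useDynLib dentseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif pnorm dnorm quantile sd
#' @importFrom utils write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Minimal reverse-mode automatic differentiation.
#
# A tensor (`tsr`) is an environment holding $v (a numeric array / matrix /
# vector), $grad, and a $requires flag. While a tape is active every operation
# appends a node {out, inputs, bwd}; backward() walks the tape in reverse
# creation order, which is a valid topological order for the DAG, and
# accumulates gradients on every input tensor it meets. Gradients of
# intermediate tensors are dropped as soon as their producing node has been
# processed; parameter gradients persist until the optimiser clears them, so
# successive backward() calls inside one batch accumulate.

.dl <- new.env(parent = emptyenv())
.dl$tape <- NULL
.dl$train <- FALSE

#' Create a tensor
#'
#' Wraps a numeric array in the autodiff tensor type used throughout the
#' network code. Plain arrays passed to network operations are wrapped
#' automatically; explicit construction is only needed for leaf parameters.
#'
#' @param v numeric vector, matrix or array.
#' @param requires_grad should gradients be accumulated into this tensor?
#' @return an object of class `tsr`.
#' @export
tsr <- function(v, requires_grad = FALSE) {
  e <- new.env(parent = emptyenv())
  e$v <- v
  e$grad <- NULL
  e$requires <- requires_grad
  class(e) <- "tsr"
  e
}

#' @export
print.tsr <- function(x, ...) {
  cat("<tsr", paste(dim(x$v) %||% length(x$v), collapse = "x"),
      if (x$requires) "requires_grad" else "", ">\n")
  invisible(x)
}

is_tsr <- function(x) inherits(x, "tsr")
as_tsr <- function(x) if (is_tsr(x)) x else tsr(x)

#' Extract the value of a tensor
#' @param x a `tsr` or plain array (returned unchanged).
#' @return the underlying numeric array.
#' @export
vals <- function(x) if (is_tsr(x)) x$v else x

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Start / stop recording operations for backpropagation
#'
#' `tape_begin()` opens a fresh gradient tape; subsequent network operations
#' record backward closures. `tape_end()` discards the tape. `backward()`
#' seeds the scalar loss gradient with 1 and accumulates gradients into every
#' tensor created with `requires_grad = TRUE` (and intermediates).
#'
#' @return `tape_begin`/`tape_end` return `NULL` invisibly.
#' @export
tape_begin <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 1024L)
  tp$n <- 0L
  .dl$tape <- tp
  invisible(NULL)
}

#' @rdname tape_begin
#' @export
tape_end <- function() {
  .dl$tape <- NULL
  invisible(NULL)
}

tape_active <- function() !is.null(.dl$tape)

#' Switch train / eval behaviour of stochastic and normalisation layers
#' @param on logical.
#' @export
set_train_mode <- function(on) {
  .dl$train <- isTRUE(on)
  invisible(NULL)
}

train_mode <- function() .dl$train

record <- function(out, inputs, bwd) {
  tp <- .dl$tape
  # outside a tape, operations are array-in / array-out
  if (is.null(tp)) return(out$v)
  n <- tp$n + 1L
  if (n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  tp$nodes[[n]] <- list(out = out, inputs = inputs, bwd = bwd)
  tp$n <- n
  out
}

#' @param loss a scalar `tsr` produced while the tape was active.
#' @rdname tape_begin
#' @export
backward <- function(loss) {
  tp <- .dl$tape
  if (is.null(tp)) stop("backward() called without an active tape")
  loss$grad <- array(1, dim = dim(loss$v) %||% 1L)
  for (i in rev(seq_len(tp$n))) {
    nd <- tp$nodes[[i]]
    dy <- nd$out$grad
    if (is.null(dy)) next
    gs <- nd$bwd(dy)
    ins <- nd$inputs
    for (j in seq_along(ins)) {
      g <- gs[[j]]
      if (is.null(g)) next
      tin <- ins[[j]]
      tin$grad <- if (is.null(tin$grad)) g else tin$grad + g
    }
    nd$out$grad <- NULL
  }
  invisible(NULL)
}

# Run `fwd` returning plain arrays when called outside a tape, tensors inside.
unwrap <- function(x) if (tape_active()) x else vals(x)

# ---------------------------------------------------------------------------
# Elementwise and shape primitives. All assume operands of identical shape
# unless stated otherwise; no implicit broadcasting.

op_add <- function(a, b) {
  a <- as_tsr(a); b <- as_tsr(b)
  out <- tsr(a$v + b$v)
  record(out, list(a, b), function(dy) list(dy, dy))
}

op_sub <- function(a, b) {
  a <- as_tsr(a); b <- as_tsr(b)
  out <- tsr(a$v - b$v)
  record(out, list(a, b), function(dy) list(dy, -dy))
}

op_mul <- function(a, b) {
  a <- as_tsr(a); b <- as_tsr(b)
  av <- a$v; bv <- b$v
  out <- tsr(av * bv)
  record(out, list(a, b), function(dy) list(dy * bv, dy * av))
}

op_div <- function(a, b) {
  a <- as_tsr(a); b <- as_tsr(b)
  av <- a$v; bv <- b$v
  out <- tsr(av / bv)
  record(out, list(a, b), function(dy) list(dy / bv, -dy * av / (bv * bv)))
}

op_const_mul <- function(a, k) {
  a <- as_tsr(a)
  out <- tsr(a$v * k)
  record(out, list(a), function(dy) list(dy * k))
}

op_const_add <- function(a, k) {
  a <- as_tsr(a)
  out <- tsr(a$v + k)
  record(out, list(a), function(dy) list(dy))
}

op_sum <- function(a) {
  a <- as_tsr(a)
  d <- dim(a$v) %||% length(a$v)
  out <- tsr(sum(a$v))
  record(out, list(a), function(dy) list(array(as.numeric(dy), dim = d)))
}

op_mean <- function(a) {
  a <- as_tsr(a)
  n <- length(a$v)
  d <- dim(a$v) %||% n
  out <- tsr(mean(a$v))
  record(out, list(a), function(dy) list(array(as.numeric(dy) / n, dim = d)))
}

op_log <- function(a) {
  a <- as_tsr(a)
  av <- a$v
  out <- tsr(log(av))
  record(out, list(a), function(dy) list(dy / av))
}

op_square <- function(a) {
  a <- as_tsr(a)
  av <- a$v
  out <- tsr(av * av)
  record(out, list(a), function(dy) list(2 * dy * av))
}

# Clamp with straight-through gradient inside the kept interval.
op_clamp <- function(a, lo, hi) {
  a <- as_tsr(a)
  av <- a$v
  keep <- (av >= lo) & (av <= hi)
  out <- tsr(pmin(pmax(av, lo), hi))
  record(out, list(a), function(dy) list(dy * keep))
}

# ---------------------------------------------------------------------------
# Activations

op_relu <- function(a) {
  a <- as_tsr(a)
  pos <- a$v > 0
  out <- tsr(a$v * pos)
  record(out, list(a), function(dy) list(dy * pos))
}

op_gelu <- function(a) {
  a <- as_tsr(a)
  av <- a$v
  out <- tsr(av * pnorm(av))
  record(out, list(a), function(dy) list(dy * (pnorm(av) + av * dnorm(av))))
}

op_sigmoid <- function(a) {
  a <- as_tsr(a)
  s <- 1 / (1 + exp(-a$v))
  out <- tsr(s)
  record(out, list(a), function(dy) list(dy * s * (1 - s)))
}

op_silu <- function(a) {
  a <- as_tsr(a)
  av <- a$v
  s <- 1 / (1 + exp(-av))
  out <- tsr(av * s)
  record(out, list(a), function(dy) list(dy * (s + av * s * (1 - s))))
}

op_softplus <- function(a) {
  a <- as_tsr(a)
  av <- a$v
  # numerically stable log(1 + exp(x))
  out <- tsr(ifelse(av > 30, av, log1p(exp(pmin(av, 30)))))
  s <- 1 / (1 + exp(-av))
  record(out, list(a), function(dy) list(dy * s))
}

op_exp <- function(a) {
  a <- as_tsr(a)
  ev <- exp(a$v)
  out <- tsr(ev)
  record(out, list(a), function(dy) list(dy * ev))
}

op_neg_exp <- function(a) { # -exp(a), used for stable state decay A = -exp(A_log)
  a <- as_tsr(a)
  ev <- exp(a$v)
  out <- tsr(-ev)
  record(out, list(a), function(dy) list(-dy * ev))
}

# Softmax over the first dimension of a (K, P) matrix.
op_softmax1 <- function(a) {
  a <- as_tsr(a)
  m <- a$v
  mx <- apply(m, 2, max)
  e <- exp(sweep(m, 2, mx, "-"))
  s <- sweep(e, 2, colSums(e), "/")
  out <- tsr(s)
  record(out, list(a), function(dy) {
    dot <- colSums(dy * s)
    list(s * sweep(dy, 2, dot, "-"))
  })
}

# ---------------------------------------------------------------------------
# Channel/shape ops for (C, H, W) arrays

# y[o,h,w] = sum_c W[o,c] x[c,h,w] + b[o]; the pointwise (1x1) linear map.
op_pixlin <- function(x, W, b = NULL) {
  x <- as_tsr(x)
  d <- dim(x$v)
  Wv <- W$v
  X <- matrix(x$v, nrow = d[1])
  Y <- Wv %*% X
  if (!is.null(b)) Y <- Y + b$v
  out <- tsr(array(Y, dim = c(nrow(Wv), d[2], d[3])))
  record(out, list(x, W, b), function(dy) {
    dY <- matrix(dy, nrow = nrow(Wv))
    list(array(crossprod(Wv, dY), dim = d),
         tcrossprod(dY, X),
         if (is.null(b)) NULL else rowSums(dY))
  })
}

# General matrix product of 2-D tensors: (m,n) x (n,p).
op_matmul <- function(a, b) {
  a <- as_tsr(a); b <- as_tsr(b)
  av <- a$v; bv <- b$v
  out <- tsr(av %*% bv)
  record(out, list(a, b), function(dy) list(tcrossprod(dy, bv), crossprod(av, dy)))
}

op_concat_c <- function(xs) {
  xs <- lapply(xs, as_tsr)
  vs <- lapply(xs, function(t) t$v)
  cs <- vapply(vs, function(v) dim(v)[1], 0L)
  d <- dim(vs[[1]])
  tot <- sum(cs)
  arr <- array(0, dim = c(tot, d[2], d[3]))
  at <- 0L
  for (i in seq_along(vs)) {
    arr[at + seq_len(cs[i]), , ] <- vs[[i]]
    at <- at + cs[i]
  }
  out <- tsr(arr)
  record(out, xs, function(dy) {
    res <- vector("list", length(xs))
    at <- 0L
    for (i in seq_along(xs)) {
      res[[i]] <- dy[at + seq_len(cs[i]), , , drop = FALSE]
      dim(res[[i]]) <- c(cs[i], d[2], d[3])
      at <- at + cs[i]
    }
    res
  })
}

op_slice_c <- function(x, idx) {
  x <- as_tsr(x)
  d <- dim(x$v)
  sv <- x$v[idx, , , drop = FALSE]
  out <- tsr(array(sv, dim = c(length(idx), d[2], d[3])))
  record(out, list(x), function(dy) {
    g <- array(0, dim = d)
    g[idx, , ] <- dy
    list(g)
  })
}

# Per-channel scale and shift: y = x * g[c] (+ b[c]).
op_channel_affine <- function(x, g, b = NULL) {
  x <- as_tsr(x)
  d <- dim(x$v)
  X <- matrix(x$v, nrow = d[1])
  gv <- g$v
  Y <- X * gv
  if (!is.null(b)) Y <- Y + b$v
  out <- tsr(array(Y, dim = d))
  record(out, list(x, g, b), function(dy) {
    dY <- matrix(dy, nrow = d[1])
    list(array(dY * gv, dim = d), rowSums(dY * X),
         if (is.null(b)) NULL else rowSums(dY))
  })
}

# Layer normalisation over the channel dimension at every pixel.
op_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_tsr(x)
  d <- dim(x$v)
  C <- d[1]
  X <- matrix(x$v, nrow = C)
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu, "-")
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, "*")
  Y <- xhat * gamma$v + beta$v
  out <- tsr(array(Y, dim = d))
  record(out, list(x, gamma, beta), function(dy) {
    dY <- matrix(dy, nrow = C)
    dxhat <- dY * gamma$v
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * xhat)
    dx <- sweep(dxhat, 2, m1, "-") - sweep(xhat, 2, m2, "*")
    dx <- sweep(dx, 2, inv, "*")
    list(array(dx, dim = d), rowSums(dY * xhat), rowSums(dY))
  })
}

# Batch normalisation over the spatial field of one sample (per-channel).
# `state` is a mutable environment with running_mean / running_var. When the
# spatial field is a single pixel (variance undefined) the running statistics
# are used even in training, and no update is made.
op_batchnorm <- function(x, gamma, beta, state, eps = 1e-5, momentum = 0.1) {
  x <- as_tsr(x)
  d <- dim(x$v)
  C <- d[1]
  P <- prod(d[-1])
  X <- matrix(x$v, nrow = C)
  use_batch <- train_mode() && P > 1
  if (use_batch) {
    mu <- rowMeans(X)
    xc <- X - mu
    va <- rowMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var + momentum * va * P / max(P - 1, 1)
  } else {
    mu <- state$running_mean
    va <- state$running_var
    xc <- X - mu
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  Y <- xhat * gamma$v + beta$v
  out <- tsr(array(Y, dim = d))
  record(out, list(x, gamma, beta), function(dy) {
    dY <- matrix(dy, nrow = C)
    dxhat <- dY * gamma$v
    if (use_batch) {
      m1 <- rowMeans(dxhat)
      m2 <- rowMeans(dxhat * xhat)
      dx <- (dxhat - m1 - xhat * m2) * inv
    } else {
      dx <- dxhat * inv
    }
    list(array(dx, dim = d), rowSums(dY * xhat), rowSums(dY))
  })
}

op_global_avgpool <- function(x) {
  x <- as_tsr(x)
  d <- dim(x$v)
  P <- d[2] * d[3]
  out <- tsr(array(rowMeans(matrix(x$v, nrow = d[1])), dim = c(d[1], 1, 1)))
  record(out, list(x), function(dy) {
    list(array(rep(as.numeric(dy) / P, P), dim = d))
  })
}

op_broadcast_hw <- function(x, H, W) {
  x <- as_tsr(x)
  C <- dim(x$v)[1]
  out <- tsr(array(rep(as.numeric(x$v), H * W), dim = c(C, H, W)))
  record(out, list(x), function(dy) {
    list(array(rowSums(matrix(dy, nrow = C)), dim = c(C, 1, 1)))
  })
}

# Stochastic depth on a residual branch: during training the whole branch is
# dropped with probability p (and scaled by 1/(1-p) when kept); identity in
# evaluation mode.
op_droppath <- function(x, p) {
  x <- as_tsr(x)
  if (!train_mode() || p <= 0) return(record(tsr(x$v), list(x), function(dy) list(dy)))
  if (runif(1) < p) {
    d <- dim(x$v)
    out <- tsr(array(0, dim = d))
    record(out, list(x), function(dy) list(array(0, dim = d)))
  } else {
    k <- 1 / (1 - p)
    out <- tsr(x$v * k)
    record(out, list(x), function(dy) list(dy * k))
  }
}

# Reorder pixels of a (C,H,W) map into a (C, H*W) sequence given a pixel
# permutation (indices into the column-major pixel order), and back.
op_flatten_seq <- function(x, ord) {
  x <- as_tsr(x)
  d <- dim(x$v)
  X <- matrix(x$v, nrow = d[1])
  out <- tsr(X[, ord, drop = FALSE])
  record(out, list(x), function(dy) {
    g <- matrix(0, d[1], d[2] * d[3])
    g[, ord] <- dy
    list(array(g, dim = d))
  })
}

op_unflatten_seq <- function(x, ord, H, W) {
  x <- as_tsr(x)
  C <- dim(x$v)[1]
  g <- matrix(0, C, H * W)
  g[, ord] <- x$v
  out <- tsr(array(g, dim = c(C, H, W)))
  record(out, list(x), function(dy) {
    dg <- matrix(dy, nrow = C)
    list(dg[, ord, drop = FALSE])
  })
}

# ---------------------------------------------------------------------------
# Compiled-kernel ops

op_conv2d <- function(x, W, b, stride = 1L, pad = 0L) {
  x <- as_tsr(x)
  xv <- x$v; Wv <- W$v
  out <- tsr(cpp_conv2d_fwd(xv, Wv, b$v, as.integer(stride), as.integer(pad)))
  record(out, list(x, W, b), function(dy) {
    g <- cpp_conv2d_bwd(xv, Wv, dy, as.integer(stride), as.integer(pad))
    list(g$dx, g$dw, g$db)
  })
}

op_convt2d <- function(x, W, b) {
  x <- as_tsr(x)
  xv <- x$v; Wv <- W$v
  out <- tsr(cpp_convt2d_fwd(xv, Wv, b$v))
  record(out, list(x, W, b), function(dy) {
    g <- cpp_convt2d_bwd(xv, Wv, dy)
    list(g$dx, g$dw, g$db)
  })
}

# DCNv3 sampling core; offsets (2GK,H,W), modulation m (GK,H,W) softmaxed.
op_dcn_core <- function(x, off, m, pk, G) {
  x <- as_tsr(x); off <- as_tsr(off); m <- as_tsr(m)
  xv <- x$v; offv <- off$v; mv <- m$v
  out <- tsr(cpp_dcn_fwd(xv, offv, mv, pk, as.integer(G)))
  record(out, list(x, off, m), function(dy) {
    g <- cpp_dcn_bwd(xv, offv, mv, pk, as.integer(G), dy)
    list(g$dx, g$doff, g$dm)
  })
}

# Selective-scan core on explicit per-step parameters.
op_scan_core <- function(x, delta, A, B, Cc) {
  x <- as_tsr(x); delta <- as_tsr(delta); A <- as_tsr(A)
  B <- as_tsr(B); Cc <- as_tsr(Cc)
  xv <- x$v; dv <- delta$v; Av <- A$v; Bv <- B$v; Cv <- Cc$v
  keep <- tape_active()
  f <- cpp_scan_fwd(xv, dv, Av, Bv, Cv, keep)
  out <- tsr(f$y)
  h <- f$h
  record(out, list(x, delta, A, B, Cc), function(dy) {
    g <- cpp_scan_bwd(xv, dv, Av, Bv, Cv, h, dy)
    list(g$dx, g$ddelta, g$dA, g$dB, g$dC)
  })
}
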