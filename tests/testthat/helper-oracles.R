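# Independently written brute-force oracles. These deliberately use naive
# loops and must stay structurally independent of the package implementation
# they check.

oracle_bilinear <- function(feature, r, cl) {
  C <- dim(feature)[1]; H <- dim(feature)[2]; W <- dim(feature)[3]
  r0 <- floor(r); c0 <- floor(cl)
  ar <- r - r0; ac <- cl - c0
  acc <- numeric(C)
  for (dr in 0:1) for (dc in 0:1) {
    wgt <- (if (dr) ar else 1 - ar) * (if (dc) ac else 1 - ac)
    rr <- r0 + dr; cc <- c0 + dc
    if (rr >= 0 && rr < H && cc >= 0 && cc < W)
      acc <- acc + wgt * feature[, rr + 1, cc + 1]
  }
  acc
}

# triple-loop DCNv3: per pixel, per group, per point
oracle_dcn <- function(x, proj, off, logits, pk, G) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  K <- ncol(pk); Cg <- C / G
  y <- array(0, dim = d)
  for (h in seq_len(H)) for (w in seq_len(W)) {
    for (g in seq_len(G)) {
      lg <- sapply(seq_len(K), function(k) logits[(g - 1) * K + k, h, w])
      m <- exp(lg - max(lg)); m <- m / sum(m)
      acc <- numeric(Cg)
      for (k in seq_len(K)) {
        oi <- 2 * ((k - 1) + K * (g - 1))
        r <- (h - 1) + pk[1, k] + off[oi + 1, h, w]
        cl <- (w - 1) + pk[2, k] + off[oi + 2, h, w]
        sv <- oracle_bilinear(x, r, cl)[(g - 1) * Cg + seq_len(Cg)]
        acc <- acc + m[k] * sv
      }
      y[(g - 1) * Cg + seq_len(Cg), h, w] <-
        if (is.null(proj)) acc else as.numeric(proj[[g]] %*% acc)
    }
  }
  y
}

# step-by-step selective-scan recurrence
oracle_scan <- function(x, delta, A, B, Cc) {
  C <- nrow(x); Tn <- ncol(x); N <- ncol(A)
  y <- matrix(0, C, Tn)
  h <- matrix(0, C, N)
  for (t in seq_len(Tn)) {
    for (c in seq_len(C)) {
      for (n in seq_len(N)) {
        a <- exp(delta[c, t] * A[c, n])
        h[c, n] <- a * h[c, n] + delta[c, t] * x[c, t] * B[n, t]
      }
      y[c, t] <- sum(h[c, ] * Cc[, t])
    }
  }
  y
}

# double-loop codebook gating: per pixel, per codeword
oracle_lvc <- function(F_in, mu, alpha, conv_w, conv_b, negate = FALSE) {
  d <- dim(F_in); C <- d[1]
  K <- ncol(mu)
  out <- array(0, dim = d)
  for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
    xi <- F_in[, h, w]
    lg <- numeric(K)
    for (k in seq_len(K)) {
      d2 <- sum((xi - mu[, k])^2)
      lg[k] <- (if (negate) -1 else 1) * alpha[k] * d2
    }
    wts <- exp(lg - max(lg)); wts <- wts / sum(wts)
    r <- numeric(C)
    for (k in seq_len(K)) r <- r + wts[k] * (xi - mu[, k])^2
    g <- 1 / (1 + exp(-(conv_w %*% r + conv_b)))
    out[, h, w] <- xi + xi * g
  }
  out
}

# boundary pixels by explicit 8-neighbourhood inspection (outside = background)
oracle_boundary <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  res <- NULL
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1) next
    edge <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > H || jj < 1 || jj > W || mask[ii, jj] == 0) edge <- TRUE
    }
    if (edge) res <- rbind(res, c(i, j))
  }
  res
}

# all-pairs percentile Hausdorff on boundary point sets
oracle_hd <- function(pred, truth, percentile = 95) {
  if (sum(pred) == 0 || sum(truth) == 0) return(NA_real_)
  bp <- oracle_boundary(pred); bt <- oracle_boundary(truth)
  dmat <- sqrt(outer(bp[, 1], bt[, 1], "-")^2 + outer(bp[, 2], bt[, 2], "-")^2)
  pooled <- c(apply(dmat, 1, min), apply(dmat, 2, min))
  as.numeric(quantile(pooled, percentile / 100, type = 7, names = FALSE))
}

# 8-connected component count via BFS
oracle_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (mask[i, j] != 1 || seen[i, j]) next
    ncomp <- ncomp + 1L
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        ii <- p[1] + di; jj <- p[2] + dj
        if (ii >= 1 && ii <= H && jj >= 1 && jj <= W &&
            mask[ii, jj] == 1 && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue[[length(queue) + 1L]] <- c(ii, jj)
        }
      }
    }
  }
  ncomp
}

# depthwise 3x3 box average with zero padding (independent zero-offset check)
oracle_box_mean <- function(x) {
  d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]
  y <- array(0, dim = d)
  for (c in seq_len(C)) {
    pad <- matrix(0, H + 2, W + 2)
    pad[2:(H + 1), 2:(W + 1)] <- x[c, , ]
    acc <- matrix(0, H, W)
    for (di in 0:2) for (dj in 0:2)
      acc <- acc + pad[(1 + di):(H + di), (1 + dj):(W + dj)]
    y[c, , ] <- acc / 9
  }
  y
}

rand_feature <- function(C, H, W, sd = 1) array(rnorm(C * H * W, sd = sd), c(C, H, W))

rand_mask <- function(H, W, p = 0.3) {
  matrix(as.integer(runif(H * W) < p), H, W)
}

# a blobby random mask (connected-ish regions rather than salt-and-pepper)
rand_blob_mask <- function(H, W, n_blobs = 3) {
  m <- matrix(0L, H, W)
  for (b in seq_len(n_blobs)) {
    ci <- runif(1, 1, H); cj <- runif(1, 1, W)
    r <- runif(1, 1.5, max(2, min(H, W) / 4))
    for (i in seq_len(H)) for (j in seq_len(W))
      if ((i - ci)^2 + (j - cj)^2 < r^2) m[i, j] <- 1L
  }
  m
}
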