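# Layer constructors. A "module" is a plain list carrying tsr parameters
# (leaves created with requires_grad = TRUE) and an $fwd closure; parameters
# are discovered by recursive traversal, so composite modules just nest their
# sub-modules in the list.

he_init <- function(fan_in, n, gain = 2) {
  rnorm(n, sd = sqrt(gain / max(fan_in, 1)))
}

param <- function(v) tsr(v, requires_grad = TRUE)

#' Collect the learnable parameters of a module
#'
#' Recursively walks a module (nested lists) and returns every tensor created
#' with `requires_grad = TRUE`.
#'
#' @param mod a module (nested list of sub-modules and `tsr` leaves).
#' @return flat list of `tsr` parameters.
#' @export
parameters <- function(mod) {
  out <- list()
  walk <- function(x) {
    if (is_tsr(x)) {
      if (x$requires) out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !is.function(x)) {
      for (el in x) if (!is.function(el)) walk(el)
    }
  }
  walk(mod)
  out
}

#' Count scalar parameters of a module
#' @inheritParams parameters
#' @return integer count of scalars across all parameter tensors.
#' @export
n_parameters <- function(mod) {
  sum(vapply(parameters(mod), function(p) length(p$v), 0))
}

nn_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                      init_gain = 2) {
  w <- param(array(he_init(cin * k * k, cout * cin * k * k, init_gain),
                   dim = c(cout, cin, k, k)))
  b <- param(numeric(cout))
  m <- list(w = w, b = b, k = k, stride = stride, pad = pad,
            cin = cin, cout = cout)
  m$fwd <- function(x) op_conv2d(x, w, b, stride, pad)
  m
}

nn_convt2d <- function(cin, cout) {
  w <- param(array(he_init(cin * 4, cin * cout * 4), dim = c(cin, cout, 2, 2)))
  b <- param(numeric(cout))
  m <- list(w = w, b = b, cin = cin, cout = cout)
  m$fwd <- function(x) op_convt2d(x, w, b)
  m
}

nn_pixlin <- function(cin, cout, bias = TRUE, init_gain = 2) {
  w <- param(matrix(he_init(cin, cout * cin, init_gain), cout, cin))
  b <- if (bias) param(numeric(cout)) else NULL
  m <- list(w = w, b = b, cin = cin, cout = cout)
  m$fwd <- function(x) op_pixlin(x, w, b)
  m
}

nn_layernorm <- function(C, eps = 1e-5) {
  g <- param(rep(1, C)); b <- param(numeric(C))
  m <- list(gamma = g, beta = b)
  m$fwd <- function(x) op_layernorm(x, g, b, eps)
  m
}

nn_batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  g <- param(rep(1, C)); b <- param(numeric(C))
  st <- new.env(parent = emptyenv())
  st$running_mean <- numeric(C)
  st$running_var <- rep(1, C)
  m <- list(gamma = g, beta = b, state = st)
  m$fwd <- function(x) op_batchnorm(x, g, b, st, eps, momentum)
  m
}

# Per-pixel MLP over channels: expand -> GELU -> project.
nn_mlp <- function(C, ratio = 4, cout = C) {
  hidden <- max(1L, as.integer(round(C * ratio)))
  fc1 <- nn_pixlin(C, hidden)
  fc2 <- nn_pixlin(hidden, cout)
  m <- list(fc1 = fc1, fc2 = fc2)
  m$fwd <- function(x) fc2$fwd(op_gelu(fc1$fwd(x)))
  m
}

# ---------------------------------------------------------------------------
# Adam optimiser on a flat parameter list.

#' Adam optimiser
#'
#' @param params list of parameter tensors (see [parameters()]).
#' @param lr learning rate.
#' @param betas,eps Adam moment decay rates and stabiliser.
#' @return optimiser object with `$step()`, `$zero_grad()`, and mutable `$lr`.
#' @export
optim_adam <- function(params, lr = 1e-5, betas = c(0.9, 0.999), eps = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p$v * 0) # keeps vector/array shape
  st$v <- lapply(params, function(p) p$v * 0)
  st$t <- 0L
  st$lr <- lr
  st$params <- params
  st$step <- function(grad_scale = 1) {
    st$t <- st$t + 1L
    b1 <- betas[1]; b2 <- betas[2]
    bc1 <- 1 - b1^st$t; bc2 <- 1 - b2^st$t
    for (i in seq_along(st$params)) {
      p <- st$params[[i]]
      g <- p$grad
      if (is.null(g)) next
      g <- g * grad_scale
      st$m[[i]] <- b1 * st$m[[i]] + (1 - b1) * g
      st$v[[i]] <- b2 * st$v[[i]] + (1 - b2) * g * g
      mhat <- st$m[[i]] / bc1
      vhat <- st$v[[i]] / bc2
      p$v <- p$v - st$lr * mhat / (sqrt(vhat) + eps)
    }
    invisible(NULL)
  }
  st$zero_grad <- function() {
    for (p in st$params) p$grad <- NULL
    invisible(NULL)
  }
  class(st) <- "dentseg_adam"
  st
}

# Reduce-on-plateau learning-rate scheduler (minimised quantity).
lr_plateau <- function(optimizer, patience = 5L, factor = 0.1, min_lr = 1e-8) {
  st <- new.env(parent = emptyenv())
  st$best <- Inf
  st$bad <- 0L
  st$events <- 0L
  st$step <- function(metric) {
    if (metric < st$best - 1e-12) {
      st$best <- metric
      st$bad <- 0L
    } else {
      st$bad <- st$bad + 1L
      if (st$bad > patience) {
        optimizer$lr <- max(optimizer$lr * factor, min_lr)
        st$bad <- 0L
        st$events <- st$events + 1L
      }
    }
    optimizer$lr
  }
  st
}

# Snapshot / restore parameter values (used for best-on-validation checkpoints).
param_values <- function(params) lapply(params, function(p) p$v)
set_param_values <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$v <- values[[i]]
  invisible(NULL)
}
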