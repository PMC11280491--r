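# Training loop: Adam on the composite Dice + cross-entropy loss, plateau
# learning-rate scheduling on the validation loss, best-on-validation
# checkpointing, CSV history. Samples are processed one at a time with
# gradient accumulation over the batch (normalisation layers therefore see
# per-sample statistics; see the methods vignette).

sample_input <- function(sample) aperm(sample$image, c(3, 1, 2))

model_loss <- function(model, sample, config, train = TRUE) {
  set_train_mode(train)
  logits <- model$fwd(sample_input(sample))
  prob <- if (is_tsr(logits)) op_sigmoid(logits) else 1 / (1 + exp(-logits))
  mask <- array(sample$mask, dim = c(1, dim(sample$mask)))
  composite_loss(prob, mask, config$loss$w_dice %||% 1, config$loss$w_ce %||% 1)
}

#' Train a segmentation model
#'
#' @param model model from [build_model()].
#' @param train_set,val_set lists of `image_sample` objects.
#' @param epochs,batch_size,lr training schedule; defaults come from
#'   `model$config$train`.
#' @param max_steps optional cap on the number of optimiser steps (the
#'   epoch loop stops early once reached).
#' @param patience,factor plateau scheduler: after `patience + 1`
#'   consecutive epochs without validation-loss improvement the learning
#'   rate is multiplied by `factor`.
#' @param seed RNG seed covering shuffling, DropPath and any augmentation.
#' @param augment_with optional [augment_spec()] template; when given, each
#'   training sample is augmented with a spec seeded per (epoch, sample).
#' @param history_csv optional path for the per-epoch history.
#' @param verbose print per-epoch progress to stderr.
#' @return list with `$history` (data.frame), `$best` (epoch and loss),
#'   `$steps`; the model parameters are left at the best-on-validation
#'   checkpoint.
#' @export
train_model <- function(model, train_set, val_set,
                        epochs = NULL, batch_size = NULL, lr = NULL,
                        max_steps = Inf, patience = NULL, factor = NULL,
                        seed = 1L, augment_with = NULL, history_csv = NULL,
                        verbose = FALSE) {
  stopifnot(length(train_set) > 0, length(val_set) > 0)
  tc <- model$config$train %||% list()
  epochs <- epochs %||% tc$epochs %||% 50L
  batch_size <- batch_size %||% tc$batch_size %||% 2L
  lr <- lr %||% tc$lr %||% 1e-5
  patience <- patience %||% tc$plateau_patience %||% 5L
  factor <- factor %||% tc$plateau_factor %||% 0.1
  params <- parameters(model)
  opt <- optim_adam(params, lr = lr)
  sched <- lr_plateau(opt, patience = patience, factor = factor)
  best <- list(loss = Inf, epoch = 0L, values = NULL)
  hist <- list()
  steps <- 0L
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      if (steps >= max_steps) break
      ord <- sample(seq_along(train_set))
      ep_losses <- c()
      for (b0 in seq(1, length(ord), by = batch_size)) {
        if (steps >= max_steps) break
        idx <- ord[b0:min(b0 + batch_size - 1, length(ord))]
        opt$zero_grad()
        bl <- 0
        for (i in idx) {
          s <- train_set[[i]]
          if (!is.null(augment_with)) {
            sp <- augment_with
            sp$seed <- as.integer((seed + 131L * ep + 7919L * i) %% .Machine$integer.max)
            s <- augment(s, sp)
          }
          tape_begin()
          loss <- model_loss(model, s, model$config, train = TRUE)
          lv <- vals(loss)
          if (!is.finite(lv))
            stop("NaN/Inf training loss at epoch ", ep, ", sample '", s$id, "'")
          backward(loss)
          tape_end()
          bl <- bl + lv
        }
        opt$step(grad_scale = 1 / length(idx))
        steps <- steps + 1L
        ep_losses <- c(ep_losses, bl / length(idx))
      }
      # validation (eval mode, no tape)
      val_losses <- vapply(val_set, function(s)
        vals(model_loss(model, s, model$config, train = FALSE)), 0)
      val_dice <- mean(vapply(val_set, function(s)
        dsc(predict_mask(model, s), s$mask), 0))
      vl <- mean(val_losses)
      if (vl < best$loss) {
        best <- list(loss = vl, epoch = ep, values = param_values(params))
      }
      lr_now <- sched$step(vl)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = mean(ep_losses),
                               val_loss = vl, val_dice = val_dice,
                               lr = lr_now, steps = steps)
      if (verbose)
        message(sprintf("epoch %d  train %.4f  val %.4f  dice %.1f  lr %.2g",
                        ep, mean(ep_losses), vl, val_dice, lr_now))
    }
  })
  history <- do.call(rbind, hist)
  if (!is.null(history_csv)) write.csv(history, history_csv, row.names = FALSE)
  if (!is.null(best$values)) set_param_values(params, best$values)
  list(history = history, best = best[c("loss", "epoch")], steps = steps)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the configuration echo and all
#' parameter values plus batch-norm running statistics; loading rebuilds the
#' model from the stored config and restores the values.
#'
#' @param model model object; `path` file path.
#' @return `save_checkpoint` returns `path`; `load_checkpoint` a model.
#' @export
save_checkpoint <- function(model, path) {
  params <- parameters(model)
  bn <- collect_bn_states(model)
  saveRDS(list(config = model$config,
               values = param_values(params),
               bn = lapply(bn, function(e) list(m = e$running_mean,
                                                v = e$running_var))),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_model(ck$config)
  set_param_values(parameters(model), ck$values)
  bn <- collect_bn_states(model)
  stopifnot(length(bn) == length(ck$bn))
  for (i in seq_along(bn)) {
    bn[[i]]$running_mean <- ck$bn[[i]]$m
    bn[[i]]$running_var <- ck$bn[[i]]$v
  }
  model
}

collect_bn_states <- function(mod) {
  out <- list()
  walk <- function(x) {
    if (is.environment(x) && !is_tsr(x)) {
      if (!is.null(x$running_mean)) out[[length(out) + 1L]] <<- x
    } else if (is.list(x) && !is.function(x)) {
      for (el in x) if (!is.function(el)) walk(el)
    }
  }
  walk(mod)
  out
}

#' Overfit probe: desk-scale end-to-end learnability check
#'
#' Trains a small-preset model on a handful of synthetic phantoms at
#' 64 x 128 with Adam at `lr = 1e-3` for at most `max_steps` optimiser
#' steps and reports the final training-set Dice. This deliberately uses a
#' larger learning rate than the full-scale default (1e-5), which is far
#' too slow for a minutes-scale check.
#'
#' @param seed RNG seed for phantoms, initialisation and training.
#' @param n_images number of phantoms (default 8).
#' @param canvas phantom canvas (default `c(64, 128)`).
#' @param max_steps optimiser-step budget (default 500).
#' @param lr learning rate (default 1e-3).
#' @param target_dice early-stop threshold on mean training Dice.
#' @param check_every evaluate training Dice every this many steps.
#' @param verbose print progress.
#' @return list with `$dice` (final mean training Dice, percent),
#'   `$steps`, `$history` of probe evaluations.
#' @export
overfit_probe <- function(seed = 1L, n_images = 8L, canvas = c(64L, 128L),
                          max_steps = 500L, lr = 1e-3, target_dice = 92,
                          check_every = 25L, verbose = FALSE) {
  samples <- lapply(seq_len(n_images), function(i)
    generate_phantom(phantom_config(canvas = canvas, n_teeth = 6L,
                                    seed = seed * 1000L + i)))
  cfg <- default_config("small")
  cfg$seed <- seed
  model <- build_model(cfg)
  params <- parameters(model)
  opt <- optim_adam(params, lr = lr)
  train_dice <- function() mean(vapply(samples, function(s)
    dsc(predict_mask(model, s), s$mask), 0))
  hist <- list()
  steps <- 0L
  with_seed(seed + 1L, {
    while (steps < max_steps) {
      opt$zero_grad()
      for (s in samples) {
        tape_begin()
        loss <- model_loss(model, s, model$config, train = TRUE)
        if (!is.finite(vals(loss))) stop("NaN loss in overfit probe")
        backward(loss)
        tape_end()
      }
      opt$step(grad_scale = 1 / length(samples))
      steps <- steps + 1L
      if (steps %% check_every == 0 || steps == max_steps) {
        dice_now <- train_dice()
        hist[[length(hist) + 1L]] <- data.frame(step = steps, dice = dice_now)
        if (verbose) message(sprintf("probe step %d  dice %.1f", steps, dice_now))
        if (dice_now >= target_dice) break
      }
    }
  })
  list(dice = train_dice(), steps = steps, history = do.call(rbind, hist))
}
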