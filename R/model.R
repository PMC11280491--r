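# Model assembly: two encoder pathways, semantic enhancement on the deepest
# level, hierarchical decoder, plus the structural ablations used in the
# component studies (single-pathway variants feed the surviving pyramid to
# both fusion inputs; the no-enhancement variant replaces the SEM with a 1x1
# fusion projection).

#' Default model / training configuration
#'
#' @param preset `"default"` for the full-size model or `"small"` for a
#'   desk-scale configuration used by fast tests and the overfit probe.
#' @return nested configuration list; any entry may be overridden before
#'   passing to [build_model()].
#' @export
default_config <- function(preset = c("default", "small")) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = 1L,
    stages = list(depths = c(2L, 2L, 2L, 2L),
                  channels = c(64L, 128L, 256L, 512L)),
    dcn = list(groups = 4L, points = 9L),
    droppath_rate = 0.1,
    mlp_ratio = 4,
    ssm = list(state_dim = 16L, stem_channels = 48L, mlp_ratio = 4),
    sem = list(enabled = TRUE, fused_channels = 256L, mlp_ratio = 2),
    lvc = list(codewords = 64L, negate_distance = FALSE),
    decoder = list(channels = c(256L, 128L, 64L, 32L), head_channels = 16L,
                   attention_ratio = 4L, disable_tafi = integer(0)),
    ablate = character(0),
    loss = list(w_dice = 1, w_ce = 1),
    train = list(lr = 1e-5, epochs = 50L, batch_size = 2L,
                 plateau_patience = 5L, plateau_factor = 0.1)
  )
  if (preset == "small") {
    cfg$stages <- list(depths = c(1L, 1L, 1L, 1L),
                       channels = c(8L, 16L, 24L, 32L))
    cfg$dcn <- list(groups = 2L, points = 9L)
    cfg$droppath_rate <- 0
    cfg$mlp_ratio <- 2
    cfg$ssm <- list(state_dim = 4L, stem_channels = 8L, mlp_ratio = 2)
    cfg$sem <- list(enabled = TRUE, fused_channels = 24L, mlp_ratio = 2)
    cfg$lvc <- list(codewords = 8L, negate_distance = FALSE)
    cfg$decoder <- list(channels = c(24L, 16L, 12L, 8L), head_channels = 8L,
                        attention_ratio = 2L, disable_tafi = integer(0))
  }
  cfg
}

#' Build the segmentation network
#'
#' Wires the deformable pathway, the state-space pathway, the semantic
#' enhancement module and the hierarchical decoder according to `config`.
#' `config$ablate` may contain any of `"ssp"` (drop the state-space
#' pathway), `"adp"` (drop the deformable pathway), `"tafi"` (replace all
#' gated fusions by concatenation) and `"sem"` (replace the enhancement
#' module by a 1x1 fusion projection); single-pathway variants feed the
#' surviving pyramid to both fusion inputs.
#'
#' @param config configuration list from [default_config()].
#' @return model object with `$fwd(x)` (`x` a `3 x H x W` array, `H`, `W`
#'   divisible by 32, returning `1 x H x W` logits), `$config`, and the
#'   sub-modules.
#' @export
build_model <- function(config = default_config()) {
  ablate <- config$ablate %||% character(0)
  bad <- setdiff(ablate, c("ssp", "adp", "tafi", "sem"))
  if (length(bad)) stop("unknown ablation flag(s): ", paste(bad, collapse = ", "))
  if (all(c("ssp", "adp") %in% ablate))
    stop("cannot ablate both encoder pathways")
  ec <- config$stages$channels
  dc <- config$decoder$channels
  with_seed(config$seed %||% 1L, {
    adp <- if (!"adp" %in% ablate)
      deformable_pathway(ec, config$stages$depths, config$dcn$groups,
                         config$dcn$points, config$droppath_rate,
                         config$mlp_ratio)
    ssp <- if (!"ssp" %in% ablate)
      ssm_pathway(ec, config$ssm$stem_channels, config$ssm$state_dim,
                  config$ssm$mlp_ratio)
    sem_enabled <- !("sem" %in% ablate) && isTRUE(config$sem$enabled)
    sem <- if (sem_enabled)
      sem_module(ec[4], ec[4], config$sem$fused_channels, dc[1],
                 config$lvc$codewords, config$sem$mlp_ratio,
                 config$lvc$negate_distance)
    sem_fallback <- if (!sem_enabled) nn_pixlin(2L * ec[4], dc[1])
    disable <- if ("tafi" %in% ablate) 1:3 else
      as.integer(config$decoder$disable_tafi %||% integer(0))
    dec <- hcd_decoder(ec, dc, config$decoder$head_channels,
                       config$decoder$attention_ratio, disable)
    m <- list(adp = adp, ssp = ssp, sem = sem, sem_fallback = sem_fallback,
              dec = dec, config = config)
    m$fwd <- function(x) {
      x <- as_tsr(x)
      d <- dim(x$v)
      if (d[1] != 3) stop("model input must be 3 x H x W")
      if (d[2] %% 32 != 0 || d[3] %% 32 != 0)
        stop("input spatial dims must be divisible by 32 (use predict_mask ",
             "for automatic padding)")
      pyr_x <- if (!is.null(adp)) adp$fwd(x) else NULL
      pyr_y <- if (!is.null(ssp)) ssp$fwd(x) else NULL
      if (is.null(pyr_x)) pyr_x <- pyr_y
      if (is.null(pyr_y)) pyr_y <- pyr_x
      deep <- if (!is.null(sem)) sem$fwd(pyr_x[[4]], pyr_y[[4]])
              else sem_fallback$fwd(op_concat_c(list(pyr_x[[4]], pyr_y[[4]])))
      out <- dec$fwd(pyr_x, pyr_y, deep)
      unwrap(out)
    }
    m
  })
}

#' Reflect-pad an image to spatial multiples of 32
#'
#' @param img `H x W x C` array (or `H x W` matrix).
#' @return list with `$img` (padded) and `$record` (original and padded
#'   dims plus crop indices); cropping with `$record` restores the original
#'   dims exactly.
#' @export
pad_to_multiple <- function(img, multiple = 32L) {
  d <- dim(img)
  H <- d[1]; W <- d[2]
  Hp <- as.integer(ceiling(H / multiple) * multiple)
  Wp <- as.integer(ceiling(W / multiple) * multiple)
  rec <- list(orig = c(H, W), padded = c(Hp, Wp),
              rows = seq_len(H), cols = seq_len(W))
  if (Hp == H && Wp == W) return(list(img = img, record = rec))
  reflect_idx <- function(n, np) {
    idx <- seq_len(np)
    # reflect without repeating the edge sample where possible
    over <- idx > n
    idx[over] <- pmax(n - (idx[over] - n), 1L)
    idx
  }
  ri <- reflect_idx(H, Hp); ci <- reflect_idx(W, Wp)
  out <- if (length(d) == 3) img[ri, ci, , drop = FALSE] else img[ri, ci]
  list(img = out, record = rec)
}

#' Predict a binary mask for an arbitrarily sized image
#'
#' Pads the input by reflection to multiples of 32, runs the network in
#' evaluation mode, applies the sigmoid, thresholds, and crops back to the
#' original size.
#'
#' @param model a model from [build_model()].
#' @param image `H x W x 3` array in `[0,1]` (or an `image_sample`).
#' @param threshold probability threshold (default 0.5).
#' @param return_prob also return the probability map.
#' @return `H x W` binary matrix (or `list(mask, prob)`).
#' @export
predict_mask <- function(model, image, threshold = 0.5, return_prob = FALSE) {
  if (inherits(image, "image_sample")) image <- image$image
  set_train_mode(FALSE)
  pr <- pad_to_multiple(image)
  x <- aperm(pr$img, c(3, 1, 2))
  logits <- model$fwd(x)
  prob <- 1 / (1 + exp(-logits[1, , ]))
  prob <- prob[pr$record$rows, pr$record$cols, drop = FALSE]
  mask <- (prob > threshold) * 1L
  if (return_prob) list(mask = mask, prob = prob) else mask
}
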