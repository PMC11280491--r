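# Composite training loss: soft Dice + binary cross-entropy. Both accept
# plain arrays (evaluation) or tsr tensors (training, differentiable).

#' Soft Dice loss
#'
#' `1 - (2 * sum(p*y) + eps) / (sum(p) + sum(y) + eps)` for a probability
#' map `p` and binary mask `y`; the epsilon smoothing keeps the loss defined
#' on empty masks.
#'
#' @param prob probability map in `[0,1]` (array or `tsr`).
#' @param mask binary array of the same shape.
#' @param eps smoothing constant (default 1).
#' @return scalar (or scalar `tsr` under an active tape).
#' @export
dice_loss <- function(prob, mask, eps = 1) {
  mask <- vals(mask)
  if (is_tsr(prob)) {
    inter <- op_sum(op_mul(prob, tsr(mask)))
    num <- op_const_add(op_const_mul(inter, 2), eps)
    den <- op_const_add(op_sum(prob), sum(mask) + eps)
    op_const_add(op_const_mul(op_div(num, den), -1), 1)
  } else {
    1 - (2 * sum(prob * mask) + eps) / (sum(prob) + sum(mask) + eps)
  }
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y log p + (1-y) log(1-p))` with probabilities clipped to
#' `[eps, 1-eps]`.
#'
#' @inheritParams dice_loss
#' @param eps clipping constant (default 1e-7).
#' @return scalar (or scalar `tsr`).
#' @export
ce_loss <- function(prob, mask, eps = 1e-7) {
  mask <- vals(mask)
  if (is_tsr(prob)) {
    p <- op_clamp(prob, eps, 1 - eps)
    t1 <- op_mul(op_log(p), tsr(mask))
    one_minus <- op_const_add(op_const_mul(p, -1), 1)
    t2 <- op_mul(op_log(one_minus), tsr(1 - mask))
    op_const_mul(op_mean(op_add(t1, t2)), -1)
  } else {
    p <- pmin(pmax(prob, eps), 1 - eps)
    -mean(mask * log(p) + (1 - mask) * log(1 - p))
  }
}

#' Composite segmentation loss
#'
#' `w_dice * dice_loss + w_ce * ce_loss` (defaults 1 and 1).
#'
#' @inheritParams dice_loss
#' @param w_dice,w_ce branch weights.
#' @param dice_eps,ce_eps smoothing/clipping constants of the two parts.
#' @return scalar (or scalar `tsr`).
#' @export
composite_loss <- function(prob, mask, w_dice = 1, w_ce = 1,
                           dice_eps = 1, ce_eps = 1e-7) {
  d <- dice_loss(prob, mask, dice_eps)
  ce <- ce_loss(prob, mask, ce_eps)
  if (is_tsr(d)) op_add(op_const_mul(d, w_dice), op_const_mul(ce, w_ce))
  else w_dice * d + w_ce * ce
}
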