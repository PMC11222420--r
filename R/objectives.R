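# Dice metric, soft Dice, and the deep-supervision training loss
# Loss_DS(x_c, y_c) = BCE(x_c, y_c) + 1 - DICE(x_c, y_c), evaluated per
# class c and decoder level l after upscaling each side output to the input
# resolution. BCE is the per-pixel mean; levels and classes are weighted
# equally in the total.

BCE_CLIP <- 1e-7

#' Dice coefficient between two binary masks
#'
#' `2|S ∩ G| / (|S| + |G|)`: 1 is perfect agreement, 0 is no overlap. Two
#' empty masks score 1 — a slice with no ureter that is correctly predicted
#' empty is a correct result, not an undefined one.
#'
#' @param s,g binary arrays of identical shape (prediction, ground truth).
#' @return scalar in [0, 1].
#' @export
dice_coefficient <- function(s, g) {
  check_same_grid(s, g)
  sv <- as.vector(s) != 0
  gv <- as.vector(g) != 0
  denom <- sum(sv) + sum(gv)
  if (denom == 0) return(1.0)
  2 * sum(sv & gv) / denom
}

#' Smoothed (soft) Dice between a probability map and a binary mask
#'
#' `(2 Σ p·g + eps) / (Σ p + Σ g + eps)`; differentiable in `p` and equal to
#' [dice_coefficient()] in the limit of binary `p` and `eps -> 0`. Two empty
#' inputs score 1 by the smoothing convention.
#'
#' @param p probability array in [0, 1].
#' @param g binary array, same shape.
#' @param eps smoothing constant.
#' @return scalar.
#' @export
soft_dice <- function(p, g, eps = 1e-6) {
  check_same_grid(p, g)
  (2 * sum(p * g) + eps) / (sum(p) + sum(g) + eps)
}

#' Per-pixel mean binary cross-entropy
#' @param p probability array in [0, 1] (clipped internally for the logs).
#' @param g binary array, same shape.
#' @return scalar.
#' @export
bce_loss <- function(p, g) {
  check_same_grid(p, g)
  pc <- pmin(pmax(p, BCE_CLIP), 1 - BCE_CLIP)
  -mean(g * log(pc) + (1 - g) * log(1 - pc))
}

#' Deep-supervision loss for one prediction/target pair
#'
#' `BCE(x, y) + 1 - soft_dice(x, y)`; non-negative, and approaches 0 as the
#' prediction approaches the binary target.
#'
#' @param x probability array in [0, 1].
#' @param y binary target, same shape.
#' @param eps soft-Dice smoothing.
#' @return scalar loss.
#' @export
loss_ds <- function(x, y, eps = 1e-6) {
  if (any(x < 0 | x > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  bce_loss(x, y) + 1 - soft_dice(x, y, eps)
}

#' Analytic gradient of [loss_ds()] with respect to the probabilities
#'
#' @inheritParams loss_ds
#' @return array of the same shape as `x`.
#' @export
loss_ds_grad <- function(x, y, eps = 1e-6) {
  check_same_grid(x, y)
  n <- length(x)
  pc <- pmin(pmax(x, BCE_CLIP), 1 - BCE_CLIP)
  g_bce <- (pc - y) / (pc * (1 - pc)) / n
  sp <- sum(x); sg <- sum(y); num <- 2 * sum(x * y) + eps
  den <- sp + sg + eps
  # d(1 - soft_dice)/dp = -(2*y*den - num) / den^2
  g_dice <- -(2 * y * den - num) / den^2
  g_bce + g_dice
}

as_target_list <- function(targets, class_names = NULL) {
  if (inherits(targets, "mask_set")) {
    return(targets$masks)
  }
  if (is.list(targets)) return(targets)
  if (is.array(targets) && length(dim(targets)) == 4L) {
    nc <- dim(targets)[3]
    nms <- class_names
    if (is.null(nms)) nms <- paste0("class", seq_len(nc))
    out <- lapply(seq_len(nc), function(ci) targets[, , ci, , drop = FALSE])
    names(out) <- nms
    return(out)
  }
  stop("targets must be a mask_set, a named list, or an (H,W,C,N) array",
       call. = FALSE)
}

#' Aggregate deep-supervision loss over classes and decoder levels
#'
#' Every side output is upscaled bilinearly to the input resolution and
#' compared to its class target with [loss_ds()]; the total is the equally
#' weighted mean over all (class, level) pairs. With `with_grad = TRUE` the
#' gradients with respect to each side output (at its native resolution) are
#' returned for backpropagation.
#'
#' @param out a forward output: list with `final_probs` (H, W, C, N) and
#'   `side_outputs` (per class, per level).
#' @param targets a [mask_set()], a named list of binary masks, or a binary
#'   (H, W, C, N) array in the class order of the model.
#' @param eps soft-Dice smoothing.
#' @param with_grad also return `grads[[class]][[level]]`.
#' @return list with `total`, `breakdown` (data.frame: class, level, bce,
#'   soft_dice, loss_ds), and optionally `grads`.
#' @export
deep_supervision_loss <- function(out, targets, eps = 1e-6,
                                  with_grad = FALSE) {
  tl <- as_target_list(targets)
  nc <- length(out$side_outputs)
  if (length(tl) != nc) {
    stop(sprintf("model has %d classes but targets have %d", nc, length(tl)),
         call. = FALSE)
  }
  d <- dim(out$final_probs)
  H <- d[1]; W <- d[2]
  nlev <- length(out$side_outputs[[1]])
  wgt <- 1 / (nc * nlev)
  rows <- list()
  grads <- if (with_grad) vector("list", nc) else NULL
  total <- 0
  for (ci in seq_len(nc)) {
    y <- tl[[ci]]
    ydim4 <- if (length(dim(y)) == 2L) array(y, dim = c(dim(y), 1L, 1L)) else y
    if (with_grad) grads[[ci]] <- vector("list", nlev)
    for (l in seq_len(nlev)) {
      p_native <- out$side_outputs[[ci]][[l]]
      pd <- dim(p_native)
      p_full <- resize_bilinear(p_native, H, W)
      p_full <- pmin(pmax(p_full, 0), 1)  # interpolation rounding guard
      b <- bce_loss(p_full, ydim4)
      sd_ <- soft_dice(p_full, ydim4, eps)
      ld <- b + 1 - sd_
      total <- total + wgt * ld
      rows[[length(rows) + 1L]] <- data.frame(
        class = if (!is.null(names(tl))) names(tl)[ci] else as.character(ci),
        level = l, bce = b, soft_dice = sd_, loss_ds = ld)
      if (with_grad) {
        g_full <- wgt * loss_ds_grad(p_full, ydim4, eps)
        grads[[ci]][[l]] <- resize_bilinear_bwd(g_full, pd[1], pd[2])
      }
    }
  }
  res <- list(total = total, breakdown = do.call(rbind, rows))
  if (with_grad) res$grads <- grads
  res
}
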