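# The modified U-Net: a shared 4-level residual encoder and N_c structurally
# identical, parameter-independent decoders, one per class. Each decoder
# upsamples with 2x2 stride-2 transposed convolutions, concatenates the skip
# feature of the corresponding encoder level, and carries a sigmoid side head
# per level for deep supervision; the full-resolution heads, stacked across
# decoders, form the final per-class probability map at input resolution.

#' Model configuration
#'
#' Defaults follow the published architecture: encoder levels of 3/4/6/3
#' residual blocks with 128/256/512/1024 channels, decoder levels of 6/4/3
#' blocks with 1024/512/256 channels. `width_scale` multiplies every channel
#' count (minimum 1) and exists to build desk-scale test models, e.g.
#' `width_scale = 0.0625` gives an 8/16/32/64-channel encoder.
#'
#' @param n_classes number of parallel decoders N_c (>= 1).
#' @param encoder_channels,encoder_blocks length-4 integer vectors.
#' @param decoder_channels,decoder_blocks length-3 integer vectors.
#' @param width_scale channel multiplier.
#' @param in_channels input image channels.
#' @param norm `"batch"` or `"none"`.
#' @return a `model_config` list with the scaled channel counts attached.
#' @export
model_config <- function(n_classes,
                         encoder_channels = c(128L, 256L, 512L, 1024L),
                         encoder_blocks = c(3L, 4L, 6L, 3L),
                         decoder_blocks = c(6L, 4L, 3L),
                         decoder_channels = c(1024L, 512L, 256L),
                         width_scale = 1.0,
                         in_channels = 1L,
                         norm = c("batch", "none")) {
  norm <- match.arg(norm)
  if (length(encoder_channels) != 4L || length(encoder_blocks) != 4L) {
    stop("encoder_channels and encoder_blocks must have length 4", call. = FALSE)
  }
  if (length(decoder_channels) != 3L || length(decoder_blocks) != 3L) {
    stop("decoder_channels and decoder_blocks must have length 3", call. = FALSE)
  }
  if (n_classes < 1L) stop("n_classes must be >= 1", call. = FALSE)
  scaled_enc <- pmax(1L, as.integer(round(encoder_channels * width_scale)))
  scaled_dec <- pmax(1L, as.integer(round(decoder_channels * width_scale)))
  structure(list(n_classes = as.integer(n_classes),
                 encoder_channels = as.integer(encoder_channels),
                 encoder_blocks = as.integer(encoder_blocks),
                 decoder_blocks = as.integer(decoder_blocks),
                 decoder_channels = as.integer(decoder_channels),
                 width_scale = width_scale,
                 in_channels = as.integer(in_channels),
                 norm = norm,
                 scaled_encoder_channels = scaled_enc,
                 scaled_decoder_channels = scaled_dec),
            class = "model_config")
}

# One decoder: 3 levels of (transposed-conv upsample -> concat skip ->
# residual blocks -> sigmoid side head). Level l consumes encoder level 4-l.
build_decoder <- function(cfg) {
  ec <- cfg$scaled_encoder_channels
  dc <- cfg$scaled_decoder_channels
  dec <- list(levels = list())
  prev <- ec[4]
  for (l in 1:3) {
    skip_ch <- ec[4 - l]
    up <- nn_convT(prev, skip_ch)
    cat_ch <- 2L * skip_ch
    blocks <- list()
    bin <- cat_ch
    for (b in seq_len(cfg$decoder_blocks[l])) {
      blocks[[b]] <- nn_resblock(bin, dc[l], cfg$norm)
      bin <- dc[l]
    }
    head <- nn_conv(dc[l], 1L, 1L, 0L)
    dec$levels[[l]] <- list(up = up, blocks = blocks, head = head,
                            head_sig = nn_sigmoid())
    prev <- dc[l]
  }
  dec
}

#' Build a modified U-Net
#'
#' @param cfg a [model_config()].
#' @param seed optional seed for weight initialisation (two builds from the
#'   same config and seed have identical parameters).
#' @return a `munet` model object.
#' @export
build_model <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ec <- cfg$scaled_encoder_channels
  stem <- nn_conv(cfg$in_channels, ec[1], 3L)
  enc <- list()
  cin <- ec[1]
  for (lev in 1:4) {
    blocks <- list()
    for (b in seq_len(cfg$encoder_blocks[lev])) {
      blocks[[b]] <- nn_resblock(cin, ec[lev], cfg$norm)
      cin <- ec[lev]
    }
    enc[[lev]] <- blocks
  }
  pools <- list(nn_maxpool(), nn_maxpool(), nn_maxpool())
  decoders <- lapply(seq_len(cfg$n_classes), function(i) build_decoder(cfg))
  structure(list(cfg = cfg, stem = stem, enc = enc, pools = pools,
                 decoders = decoders),
            class = "munet")
}

#' @export
print.munet <- function(x, ...) {
  cat(sprintf("<munet> N_c=%d decoders, encoder %s ch, decoder %s ch, %s norm\n",
              x$cfg$n_classes,
              paste(x$cfg$scaled_encoder_channels, collapse = "/"),
              paste(x$cfg$scaled_decoder_channels, collapse = "/"),
              x$cfg$norm))
  cat(sprintf("  parameters: %d\n", count_params(x)))
  invisible(x)
}

model_param_modules <- function(model) {
  mods <- collect_param_modules(model$stem)
  for (lev in model$enc) for (b in lev) {
    mods <- c(mods, collect_param_modules(b))
  }
  for (dec in model$decoders) mods <- c(mods, decoder_param_modules(dec))
  mods
}

decoder_param_modules <- function(dec) {
  mods <- list()
  for (lv in dec$levels) {
    mods <- c(mods, collect_param_modules(lv$up))
    for (b in lv$blocks) mods <- c(mods, collect_param_modules(b))
    mods <- c(mods, collect_param_modules(lv$head))
  }
  mods
}

#' Number of trainable parameters of a model
#' @param model a `munet`.
#' @return integer parameter count.
#' @export
count_params <- function(model) {
  sum(vapply(model_param_modules(model),
             function(m) sum(vapply(m$params, length, numeric(1))),
             numeric(1)))
}

#' Parameter count of one isolated decoder stack
#' @param model a `munet`.
#' @param class_index which decoder.
#' @return integer parameter count.
#' @export
count_decoder_params <- function(model, class_index = 1L) {
  sum(vapply(decoder_param_modules(model$decoders[[class_index]]),
             function(m) sum(vapply(m$params, length, numeric(1))),
             numeric(1)))
}

#' Copy all parameters of one decoder into another
#'
#' Useful for symmetry checks: two weight-identical decoders produce
#' identical output channels.
#' @param model a `munet`.
#' @param from,to decoder indices.
#' @export
copy_decoder_params <- function(model, from, to) {
  src <- decoder_param_modules(model$decoders[[from]])
  dst <- decoder_param_modules(model$decoders[[to]])
  for (i in seq_along(src)) {
    dst[[i]]$params <- src[[i]]$params
    dst[[i]]$state <- src[[i]]$state
  }
  invisible(model)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Forward pass
#'
#' @param model a `munet`.
#' @param x input batch, array (H, W, in_channels, N) with values in [0, 1];
#'   H and W must be divisible by 8 (three pooling stages).
#' @param training use batch statistics and keep caches for backprop.
#' @return list with `final_probs` (H, W, N_c, N) — the stacked
#'   full-resolution decoder outputs — and `side_outputs`, a list over
#'   classes of per-level probability maps at native resolutions
#'   (H/4, H/2, H).
#' @export
munet_forward <- function(model, x, training = FALSE) {
  d <- dim(x)
  if (length(d) == 2L) {
    x <- array(x, dim = c(d, 1L, 1L))
    d <- dim(x)
  }
  if (d[1] %% 8L != 0L || d[2] %% 8L != 0L) {
    stop(sprintf("input spatial size %dx%d must be divisible by 8 (three 2x2 poolings)",
                 d[1], d[2]), call. = FALSE)
  }
  e0 <- nn_forward(model$stem, x, training)
  e <- list()
  h <- e0
  for (lev in 1:4) {
    for (b in model$enc[[lev]]) h <- nn_forward(b, h, training)
    e[[lev]] <- h
    if (lev < 4L) h <- nn_forward(model$pools[[lev]], h, training)
  }
  nc <- model$cfg$n_classes
  side <- vector("list", nc)
  final <- array(0, dim = c(d[1], d[2], nc, d[4]))
  for (ci in seq_len(nc)) {
    dec <- model$decoders[[ci]]
    dcur <- e[[4]]
    side[[ci]] <- vector("list", 3L)
    for (l in 1:3) {
      lv <- dec$levels[[l]]
      u <- nn_forward(lv$up, dcur, training)
      h2 <- concat_ch(u, e[[4 - l]])
      for (b in lv$blocks) h2 <- nn_forward(b, h2, training)
      dcur <- h2
      logit <- nn_forward(lv$head, dcur, training)
      side[[ci]][[l]] <- nn_forward(lv$head_sig, logit, training)
    }
    final[, , ci, ] <- side[[ci]][[3]][, , 1L, ]
  }
  list(final_probs = final, side_outputs = side)
}

# Backward through the whole graph. `dside` is a list over classes of
# per-level gradients w.r.t. the sigmoid side outputs (same shapes as
# side_outputs). Gradients accumulate into every module's $grads.
munet_backward <- function(model, dside) {
  nc <- model$cfg$n_classes
  de <- vector("list", 4L)   # grad accumulators for encoder level outputs
  for (ci in seq_len(nc)) {
    dec <- model$decoders[[ci]]
    ddcur <- NULL
    for (l in 3:1) {
      lv <- dec$levels[[l]]
      dlogit <- nn_backward(lv$head_sig, dside[[ci]][[l]])
      dd <- nn_backward(lv$head, dlogit)
      if (!is.null(ddcur)) dd <- dd + ddcur
      for (b in rev(lv$blocks)) dd <- nn_backward(b, dd)
      # split concat grad into upsample branch and skip branch
      nu <- dim(dd)[3]  # total channels after concat
      up_ch <- lv$up$cout
      du <- dd[, , seq_len(up_ch), , drop = FALSE]
      dskip <- dd[, , up_ch + seq_len(nu - up_ch), , drop = FALSE]
      skip_lev <- 4L - l
      de[[skip_lev]] <- if (is.null(de[[skip_lev]])) dskip else de[[skip_lev]] + dskip
      ddcur <- nn_backward(lv$up, du)
    }
    de[[4L]] <- if (is.null(de[[4L]])) ddcur else de[[4L]] + ddcur
  }
  dh <- de[[4L]]
  for (lev in 4:1) {
    if (lev < 4L) {
      dh <- nn_backward(model$pools[[lev]], dh)
      dh <- dh + de[[lev]]
    }
    for (b in rev(model$enc[[lev]])) dh <- nn_backward(b, dh)
  }
  dx <- nn_backward(model$stem, dh)
  invisible(dx)
}

#' Predict class probabilities for a batch of slices (inference mode)
#'
#' @param model a `munet` or a plain function `batch -> probs` (an oracle
#'   predictor, used in tests and for ground-truth pass-through pipelines).
#' @param x array (H, W, in_channels, N) or a single (H, W) matrix.
#' @return probability array (H, W, N_c, N).
#' @export
munet_predict <- function(model, x) {
  if (is.function(model)) return(model(x))
  munet_forward(model, x, training = FALSE)$final_probs
}
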