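#' Normalise CT intensities to [0, 1]
#'
#' Linearly maps the soft-tissue window [-175, 250] HU onto [0, 1]; values
#' outside the window are clamped to the nearest bound. The result is
#' flagged as normalised, and normalising twice is an error — double
#' normalisation is a silent bug otherwise.
#'
#' @param vol a [ct_volume()] in HU (or a bare numeric array).
#' @param window HU window mapped to [0, 1].
#' @return the normalised volume/array.
#' @export
normalize_hu <- function(vol, window = c(-175, 250)) {
  if (inherits(vol, "ct_volume")) {
    if (vol$normalized) {
      stop("volume is already normalised; refusing to normalise twice",
           call. = FALSE)
    }
    out <- vol
    out$data <- pmin(pmax((vol$data - window[1]) / diff(window), 0), 1)
    out$normalized <- TRUE
    out
  } else {
    v <- pmin(pmax((vol - window[1]) / diff(window), 0), 1)
    v
  }
}

#' Augmentation configuration
#'
#' The three training-time augmentations and their stated probabilities:
#' per-axis random flips (p = 0.2), a random intensity shift of magnitude at
#' most 0.1 in normalised units applied with p = 0.5, and an in-plane random
#' rotation (p = 0.1, range -15..15 degrees).
#'
#' @param flip_prob_per_axis per-axis flip probability.
#' @param intensity_shift_offset maximum absolute shift (normalised units).
#' @param intensity_shift_prob probability the shift is applied.
#' @param rotation_prob probability an in-plane rotation is applied.
#' @param rotation_range_deg rotation range, symmetric about 0.
#' @param flip_3d also flip along z for 3D inputs (default in-plane only,
#'   since the model consumes axial slices).
#' @param seed optional seed recorded for bookkeeping; draws are taken from
#'   the R RNG stream so `set.seed()` before a run replays it exactly.
#' @return an `augment_config` list.
#' @export
augment_config <- function(flip_prob_per_axis = 0.2,
                           intensity_shift_offset = 0.1,
                           intensity_shift_prob = 0.5,
                           rotation_prob = 0.1,
                           rotation_range_deg = c(-15, 15),
                           flip_3d = FALSE,
                           seed = NULL) {
  probs <- c(flip_prob_per_axis, intensity_shift_prob, rotation_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(rotation_range_deg[1] + rotation_range_deg[2]) > 1e-9) {
    stop("rotation_range_deg must be symmetric about 0", call. = FALSE)
  }
  structure(list(flip_prob_per_axis = flip_prob_per_axis,
                 intensity_shift_offset = intensity_shift_offset,
                 intensity_shift_prob = intensity_shift_prob,
                 rotation_prob = rotation_prob,
                 rotation_range_deg = as.numeric(rotation_range_deg),
                 flip_3d = isTRUE(flip_3d),
                 seed = seed),
            class = "augment_config")
}

# In-plane rotation about the image centre by inverse mapping.
rotate2d <- function(mat, angle_deg, interp = c("linear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  th <- angle_deg * pi / 180
  d <- dim(mat)
  cy <- (d[1] + 1) / 2; cx <- (d[2] + 1) / 2
  yy <- rep(seq_len(d[1]), times = d[2]) - cy
  xx <- rep(seq_len(d[2]), each = d[1]) - cx
  # inverse rotation: source = R(-th) . target
  sy <- cos(th) * yy + sin(th) * xx + cy
  sx <- -sin(th) * yy + cos(th) * xx + cx
  if (interp == "nearest") {
    iy <- round(sy); ix <- round(sx)
    ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2]
    out <- rep(fill, length(yy))
    out[ok] <- mat[cbind(iy[ok], ix[ok])]
  } else {
    y0 <- floor(sy); x0 <- floor(sx)
    wy <- sy - y0; wx <- sx - x0
    out <- rep(fill, length(yy))
    gather <- function(iy, ix) {
      ok <- iy >= 1 & iy <= d[1] & ix >= 1 & ix <= d[2]
      v <- rep(fill, length(iy))
      v[ok] <- mat[cbind(iy[ok], ix[ok])]
      v
    }
    out <- gather(y0, x0) * (1 - wy) * (1 - wx) +
      gather(y0 + 1, x0) * wy * (1 - wx) +
      gather(y0, x0 + 1) * (1 - wy) * wx +
      gather(y0 + 1, x0 + 1) * wy * wx
  }
  matrix(out, nrow = d[1], ncol = d[2])
}

flip_array <- function(arr, axis) {
  d <- dim(arr)
  idx <- lapply(seq_along(d), function(a) {
    if (a == axis) rev(seq_len(d[a])) else seq_len(d[a])
  })
  do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
}

#' Apply the training-time augmentations
#'
#' Flips and rotation are applied identically to the image and every mask
#' (linear interpolation for the image, nearest for masks); the intensity
#' shift touches the image only and is clamped back into [0, 1]. Draws come
#' from the R RNG stream, so seeding before the call replays the transform.
#'
#' @param image normalised 2D matrix or 3D array (values in [0, 1]).
#' @param masks a [mask_set()] or a named list of binary arrays with the
#'   same shape as `image`.
#' @param cfg an [augment_config()].
#' @return list with `image` and `masks` (same type as supplied).
#' @export
augment <- function(image, masks, cfg = augment_config()) {
  was_mask_set <- inherits(masks, "mask_set")
  mlist <- if (was_mask_set) masks$masks else masks
  for (nm in names(mlist)) {
    if (!identical(dim(mlist[[nm]]), dim(image))) {
      stop(sprintf("mask '%s' shape differs from image", nm), call. = FALSE)
    }
  }
  nd <- length(dim(image))
  flip_axes <- if (nd == 2L) 1:2 else if (cfg$flip_3d) 1:3 else 2:3

  for (ax in flip_axes) {
    if (stats::runif(1) < cfg$flip_prob_per_axis) {
      image <- flip_array(image, ax)
      mlist <- lapply(mlist, flip_array, axis = ax)
    }
  }
  if (stats::runif(1) < cfg$intensity_shift_prob) {
    delta <- stats::runif(1, -cfg$intensity_shift_offset,
                          cfg$intensity_shift_offset)
    image <- pmin(pmax(image + delta, 0), 1)
  }
  if (stats::runif(1) < cfg$rotation_prob) {
    angle <- stats::runif(1, cfg$rotation_range_deg[1],
                          cfg$rotation_range_deg[2])
    rot_img <- function(m) rotate2d(m, angle, "linear", fill = 0)
    rot_msk <- function(m) rotate2d(m, angle, "nearest", fill = 0)
    if (nd == 2L) {
      image <- rot_img(image)
      mlist <- lapply(mlist, function(m) {
        r <- rot_msk(m); storage.mode(r) <- "integer"; r
      })
    } else {
      for (i in seq_len(dim(image)[1])) image[i, , ] <- rot_img(image[i, , ])
      mlist <- lapply(mlist, function(m) {
        for (i in seq_len(dim(m)[1])) m[i, , ] <- rot_msk(m[i, , ])
        storage.mode(m) <- "integer"
        m
      })
    }
  }
  mlist <- lapply(mlist, function(m) { storage.mode(m) <- "integer"; m })
  masks_out <- if (was_mask_set) mask_set(mlist, names(mlist)) else mlist
  list(image = image, masks = masks_out)
}
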