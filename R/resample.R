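# Grid resampling under the voxel-centre convention. Interpolation is
# separable, one axis at a time, which is exact for (tri)linear and nearest.

interp_axis <- function(arr, axis, src_idx, interp) {
  d <- dim(arr)
  n <- d[axis]
  perm <- c(setdiff(seq_along(d), axis), axis)
  m <- matrix(aperm(arr, perm), ncol = n)
  if (interp == "nearest") {
    i <- pmin(pmax(as.integer(round(src_idx)) + 1L, 1L), n)
    out <- m[, i, drop = FALSE]
  } else {
    i0 <- floor(src_idx)
    w <- src_idx - i0
    lo <- pmin(pmax(as.integer(i0) + 1L, 1L), n)
    hi <- pmin(lo + 1L, n)
    w[lo == hi] <- 0
    out <- m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
      m[, hi, drop = FALSE] * rep(w, each = nrow(m))
  }
  new_d <- d
  new_d[axis] <- length(src_idx)
  aperm(array(out, dim = new_d[perm]), order(perm))
}

#' Resample a volume to a new voxel spacing
#'
#' The output grid covers the same world extent as the input (within one
#' voxel) and stays world-coordinate consistent: the origin is adjusted so
#' voxel centres of both grids refer to the same physical space. Use
#' `interp = "linear"` for images and `"nearest"` for masks.
#'
#' In the pipeline, the ROI stage resamples to 4 mm isotropic and the
#' fine-segmentation stage to 0.7 mm in-plane (keeping the native slice
#' spacing along z).
#'
#' @param vol a [ct_volume()].
#' @param target_spacing numeric length-3 (mm) along (z, y, x); use the
#'   input spacing on axes that should be left alone.
#' @param interp `"linear"` or `"nearest"`.
#' @return a resampled [ct_volume()].
#' @export
resample <- function(vol, target_spacing, interp = c("linear", "nearest")) {
  interp <- match.arg(interp)
  target_spacing <- as.numeric(target_spacing)
  if (length(target_spacing) != 3L || any(!is.finite(target_spacing)) ||
      any(target_spacing <= 0)) {
    stop("`target_spacing` must be three positive values (mm)", call. = FALSE)
  }
  d <- dim(vol$data)
  n_new <- pmax(1L, as.integer(round(d * vol$spacing / target_spacing)))
  # keep the leading world edge fixed: edge = origin - spacing/2
  new_origin <- vol$origin - vol$spacing / 2 + target_spacing / 2
  out <- vol$data
  for (ax in 1:3) {
    if (n_new[ax] == d[ax] && abs(target_spacing[ax] - vol$spacing[ax]) < 1e-12) next
    centres <- new_origin[ax] + (seq_len(n_new[ax]) - 1) * target_spacing[ax]
    src_idx <- (centres - vol$origin[ax]) / vol$spacing[ax]  # 0-based fractional
    out <- interp_axis(out, ax, src_idx, interp)
  }
  ct_volume(out, spacing = target_spacing, origin = new_origin, id = vol$id,
            normalized = vol$normalized)
}

#' Resample a mask set with nearest-neighbour interpolation
#'
#' @param masks a [mask_set()].
#' @param grid the [ct_volume()] the masks live on.
#' @param target_spacing numeric length-3 (mm).
#' @return a [mask_set()] on the resampled grid.
#' @export
resample_mask_set <- function(masks, grid, target_spacing) {
  out <- lapply(masks$class_names, function(nm) {
    mv <- ct_volume(array(as.double(masks$masks[[nm]]),
                          dim = dim(masks$masks[[nm]])),
                    spacing = grid$spacing, origin = grid$origin)
    m <- resample(mv, target_spacing, interp = "nearest")$data
    storage.mode(m) <- "integer"
    m
  })
  names(out) <- masks$class_names
  mask_set(out, class_names = masks$class_names)
}

#' Centre-pad or centre-crop a 2D slice to an exact size
#'
#' @param slice 2D numeric matrix.
#' @param size integer length-2 target (rows, cols).
#' @param fill pad value (normalised-intensity background is 0).
#' @return matrix of dimension `size`, with attribute `offset`: the 0-based
#'   position of the input's (1,1) pixel in the output frame (negative when
#'   cropped), so the operation can be inverted.
#' @export
pad_or_crop_to <- function(slice, size, fill = 0) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) {
    stop("`size` must be two positive integers", call. = FALSE)
  }
  d <- dim(slice)
  out <- matrix(fill, nrow = size[1], ncol = size[2])
  off <- integer(2)
  src <- list(); dst <- list()
  for (ax in 1:2) {
    if (d[ax] <= size[ax]) {
      start <- (size[ax] - d[ax]) %/% 2L          # pad
      src[[ax]] <- seq_len(d[ax])
      dst[[ax]] <- start + seq_len(d[ax])
      off[ax] <- start
    } else {
      start <- (d[ax] - size[ax]) %/% 2L          # crop
      src[[ax]] <- start + seq_len(size[ax])
      dst[[ax]] <- seq_len(size[ax])
      off[ax] <- -start
    }
  }
  out[dst[[1]], dst[[2]]] <- slice[src[[1]], src[[2]]]
  attr(out, "offset") <- off
  out
}

#' Invert [pad_or_crop_to()] for a prediction on the padded frame
#'
#' @param padded matrix produced on the `size` frame (e.g. a probability
#'   map), carrying no attributes.
#' @param original_dim dim of the slice before padding/cropping.
#' @param fill value for regions cropped away (unseen by the model).
#' @return matrix of `original_dim`.
#' @export
unpad_or_uncrop <- function(padded, original_dim, fill = 0) {
  d <- as.integer(original_dim)
  size <- dim(padded)
  out <- matrix(fill, nrow = d[1], ncol = d[2])
  src <- list(); dst <- list()
  for (ax in 1:2) {
    if (d[ax] <= size[ax]) {
      start <- (size[ax] - d[ax]) %/% 2L
      src[[ax]] <- start + seq_len(d[ax])
      dst[[ax]] <- seq_len(d[ax])
    } else {
      start <- (d[ax] - size[ax]) %/% 2L
      src[[ax]] <- seq_len(size[ax])
      dst[[ax]] <- start + seq_len(size[ax])
    }
  }
  out[dst[[1]], dst[[2]]] <- padded[src[[1]], src[[2]]]
  out
}
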