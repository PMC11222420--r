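# Sliding-window inference, argmax post-processing, and restoration of
# labels from the 0.7 mm ROI grid to the original image space.

#' Sliding-window prediction over an ROI volume
#'
#' Each axial slice is covered by k x k windows on a regular stride grid
#' (stride `k * (1 - overlap)`, default overlap 0.5 so stride k/2, with the
#' final window shifted flush to the far edge); per-class probabilities are
#' averaged over every window covering a pixel. Slices smaller than the
#' window are centre-padded to k, predicted as a single window, and cropped
#' back.
#'
#' @param model a `munet` (or oracle function, see [munet_predict()]).
#' @param roi_vol normalised ROI [ct_volume()] (0.7 mm in-plane).
#' @param k window side length.
#' @param overlap overlap fraction (default 0.5).
#' @param n_classes number of classes predicted (needed for oracle
#'   functions; taken from the model otherwise).
#' @param batch_windows windows per forward pass.
#' @return probability array (nz, H, W, C) on the ROI grid.
#' @export
sliding_window_predict <- function(model, roi_vol, k = 128L, overlap = 0.5,
                                   n_classes = NULL, batch_windows = 16L) {
  if (!roi_vol$normalized) {
    stop("roi_vol must be normalised ([normalize_hu()]) before prediction",
         call. = FALSE)
  }
  if (is.null(n_classes)) {
    if (is.function(model)) stop("n_classes is required for oracle models",
                                 call. = FALSE)
    n_classes <- model$cfg$n_classes
  }
  d <- dim(roi_vol$data)
  nz <- d[1]
  out <- array(0, dim = c(nz, d[2], d[3], n_classes))
  pad_hw <- pmax(d[2:3], k)

  for (zi in seq_len(nz)) {
    img <- roi_vol$data[zi, , ]
    if (any(dim(img) < k)) {
      img <- pad_or_crop_to(img, pad_hw, fill = 0)
      attr(img, "offset") <- NULL
    }
    H <- nrow(img); W <- ncol(img)
    ys <- sliding_starts(H, k, overlap)
    xs <- sliding_starts(W, k, overlap)
    grid <- expand.grid(y = ys, x = xs)
    acc <- array(0, dim = c(H, W, n_classes))
    cnt <- matrix(0, H, W)
    for (lo in seq(1L, nrow(grid), by = batch_windows)) {
      hi <- min(lo + batch_windows - 1L, nrow(grid))
      nb <- hi - lo + 1L
      xb <- array(0, dim = c(k, k, 1L, nb))
      for (i in seq_len(nb)) {
        g <- grid[lo + i - 1L, ]
        xb[, , 1L, i] <- img[(g$y + 1):(g$y + k), (g$x + 1):(g$x + k)]
      }
      probs <- munet_predict(model, xb)
      for (i in seq_len(nb)) {
        g <- grid[lo + i - 1L, ]
        rows <- (g$y + 1):(g$y + k); cols <- (g$x + 1):(g$x + k)
        acc[rows, cols, ] <- acc[rows, cols, , drop = FALSE] +
          array(probs[, , , i], dim = c(k, k, n_classes))
        cnt[rows, cols] <- cnt[rows, cols] + 1
      }
    }
    for (ci in seq_len(n_classes)) acc[, , ci] <- acc[, , ci] / cnt
    if (any(d[2:3] < k)) {
      for (ci in seq_len(n_classes)) {
        out[zi, , , ci] <- unpad_or_uncrop(acc[, , ci], d[2:3])
      }
    } else {
      out[zi, , , ] <- acc
    }
  }
  out
}

#' Argmax + 50% post-processing
#'
#' Per pixel the class with the highest probability wins (exact ties go to
#' the lowest class index); pixels whose winning probability is below 0.5
#' become background (label 0).
#'
#' @param probs probability array whose last axis is the class axis
#'   (e.g. (nz, H, W, C) from [sliding_window_predict()]).
#' @param threshold the 50% cutoff.
#' @return integer label array (class index 1..C, 0 = background) of the
#'   spatial shape of `probs`.
#' @export
postprocess <- function(probs, threshold = 0.5) {
  d <- dim(probs)
  nc <- d[length(d)]
  spatial <- d[-length(d)]
  m <- matrix(probs, ncol = nc)
  lab <- max.col(m, ties.method = "first")
  maxp <- m[cbind(seq_len(nrow(m)), lab)]
  lab[maxp < threshold] <- 0L
  array(as.integer(lab), dim = spatial)
}

#' Restore ROI-grid labels to the original image space
#'
#' Nearest-neighbour resampling of the exclusive label volume from the
#' 0.7 mm ROI grid back onto the original grid, pasted into a
#' background-filled full-size volume at the box location.
#'
#' @param labels_roi integer label array (nz, H, W) on the ROI grid.
#' @param roi_grid [ct_volume()] describing the ROI grid.
#' @param original the original [ct_volume()].
#' @param box the [roi_box()] used for the crop.
#' @return integer label array of `dim(original$data)`.
#' @export
restore_to_original <- function(labels_roi, roi_grid, original, box) {
  if (is.null(roi_grid$spacing) || is.null(original$spacing)) {
    stop("resampling metadata missing", call. = FALSE)
  }
  out <- array(0L, dim = dim(original$data))
  rg <- box_to_index_range(box, original)
  dl <- dim(labels_roi)
  idx_axis <- function(ax) {
    ivals <- rg$start[ax]:(rg$stop[ax] - 1L)
    coords <- original$origin[ax] + (ivals - 1) * original$spacing[ax]
    src <- round((coords - roi_grid$origin[ax]) / roi_grid$spacing[ax]) + 1
    list(dst = ivals, src = pmin(pmax(as.integer(src), 1L), dl[ax]))
  }
  az <- idx_axis(1); ay <- idx_axis(2); ax_ <- idx_axis(3)
  out[az$dst, ay$dst, ax_$dst] <- labels_roi[az$src, ay$src, ax_$src]
  out
}

#' Run the full two-stage pipeline on one case
#'
#' Stage 1 derives the ROI box (from a coarse model, or directly from
#' ground-truth kidney/bladder masks when `coarse_model` is NULL — the
#' oracle-ROI mode used for desk-scale evaluation); stage 2 crops, resamples
#' to the working in-plane resolution, runs sliding-window prediction,
#' post-processes, and restores labels to the original grid.
#'
#' @param vol case [ct_volume()] in HU.
#' @param model trained stage-2 `munet` (N_c = 5).
#' @param coarse_model stage-1 `munet` (N_c = 2) or NULL for oracle-ROI mode.
#' @param gt_masks [mask_set()]; required in oracle-ROI mode.
#' @param inplane_mm working in-plane resolution of stage 2.
#' @param k,overlap sliding-window geometry.
#' @param margin_axis see [derive_roi_box()].
#' @return list with `labels` (original grid), `box`, `probs` and `roi_grid`.
#' @export
segment_case <- function(vol, model, coarse_model = NULL, gt_masks = NULL,
                         inplane_mm = 0.7, k = 128L, overlap = 0.5,
                         margin_axis = "z") {
  if (is.null(coarse_model)) {
    if (is.null(gt_masks)) {
      stop("oracle-ROI mode needs gt_masks", call. = FALSE)
    }
    coarse <- mask_set(gt_masks$masks[c("kidney", "urinary_bladder")])
    box <- derive_roi_box(coarse, vol, margin_axis = margin_axis)
  } else {
    coarse <- predict_coarse(vol, coarse_model)
    box <- derive_roi_box(coarse, margin_axis = margin_axis)
  }
  prep <- prepare_case(vol, NULL, box, inplane_mm = inplane_mm)
  probs <- sliding_window_predict(model, prep$volume, k = k, overlap = overlap,
                                  n_classes = if (is.function(model)) 5L else NULL)
  labels_roi <- postprocess(probs)
  labels <- restore_to_original(labels_roi, prep$volume, vol, box)
  list(labels = labels, box = box, probs = probs, roi_grid = prep$volume)
}
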