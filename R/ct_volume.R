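#' CT volume container
#'
#' A `ct_volume` holds a 3D scalar grid in Hounsfield units together with its
#' geometry. The array is indexed `(z, y, x)` where `z` is the craniocaudal
#' (slice) axis, so `vol$data[i, , ]` is one axial slice. Geometry follows the
#' voxel-centre convention: the world position (mm) of voxel `(i, j, k)`
#' (1-based in R) is `origin + (c(i, j, k) - 1) * spacing` per axis.
#'
#' @param data 3D numeric array indexed (z, y, x); values in HU unless
#'   `normalized = TRUE`.
#' @param spacing numeric length-3, mm per voxel along (z, y, x); all > 0.
#' @param origin numeric length-3, world mm of the centre of voxel (1, 1, 1).
#' @param id case identifier string.
#' @param normalized logical; `TRUE` once intensities have been mapped to
#'   [0, 1] by [normalize_hu()].
#' @return An object of class `ct_volume`.
#' @seealso [mask_set()], [load_volume()], [resample()]
#' @export
ct_volume <- function(data, spacing, origin = c(0, 0, 0), id = "case",
                      normalized = FALSE) {
  if (length(dim(data)) != 3L) {
    stop("`data` must be a 3D array indexed (z, y, x)", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be three positive finite values (mm)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be three finite values (mm)", call. = FALSE)
  }
  if (anyNA(data) || any(!is.finite(data))) {
    stop("volume data must be finite everywhere (no NA/NaN/Inf)", call. = FALSE)
  }
  structure(
    list(data = data, spacing = spacing, origin = origin, id = as.character(id),
         normalized = isTRUE(normalized)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume '%s'> %d x %d x %d voxels (z,y,x)\n", x$id, d[1], d[2], d[3]))
  cat(sprintf("  spacing (mm): %.3f %.3f %.3f | origin (mm): %.1f %.1f %.1f\n",
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  intensity: %s, range [%.1f, %.1f]\n",
              if (x$normalized) "normalised [0,1]" else "HU",
              min(x$data), max(x$data)))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param vol a [ct_volume()].
#' @param idx integer matrix (n x 3) of 1-based (z, y, x) indices.
#' @return numeric matrix (n x 3) of world mm positions.
#' @export
voxel_to_world <- function(vol, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Voxel index containing a world point
#'
#' Rounds to the nearest voxel centre (the voxel whose cell contains the
#' point under the voxel-centre convention).
#'
#' @param vol a [ct_volume()].
#' @param world numeric matrix (n x 3) of world mm positions (z, y, x).
#' @return integer matrix (n x 3) of 1-based indices (may be out of range).
#' @export
world_to_voxel <- function(vol, world) {
  world <- matrix(as.numeric(world), ncol = 3)
  idx <- sweep(sweep(world, 2, vol$origin, "-"), 2, vol$spacing, "/")
  matrix(as.integer(round(idx)), ncol = 3) + 1L
}

#' Multi-label mask set
#'
#' Ordered, named collection of binary masks sharing one volume grid. Masks
#' are multi-label: classes may overlap (adjacent ureter subclasses share a
#' configurable boundary slab), so a single exclusive label map cannot
#' represent the ground truth.
#'
#' @param masks named list of 3D arrays with values in {0, 1}, all of one shape.
#' @param class_names character; defaults to `names(masks)`, fixes the order.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(masks, class_names = names(masks)) {
  if (is.null(class_names) || any(!nzchar(class_names))) {
    stop("masks must be named", call. = FALSE)
  }
  masks <- masks[class_names]
  shp <- dim(masks[[1]])
  for (nm in class_names) {
    m <- masks[[nm]]
    if (!identical(dim(m), shp)) {
      stop(sprintf("mask '%s' shape differs from '%s'", nm, class_names[1]),
           call. = FALSE)
    }
    v <- as.vector(m)
    if (anyNA(v) || any(v != 0 & v != 1)) {
      stop(sprintf("mask '%s' has values outside {0, 1}", nm), call. = FALSE)
    }
    storage.mode(masks[[nm]]) <- "integer"
  }
  structure(list(masks = masks, class_names = class_names), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  d <- dim(x$masks[[1]])
  cat(sprintf("<mask_set> %d classes on %d x %d x %d grid\n",
              length(x$class_names), d[1], d[2], d[3]))
  for (nm in x$class_names) {
    cat(sprintf("  %-16s %d voxels\n", nm, sum(x$masks[[nm]])))
  }
  invisible(x)
}

#' The five urinary-system class names, in canonical order
#' @export
uroseg_classes <- function() {
  c("kidney", "proximal_ureter", "middle_ureter", "distal_ureter",
    "urinary_bladder")
}

#' The three ureter subclass names
#' @export
ureter_classes <- function() {
  c("proximal_ureter", "middle_ureter", "distal_ureter")
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("arrays are not on the same grid (shape mismatch)", call. = FALSE)
  }
  invisible(TRUE)
}
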