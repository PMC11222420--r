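# Cropable Centre Area: the set of pixel positions where the centre of a
# k x k window can lie with the window fully inside an H x W slice,
#   CCA(I) = { (x, y) : k/2 <= x < W - k/2,  k/2 <= y < H - k/2 }
# (0-based pixel coordinates; x runs over width, y over height). Training
# windows are sampled from it; k = W (or H) makes the set empty, in which
# case a single centred window is the stated fallback.

#' Window geometry for CCA sampling and sliding-window inference
#'
#' @param H,W slice height and width in pixels.
#' @param k window side length (default 128).
#' @param overlap sliding-window overlap fraction in [0, 1).
#' @return a `window_geometry` list.
#' @export
window_geometry <- function(H, W, k = 128L, overlap = 0.5) {
  if (k < 1L || H < 1L || W < 1L) stop("H, W, k must be positive", call. = FALSE)
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)", call. = FALSE)
  structure(list(H = as.integer(H), W = as.integer(W), k = as.integer(k),
                 overlap = overlap),
            class = "window_geometry")
}

#' Cropable Centre Area bounds
#'
#' @param geom a [window_geometry()].
#' @return list with half-open integer bounds `x_range`, `y_range` (0-based
#'   centre coordinates), `n_centres`, `empty`, and — when empty — the
#'   fallback single centred window position `fallback_centre` (x, y).
#' @export
cca <- function(geom) {
  half <- geom$k / 2
  x_lo <- ceiling(half)
  x_hi <- ceiling(geom$W - half)  # exclusive
  y_lo <- ceiling(half)
  y_hi <- ceiling(geom$H - half)
  nx <- max(0L, x_hi - x_lo)
  ny <- max(0L, y_hi - y_lo)
  empty <- nx == 0L || ny == 0L
  out <- list(x_range = c(x_lo, x_hi), y_range = c(y_lo, y_hi),
              n_centres = nx * ny, empty = empty)
  if (empty) {
    out$fallback_centre <- c(x = floor(geom$W / 2), y = floor(geom$H / 2))
  }
  out
}

# half-open pixel extent [lo, hi) of a window centred at c (0-based)
window_extent <- function(centre, k) {
  lo <- centre - k %/% 2L
  c(lo, lo + k)
}

#' Sample non-overlapping random window centres from the CCA
#'
#' Rejection sampling: candidate centres are drawn uniformly from the CCA
#' and accepted when their window has zero-area intersection with every
#' accepted window (centre Chebyshev distance >= k). The attempt budget is
#' bounded, so fewer than `max_points` centres may be returned.
#'
#' When the window does not fit along an axis (`k >= H` or `k >= W`) the
#' CCA is empty by definition; that axis's centre is then fixed at the
#' single centred coordinate while any remaining free axis is still
#' sampled. With both axes degenerate this reduces to the single centred
#' fallback window.
#'
#' @param geom a [window_geometry()].
#' @param max_points maximum number of centres (default 10, the per-slice
#'   per-epoch budget used during training).
#' @param max_attempts rejection-sampling budget.
#' @return integer matrix (n x 2), columns `x`, `y` (0-based).
#' @export
sample_window_centres <- function(geom, max_points = 10L,
                                  max_attempts = 50L * max_points) {
  stopifnot(max_points >= 1L)
  cc <- cca(geom)
  nx <- cc$x_range[2] - cc$x_range[1]
  ny <- cc$y_range[2] - cc$y_range[1]
  if (nx <= 0L && ny <= 0L) {
    return(matrix(c(floor(geom$W / 2), floor(geom$H / 2)), ncol = 2,
                  dimnames = list(NULL, c("x", "y"))))
  }
  draw_x <- if (nx <= 0L) function() floor(geom$W / 2) else
    function() cc$x_range[1] + sample.int(nx, 1L) - 1L
  draw_y <- if (ny <= 0L) function() floor(geom$H / 2) else
    function() cc$y_range[1] + sample.int(ny, 1L) - 1L
  acc <- matrix(integer(0), ncol = 2)
  attempts <- 0L
  while (nrow(acc) < max_points && attempts < max_attempts) {
    attempts <- attempts + 1L
    cx <- draw_x()
    cy <- draw_y()
    if (nrow(acc) == 0L ||
        all(pmax(abs(acc[, 1] - cx), abs(acc[, 2] - cy)) >= geom$k)) {
      acc <- rbind(acc, c(cx, cy))
    }
  }
  colnames(acc) <- c("x", "y")
  acc
}

#' Sliding-window start positions covering one axis
#'
#' Regular stride `k * (1 - overlap)`; the final window is shifted to end
#' flush with the far edge, so every pixel is covered.
#'
#' @param n axis length in pixels.
#' @param k window size (`n >= k`).
#' @param overlap overlap fraction.
#' @return integer vector of 0-based start positions.
#' @export
sliding_starts <- function(n, k, overlap = 0.5) {
  if (n < k) stop("axis shorter than window", call. = FALSE)
  stride <- max(1L, as.integer(round(k * (1 - overlap))))
  s <- seq(0L, n - k, by = stride)
  if (s[length(s)] != n - k) s <- c(s, n - k)
  as.integer(s)
}
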