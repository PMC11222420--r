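# Shared fixtures: desk-scale configs and a lazily generated phantom reused
# across test files. Everything is generated in code at test time.

# small, fast phantom: 160 x 96 x 96 mm at (4, 1.5, 1.5) mm voxels
tiny_phantom_config <- function(seed = 1L, ...) {
  phantom_config(volume_shape_vox = c(40L, 64L, 64L),
                 spacing_mm = c(4, 1.5, 1.5),
                 kidney_radius_mm = c(13, 16),
                 bladder_radius_mm = c(13, 16),
                 landmark_z_mm = c(72, 100),
                 seed = seed, ...)
}

# ultra-small phantom for harness tests (64 x 64 x 64 mm)
micro_phantom_config <- function(seed = 1L, ...) {
  phantom_config(volume_shape_vox = c(16L, 32L, 32L),
                 spacing_mm = c(4, 2, 2),
                 kidney_radius_mm = c(6, 7),
                 bladder_radius_mm = c(6, 7),
                 landmark_z_mm = c(26, 40),
                 noise_sd_hu = 5,
                 seed = seed)
}

# model small enough for module contracts (reduced depth and width)
tiny_model_config <- function(n_classes, norm = "batch") {
  model_config(n_classes = n_classes, width_scale = 0.0625,
               encoder_blocks = c(1L, 1L, 1L, 1L),
               decoder_blocks = c(1L, 1L, 1L), norm = norm)
}

# one shared default phantom, generated once per test run
shared_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_config(), id = "shared")
    cache
  }
})

shared_tiny_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(tiny_phantom_config(), id = "tiny")
    cache
  }
})

gt_roi_box <- function(case, ...) {
  coarse <- mask_set(case$masks$masks[c("kidney", "urinary_bladder")])
  derive_roi_box(coarse, case$volume, ...)
}

# oracle probability model: returns per-class probabilities equal to
# pre-computed masks at the slices named by attr(batch, "slice_idx"),
# padded the same way predict_coarse pads its input
oracle_coarse_model <- function(masks_4mm, input_size = 128L) {
  function(batch) {
    idx <- attr(batch, "slice_idx")
    nb <- dim(batch)[4]
    nc <- length(masks_4mm)
    probs <- array(0, dim = c(dim(batch)[1], dim(batch)[2], nc, nb))
    for (i in seq_len(nb)) {
      for (ci in seq_len(nc)) {
        sl <- masks_4mm[[ci]][idx[i], , ]
        probs[, , ci, i] <- pad_or_crop_to(sl, dim(batch)[1:2], fill = 0)
      }
    }
    probs
  }
}
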