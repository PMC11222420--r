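# CCA sampling, the training loop mechanics, sliding-window assembly,
# post-processing, and restoration to the original grid.

test_that("cca matches direct substitution into its definition", {
  c1 <- cca(window_geometry(256, 256, 128))
  expect_equal(c1$x_range, c(64, 192))
  expect_equal(c1$y_range, c(64, 192))
  expect_equal(c1$n_centres, 128^2)
  expect_false(c1$empty)

  c2 <- cca(window_geometry(128, 128, 128))
  expect_true(c2$empty)
  expect_equal(unname(c2$fallback_centre), c(64, 64))

  c3 <- cca(window_geometry(4, 4, 2))
  expect_equal(c3$x_range, c(1, 3))
  expect_equal(c3$y_range, c(1, 3))
  expect_equal(c3$n_centres, 4)
  # enumeration oracle: brute-force count of admissible centres
  brute <- sum(outer(0:3, 0:3, function(y, x)
    x >= 1 & x < 3 & y >= 1 & y < 3))
  expect_equal(c3$n_centres, brute)
})

test_that("sampled windows are inside the slice and pairwise non-overlapping", {
  # geometry admitting exactly one non-overlapping window
  g1 <- window_geometry(130, 130, 128)
  set.seed(1)
  expect_equal(nrow(sample_window_centres(g1, max_points = 10)), 1)

  g <- window_geometry(512, 512, 128)
  set.seed(2)
  for (i in 1:50) {
    cs <- sample_window_centres(g, 10)
    for (r in seq_len(nrow(cs))) {
      ex <- uroseg:::window_extent(cs[r, 1], g$k)
      ey <- uroseg:::window_extent(cs[r, 2], g$k)
      expect_true(ex[1] >= 0 && ex[2] <= g$W && ey[1] >= 0 && ey[2] <= g$H)
    }
    # O(n^2) interval-intersection oracle
    if (nrow(cs) > 1) {
      for (a in 1:(nrow(cs) - 1)) for (b in (a + 1):nrow(cs)) {
        exa <- uroseg:::window_extent(cs[a, 1], g$k)
        exb <- uroseg:::window_extent(cs[b, 1], g$k)
        eya <- uroseg:::window_extent(cs[a, 2], g$k)
        eyb <- uroseg:::window_extent(cs[b, 2], g$k)
        ox <- max(0, min(exa[2], exb[2]) - max(exa[1], exb[1]))
        oy <- max(0, min(eya[2], eyb[2]) - max(eya[1], eyb[1]))
        expect_equal(ox * oy, 0)
      }
    }
  }
})

test_that("sliding starts use stride k/2 and cover every pixel flush to the edge", {
  s <- sliding_starts(256, 128, overlap = 0.5)
  expect_equal(s, c(0L, 64L, 128L))
  s2 <- sliding_starts(300, 128, overlap = 0.5)
  expect_equal(s2[length(s2)], 300 - 128)   # flush final window
  covered <- rep(FALSE, 300)
  for (st in s2) covered[(st + 1):(st + 128)] <- TRUE
  expect_true(all(covered))
})

test_that("assembly: constant model, single-window equivalence, order invariance", {
  # constant-output oracle: assembled map identical to the constant
  const_model <- function(batch) {
    array(0.37, c(dim(batch)[1], dim(batch)[2], 3, dim(batch)[4]))
  }
  vol <- ct_volume(array(runif(2 * 200 * 180), c(2, 200, 180)),
                   spacing = c(4, 0.7, 0.7), normalized = TRUE)
  probs <- sliding_window_predict(const_model, vol, k = 64, n_classes = 3)
  expect_true(all(abs(probs - 0.37) < 1e-15))

  # a slice exactly k x k equals the single forward pass bit-for-bit
  m <- build_model(tiny_model_config(2), seed = 9)
  slice <- matrix(runif(64 * 64), 64, 64)
  vol1 <- ct_volume(array(slice, c(1, 64, 64)), spacing = c(4, 0.7, 0.7),
                    normalized = TRUE)
  swp <- sliding_window_predict(m, vol1, k = 64)
  xb <- array(slice, c(64, 64, 1, 1))
  direct <- munet_predict(m, xb)
  expect_identical(as.vector(swp[1, , , ]), as.vector(direct[, , , 1]))

  # window visit order (batch partitioning) does not change the result
  vol2 <- ct_volume(array(runif(1 * 96 * 96), c(1, 96, 96)),
                    spacing = c(4, 0.7, 0.7), normalized = TRUE)
  p1 <- sliding_window_predict(m, vol2, k = 64, batch_windows = 1L)
  p2 <- sliding_window_predict(m, vol2, k = 64, batch_windows = 16L)
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("postprocess applies argmax with the 50% background rule", {
  probs <- array(0, c(5, 1, 1, 3))       # 5 pixels, class axis last
  probs[1, 1, 1, ] <- c(0.6, 0.3, 0.2)   # clear winner above 0.5
  probs[2, 1, 1, ] <- c(0.4, 0.45, 0.3)  # all below 0.5 -> background
  probs[3, 1, 1, ] <- c(0.7, 0.7, 0.1)   # exact tie -> lowest index
  probs[4, 1, 1, ] <- c(0.2, 0.9, 0.9)   # tie at 2/3 -> class 2
  probs[5, 1, 1, ] <- c(0.5, 0.2, 0.2)   # exactly 0.5 stays foreground
  lab <- postprocess(probs)
  expect_equal(as.vector(lab), c(1L, 0L, 1L, 2L, 1L))
})

test_that("restore_to_original is exact for the identity geometry and confined to the box", {
  ph <- shared_tiny_phantom()
  # identity: ROI grid == original grid, full box
  d <- dim(ph$volume$data)
  full_box <- roi_box(ph$volume$origin - 1, ph$volume$origin + (d - 1) *
                        ph$volume$spacing + 1)
  lab <- array(0L, d); lab[10:20, 11:30, 12:33] <- 3L
  out <- restore_to_original(lab, ph$volume, ph$volume, full_box)
  expect_identical(out, lab)

  # through the 0.7 mm ROI grid: foreground stays inside the voxelised box
  box <- gt_roi_box(ph)
  prep <- prepare_case(ph$volume, ph$masks, box)
  lroi <- array(0L, dim(prep$volume$data))
  lroi[, , ] <- prep$masks$masks$kidney
  out2 <- restore_to_original(lroi, prep$volume, ph$volume, box)
  rg <- box_to_index_range(box, ph$volume)
  outside <- out2
  outside[rg$start[1]:(rg$stop[1] - 1), rg$start[2]:(rg$stop[2] - 1),
          rg$start[3]:(rg$stop[3] - 1)] <- 0L
  expect_equal(sum(outside), 0)

  # a compact blob's world centroid moves by less than one original voxel
  centroid <- function(mask, grid) {
    idx <- which(mask != 0, arr.ind = TRUE)
    colMeans(voxel_to_world(grid, idx))
  }
  c_orig <- centroid(ph$masks$masks$kidney, ph$volume)
  c_rest <- centroid(out2, ph$volume)
  expect_true(all(abs(c_orig - c_rest) < ph$volume$spacing))
})

test_that("training is seed-deterministic and its loss log is well-formed", {
  ph <- generate_phantom(micro_phantom_config(seed = 21))
  box <- gt_roi_box(ph)
  prep <- prepare_case(ph$volume, ph$masks, box, inplane_mm = 2)
  cfg <- train_config(max_points_per_slice = 1L, epochs = 1L, batch_size = 4L,
                      lr = 1e-3, k = 32L, slice_stride = 4L, seed = 5L)
  run_once <- function() {
    model <- build_model(model_config(5, width_scale = 0.03125,
                                      encoder_blocks = c(1, 1, 1, 1),
                                      decoder_blocks = c(1, 1, 1)), seed = 11)
    train(model, list(prep), cfg, aug = augment_config())
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$loss_log, r2$loss_log)
  expect_gt(nrow(r1$loss_log), 0)
  expect_true(all(is.finite(r1$loss_log$loss)))
  # checkpoint round trip preserves predictions
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(r1$model, ck, train_cfg = cfg)
  restored <- load_checkpoint(ck)$model
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(munet_predict(restored, x), munet_predict(r1$model, x))
})
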