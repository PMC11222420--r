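# Coarse stage: box derivation arithmetic, cropping bookkeeping, the
# ureter-containment audit, and the coarse prediction path.

test_that("derive_roi_box applies 15 mm / 6 mm margins to the foreground bbox", {
  # grid chosen so foreground voxel centres span exactly z 100..300,
  # y 80..200, x 60..220 mm
  grid <- ct_volume(array(0, c(100, 80, 80)), spacing = c(5, 5, 5))
  kid <- array(0L, c(100, 80, 80))
  # indices: z 100/5+1=21 .. 300/5+1=61, y 17..41, x 13..45
  kid[21:61, 17:41, 13:45] <- 1L
  bla <- array(0L, c(100, 80, 80))
  coarse <- mask_set(list(kidney = kid, urinary_bladder = kid))
  box <- derive_roi_box(coarse, grid)
  expect_equal(box$min_corner_mm, c(85, 74, 54))
  expect_equal(box$max_corner_mm, c(315, 206, 226))
  # zero margins give the tight bbox
  tight <- derive_roi_box(coarse, grid, 0, 0)
  expect_equal(tight$min_corner_mm, c(100, 80, 60))
  expect_equal(tight$max_corner_mm, c(300, 200, 220))
  # anterior-posterior variant puts the 15 mm on y
  alt <- derive_roi_box(coarse, grid, margin_axis = "y")
  expect_equal(alt$min_corner_mm, c(94, 65, 54))
  expect_equal(alt$max_corner_mm, c(306, 215, 226))
})

test_that("boxes are clamped to the volume extent and are monotone", {
  grid <- ct_volume(array(0, c(10, 10, 10)), spacing = c(4, 4, 4))
  m <- array(0L, c(10, 10, 10)); m[1:10, 1:10, 1:10] <- 1L
  coarse <- mask_set(list(kidney = m, urinary_bladder = m))
  box <- derive_roi_box(coarse, grid)
  expect_true(all(box$min_corner_mm >= -2 - 1e-9))       # edge = origin - s/2
  expect_true(all(box$max_corner_mm <= 9 * 4 + 2 + 1e-9))
  # enlarging the mask never shrinks the box
  small <- array(0L, c(10, 10, 10)); small[4:6, 4:6, 4:6] <- 1L
  big <- small; big[3:8, 3:8, 3:8] <- 1L
  b1 <- derive_roi_box(mask_set(list(kidney = small, urinary_bladder = small)), grid)
  b2 <- derive_roi_box(mask_set(list(kidney = big, urinary_bladder = big)), grid)
  expect_true(all(b2$min_corner_mm <= b1$min_corner_mm))
  expect_true(all(b2$max_corner_mm >= b1$max_corner_mm))
  # empty masks error
  z <- array(0L, c(10, 10, 10))
  expect_error(derive_roi_box(mask_set(list(kidney = z, urinary_bladder = z)),
                              grid), "empty")
})

test_that("crop_to_box preserves world coordinates and round-trips masks", {
  ph <- shared_tiny_phantom()
  box <- gt_roi_box(ph)
  cr <- crop_to_box(ph$volume, ph$masks, box)
  rg <- cr$index_range
  # paste back into zeros reproduces the mask inside the box
  for (nm in c("kidney", "urinary_bladder")) {
    full <- array(0L, dim(ph$volume$data))
    full[rg$start[1]:(rg$stop[1] - 1), rg$start[2]:(rg$stop[2] - 1),
         rg$start[3]:(rg$stop[3] - 1)] <- cr$masks$masks[[nm]]
    expect_identical(full[rg$start[1]:(rg$stop[1] - 1),
                          rg$start[2]:(rg$stop[2] - 1),
                          rg$start[3]:(rg$stop[3] - 1)],
                     ph$masks$masks[[nm]][rg$start[1]:(rg$stop[1] - 1),
                                          rg$start[2]:(rg$stop[2] - 1),
                                          rg$start[3]:(rg$stop[3] - 1)])
  }
  # a voxel's world position is identical before and after the crop
  idx_orig <- c(rg$start[1] + 2L, rg$start[2] + 3L, rg$start[3] + 4L)
  idx_crop <- idx_orig - rg$start + 1L
  expect_equal(voxel_to_world(ph$volume, matrix(idx_orig, ncol = 3)),
               voxel_to_world(cr$volume, matrix(idx_crop, ncol = 3)))
  # full-volume box is the identity crop
  d <- dim(ph$volume$data)
  full_box <- roi_box(ph$volume$origin - ph$volume$spacing / 4,
                      ph$volume$origin + (d - 1) * ph$volume$spacing +
                        ph$volume$spacing / 4)
  idcrop <- crop_to_box(ph$volume, ph$masks, full_box)
  expect_identical(idcrop$volume$data, ph$volume$data)
  # disjoint box errors
  far <- roi_box(c(1e4, 1e4, 1e4), c(1e4 + 10, 1e4 + 10, 1e4 + 10))
  expect_error(crop_to_box(ph$volume, NULL, far), "intersect")
})

test_that("audit flags violations and vacuous containment correctly", {
  ph <- shared_tiny_phantom()
  box <- gt_roi_box(ph)
  expect_true(audit_ureter_containment(ph$masks, ph$volume, box)$contained)
  # shrink to the superior half: distal ureter must fall outside
  half <- roi_box(box$min_corner_mm,
                  c(mean(c(box$min_corner_mm[1], box$max_corner_mm[1])),
                    box$max_corner_mm[2:3]))
  aud <- audit_ureter_containment(ph$masks, ph$volume, half)
  expect_false(aud$contained)
  expect_gt(aud$n_outside_voxels, 0)
  # no ureter voxels at all -> vacuously contained
  empty <- lapply(ph$masks$masks, function(m) array(0L, dim(m)))
  aud0 <- audit_ureter_containment(mask_set(empty, ph$masks$class_names),
                                   ph$volume, half)
  expect_true(aud0$contained)
  expect_identical(aud0$n_outside_voxels, 0L)
})

test_that("predict_coarse reproduces ground truth through an oracle model", {
  ph <- shared_phantom()
  gt4 <- resample_mask_set(ph$masks, ph$volume, c(4, 4, 4))
  oracle <- oracle_coarse_model(gt4$masks[c("kidney", "urinary_bladder")])
  coarse <- predict_coarse(ph$volume, oracle)
  # thresholding the oracle's binary probabilities returns GT exactly
  expect_identical(coarse$masks$masks$kidney, gt4$masks$kidney)
  expect_true(all(coarse$masks$masks$urinary_bladder %in% c(0L, 1L)))
  # resampling-loss oracle: restore the 4 mm mask to the native grid
  # (linear interpolation + 0.5 threshold) and compare with GT
  g4 <- coarse$grid
  back <- resample(ct_volume(array(as.double(coarse$masks$masks$kidney),
                                   dim(g4$data)),
                             spacing = g4$spacing, origin = g4$origin),
                   ph$volume$spacing, interp = "linear")
  bm <- back$data >= 0.5
  # grids may differ by one voxel at the edge; compare on the overlap
  dmin <- pmin(dim(back$data), dim(ph$volume$data))
  expect_gte(dice_coefficient(bm[1:dmin[1], 1:dmin[2], 1:dmin[3]],
                              ph$masks$masks$kidney[1:dmin[1], 1:dmin[2],
                                                    1:dmin[3]]), 0.9)
})

test_that("identical coarse channels give identical masks; empty prediction errors", {
  ph <- shared_tiny_phantom()
  gt4 <- resample_mask_set(ph$masks, ph$volume, c(4, 4, 4))
  sym <- oracle_coarse_model(list(kidney = gt4$masks$kidney,
                                  urinary_bladder = gt4$masks$kidney))
  coarse <- predict_coarse(ph$volume, sym)
  expect_identical(coarse$masks$masks$kidney, coarse$masks$masks$urinary_bladder)
  zero <- function(batch) array(0, c(dim(batch)[1], dim(batch)[2], 2, dim(batch)[4]))
  expect_error(predict_coarse(ph$volume, zero), "empty coarse prediction")
})
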