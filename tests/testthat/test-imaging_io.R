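# Volume I/O, the coordinate model, and grid resampling.

test_that("NIfTI round trip preserves data, spacing and origin", {
  set.seed(42)
  vol <- ct_volume(array(rnorm(6 * 8 * 10, sd = 200), c(6, 8, 10)),
                   spacing = c(4, 0.7, 0.7), origin = c(-12.5, 3, -7.25),
                   id = "rt")
  for (ext in c("v.nii", "v.nii.gz")) {
    p <- file.path(tempdir(), ext)
    write_nifti(vol, p, datatype = "float32")
    v2 <- read_nifti(p)
    expect_identical(v2$spacing, vol$spacing)
    expect_equal(v2$origin, vol$origin, tolerance = 1e-6)
    expect_equal(v2$data, vol$data, tolerance = 1e-5)  # float32 storage
  }
  # float64 storage is bit-exact
  p <- file.path(tempdir(), "v64.nii.gz")
  write_nifti(vol, p, datatype = "float64")
  expect_identical(read_nifti(p)$data, vol$data)
  # uint8 masks survive exactly
  m <- ct_volume(array(as.double(array(runif(6 * 8 * 10) > 0.5, c(6, 8, 10))),
                       c(6, 8, 10)),
                 spacing = vol$spacing)
  pm <- file.path(tempdir(), "m.nii.gz")
  write_nifti(m, pm, datatype = "uint8")
  expect_identical(read_nifti(pm)$data, m$data)
})

test_that("NIfTI output is readable by an independent implementation (nibabel)", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  vol <- ct_volume(array(seq_len(4 * 5 * 6) * 1.0, c(4, 5, 6)),
                   spacing = c(3, 1.5, 1.25), origin = c(10, -5, 2.5))
  p <- file.path(tempdir(), "nib.nii.gz")
  write_nifti(vol, p, datatype = "float64")
  script <- sprintf(
    "import nibabel, numpy as np\nimg = nibabel.load(%s)\nd = np.asarray(img.dataobj)\nprint(d.shape)\nprint(float(d.sum()))\nprint(' '.join('%%g' %% v for v in img.header.get_zooms()))\nprint(' '.join('%%g' %% v for v in img.affine[:3, 3]))\n",
    deparse(p))
  sf <- tempfile(fileext = ".py")
  writeLines(script, sf)
  out <- system2(py, sf, stdout = TRUE)
  expect_equal(out[1], "(6, 5, 4)")            # x, y, z on disk
  expect_equal(as.numeric(out[2]), sum(vol$data))
  expect_equal(scan(text = out[3], quiet = TRUE), c(1.25, 1.5, 3))  # x, y, z
  expect_equal(scan(text = out[4], quiet = TRUE), c(2.5, -5, 10))
})

test_that("DICOM series loads with rescale applied and geometry intact", {
  vol_hu <- array(round(rnorm(4 * 6 * 6, mean = 30, sd = 100)), c(4, 6, 6))
  d <- file.path(tempdir(), "dcm_ok")
  write_test_dicom_series(d, vol_hu, spacing_zyx = c(5, 0.8, 0.9),
                          origin_zyx = c(-10, 2, 3))
  v <- load_volume(d, format = "dicom_series")
  # stored 1024 + intercept -1024 -> HU 0 identity on round(HU)
  expect_equal(v$data, vol_hu)
  expect_equal(v$spacing, c(5, 0.8, 0.9))
  expect_equal(v$origin, c(-10, 2, 3))
  # a stored value of 1024 with intercept -1024 is exactly 0 HU
  one <- array(0, c(1, 2, 2))
  d1 <- file.path(tempdir(), "dcm_zero")
  write_test_dicom_series(d1, one, spacing_zyx = c(5, 1, 1))
  expect_true(all(read_dicom_series(d1)$data == 0))
})

test_that("inconsistent DICOM series raise errors naming the attribute", {
  d <- file.path(tempdir(), "dcm_bad_orient")
  unlink(d, recursive = TRUE); dir.create(d)
  img <- matrix(1100, 4, 4)
  write_test_dicom_slice(file.path(d, "a.dcm"), img, c(1, 1), c(0, 0, 0))
  write_test_dicom_slice(file.path(d, "b.dcm"), img, c(1, 1), c(0, 0, 5),
                         iop = c(0, 1, 0, 1, 0, 0))
  expect_error(read_dicom_series(d), "ImageOrientationPatient")

  d2 <- file.path(tempdir(), "dcm_dup")
  unlink(d2, recursive = TRUE); dir.create(d2)
  write_test_dicom_slice(file.path(d2, "a.dcm"), img, c(1, 1), c(0, 0, 0))
  write_test_dicom_slice(file.path(d2, "b.dcm"), img, c(1, 1), c(0, 0, 0))
  expect_error(read_dicom_series(d2), "ImagePositionPatient")

  expect_error(load_volume(file.path(tempdir(), "nope.nii")), "not found")
})

test_that("resample is an identity at the same spacing and preserves constants", {
  ph <- shared_tiny_phantom()
  v <- ph$volume
  same <- resample(v, v$spacing, interp = "linear")
  expect_equal(same$data, v$data, tolerance = 1e-12)
  const <- ct_volume(array(7, c(10, 12, 14)), spacing = c(2, 1, 1))
  for (sp in list(c(3, 3, 3), c(1, 0.7, 0.7), c(5, 2.5, 0.5))) {
    r <- resample(const, sp, interp = "linear")
    expect_equal(range(r$data), c(7, 7))
  }
})

test_that("nearest-resampled masks stay binary and world positions are consistent", {
  ph <- shared_tiny_phantom()
  m <- resample_mask_set(ph$masks, ph$volume, c(2, 0.7, 0.7))
  for (nm in m$class_names) {
    expect_true(all(m$masks[[nm]] %in% c(0L, 1L)))
  }
  # a point landmark keeps its world position across grids
  v <- ph$volume
  idx <- matrix(c(20, 30, 40), ncol = 3)
  p_world <- voxel_to_world(v, idx)
  marker <- v
  marker$data <- array(0, dim(v$data))
  marker$data[idx] <- 1000
  for (sp in list(c(4, 0.7, 0.7), c(3.7, 1.3, 0.9))) {
    r <- resample(marker, sp, interp = "nearest")
    # the voxel of the new grid containing p carries the landmark value
    tgt <- world_to_voxel(r, p_world)
    expect_equal(r$data[tgt], 1000)
    # and any other marked voxel centre is within half a voxel of p
    hit <- voxel_to_world(r, which(r$data == 1000, arr.ind = TRUE))
    for (ax in 1:3) {
      expect_lte(max(abs(hit[, ax] - p_world[ax])),
                 (v$spacing[ax] + sp[ax]) / 2 + 1e-9)
    }
  }
})

test_that("pad_or_crop_to centres pads and crops to the exact size", {
  a <- matrix(rnorm(100 * 100), 100, 100)
  p <- pad_or_crop_to(a, c(128, 128), fill = -1)
  expect_equal(dim(p), c(128, 128))
  expect_equal(p[15:114, 15:114], a)           # 14-pixel borders
  expect_true(all(p[1:14, ] == -1) && all(p[, 1:14] == -1))

  expect_equal(pad_or_crop_to(a, c(100, 100)), a, ignore_attr = TRUE)

  b <- matrix(seq_len(200 * 150), 200, 150)
  cr <- pad_or_crop_to(b, c(128, 128))
  expect_equal(dim(cr), c(128, 128))
  expect_equal(cr, b[37:164, 12:139], ignore_attr = TRUE)  # central crop

  # unpad inverts the pad
  expect_equal(unpad_or_uncrop(p, c(100, 100)), a)
})

test_that("mask sets round-trip through per-class and multi-label NIfTI", {
  ph <- shared_tiny_phantom()
  td <- file.path(tempdir(), "masks_rt")
  dir.create(td, showWarnings = FALSE)
  paths <- write_mask_set(ph$masks, ph$volume, file.path(td, "case"))
  m2 <- read_mask_set(paths)
  expect_identical(m2$masks, ph$masks$masks)

  ml <- file.path(td, "labels.nii.gz")
  write_mask_set_multilabel(ph$masks, ph$volume, ml)
  m3 <- read_mask_set_multilabel(ml)
  expect_identical(m3$masks, ph$masks$masks)
  expect_identical(m3$class_names, ph$masks$class_names)
})
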