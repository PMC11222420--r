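# Synthetic CT phantoms of the urinary system.
#
# The generator builds a desk-scale abdominopelvic volume containing the
# geometric and intensity structure the two-stage method assumes: paired
# ellipsoidal kidneys superiorly, a urine-filled bladder inferiorly on the
# midline, two thin tubular ureters (3-4 mm diameter) descending from renal
# pelvis to bladder wall through a retroperitoneal fat sheath, and vessel-like
# tubular confusers of near-identical radiodensity running alongside them —
# the non-contrast-CT ambiguity the fine-segmentation stage must resolve.
# Ureter subclasses (proximal/middle/distal) are split at two axial landmark
# levels (the synthetic stand-in for the sacroiliac-joint margins), with a
# configurable one-voxel overlap slab at each boundary, mirroring multi-label
# clinical ground truth.

#' Phantom generator configuration
#'
#' Defaults state the emulated world: 3 mm slice spacing (the finer of the
#' two source protocols), 1.5 mm in-plane spacing (desk scale; the fine stage
#' resamples to 0.7 mm regardless), ureter diameter 3-4 mm, non-contrast HU
#' levels (soft tissue ~40, urine ~10-20, fat ~-100, vessel ~40) and 10 HU
#' Gaussian noise.
#'
#' @param volume_shape_vox integer (nz, ny, nx).
#' @param spacing_mm numeric (sz, sy, sx) mm/voxel.
#' @param kidney_radius_mm range of the kidney size parameter r; ellipsoid
#'   semi-axes are `r * c(1.3, 0.7, 0.6)` along (z, y, x).
#' @param bladder_radius_mm range of the bladder radius.
#' @param ureter_diameter_mm range of ureter diameter; must lie in [1, 10].
#' @param landmark_z_mm the two axial landmark levels (superior, inferior)
#'   splitting the ureters into proximal/middle/distal; must lie strictly
#'   between the kidney and bladder centroids.
#' @param subclass_overlap_vox thickness (in z voxels) of the slab shared by
#'   adjacent ureter subclasses; 0 disables the overlap.
#' @param n_confuser_vessels number of vessel-like tubes near the ureters.
#' @param hu_means named list of tissue HU levels.
#' @param noise_sd_hu Gaussian noise standard deviation (HU).
#' @param seed RNG seed; identical configs generate bit-identical phantoms.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(volume_shape_vox = c(64L, 96L, 96L),
                           spacing_mm = c(3, 1.5, 1.5),
                           kidney_radius_mm = c(16, 20),
                           bladder_radius_mm = c(18, 23),
                           ureter_diameter_mm = c(3, 4),
                           landmark_z_mm = c(95, 130),
                           subclass_overlap_vox = 1L,
                           n_confuser_vessels = 2L,
                           hu_means = list(air = -1000, soft_tissue = 40,
                                           fat = -100, kidney = 35,
                                           urine = 15, vessel = 40),
                           noise_sd_hu = 10,
                           seed = 1L) {
  if (any(ureter_diameter_mm < 1) || any(ureter_diameter_mm > 10)) {
    stop("ureter_diameter_mm must lie within [1, 10]", call. = FALSE)
  }
  if (length(landmark_z_mm) != 2L || landmark_z_mm[1] >= landmark_z_mm[2]) {
    stop("landmark_z_mm must be (superior, inferior) with superior < inferior",
         call. = FALSE)
  }
  structure(list(
    volume_shape_vox = as.integer(volume_shape_vox),
    spacing_mm = as.numeric(spacing_mm),
    kidney_radius_mm = as.numeric(kidney_radius_mm),
    bladder_radius_mm = as.numeric(bladder_radius_mm),
    ureter_diameter_mm = as.numeric(ureter_diameter_mm),
    landmark_z_mm = as.numeric(landmark_z_mm),
    subclass_overlap_vox = as.integer(subclass_overlap_vox),
    n_confuser_vessels = as.integer(n_confuser_vessels),
    hu_means = hu_means,
    noise_sd_hu = as.numeric(noise_sd_hu),
    seed = as.integer(seed)
  ), class = "phantom_config")
}

# voxel-centre coordinate vectors of a grid
grid_coords <- function(shape, spacing, origin = c(0, 0, 0)) {
  lapply(1:3, function(ax) origin[ax] + (seq_len(shape[ax]) - 1) * spacing[ax])
}

rasterize_ellipsoid <- function(shape, coords, centre, semi_axes) {
  fz <- (coords[[1]] - centre[1]) / semi_axes[1]
  fy <- (coords[[2]] - centre[2]) / semi_axes[2]
  fx <- (coords[[3]] - centre[3]) / semi_axes[3]
  arr <- outer(outer(fz^2, fy^2, "+"), fx^2, "+")
  array(as.integer(arr <= 1), dim = shape)
}

# Mark voxels whose centre lies within `radius` of a densely sampled polyline.
rasterize_tube <- function(shape, spacing, origin, points_mm, radius_mm) {
  mask <- array(0L, dim = shape)
  for (p in seq_len(nrow(points_mm))) {
    pt <- points_mm[p, ]
    lo <- pmax(1L, ceiling((pt - radius_mm - origin) / spacing) + 1L)
    hi <- pmin(shape, floor((pt + radius_mm - origin) / spacing) + 1L)
    if (any(lo > hi)) next
    iz <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; ix <- lo[3]:hi[3]
    cz <- origin[1] + (iz - 1) * spacing[1]
    cy <- origin[2] + (iy - 1) * spacing[2]
    cx <- origin[3] + (ix - 1) * spacing[3]
    d2 <- outer(outer((cz - pt[1])^2, (cy - pt[2])^2, "+"), (cx - pt[3])^2, "+")
    blk <- mask[iz, iy, ix, drop = FALSE]
    blk[d2 <= radius_mm^2] <- 1L
    mask[iz, iy, ix] <- blk
  }
  mask
}

# Smooth random path from `from` to `to`: z is linear in the parameter (so
# the descent is monotone), y/x are splines through jittered control points,
# clamped into `clamp_box` (list(min =, max =), mm) when given.
sample_tube_path <- function(from, to, n_ctrl = 5, jitter_mm = 5,
                             n_samples = 300, clamp_box = NULL) {
  tt <- seq(0, 1, length.out = n_ctrl)
  ctrl <- sapply(1:3, function(ax) from[ax] + tt * (to[ax] - from[ax]))
  mid <- 2:(n_ctrl - 1)
  ctrl[mid, 2] <- ctrl[mid, 2] + stats::runif(length(mid), -jitter_mm, jitter_mm)
  ctrl[mid, 3] <- ctrl[mid, 3] + stats::runif(length(mid), -jitter_mm, jitter_mm)
  ts <- seq(0, 1, length.out = n_samples)
  path <- cbind(
    from[1] + ts * (to[1] - from[1]),
    stats::spline(tt, ctrl[, 2], xout = ts)$y,
    stats::spline(tt, ctrl[, 3], xout = ts)$y
  )
  if (!is.null(clamp_box)) {
    for (ax in 1:3) {
      path[, ax] <- pmin(pmax(path[, ax], clamp_box$min[ax]), clamp_box$max[ax])
    }
  }
  path
}

mask_bbox_mm <- function(mask, coords) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask has no bounding box", call. = FALSE)
  list(min = c(min(coords[[1]][idx[, 1]]), min(coords[[2]][idx[, 2]]),
               min(coords[[3]][idx[, 3]])),
       max = c(max(coords[[1]][idx[, 1]]), max(coords[[2]][idx[, 2]]),
               max(coords[[3]][idx[, 3]])))
}

#' Generate one synthetic CT phantom with ground truth
#'
#' Builds the CT volume and the five-class multi-label ground truth
#' (`kidney`, `proximal_ureter`, `middle_ureter`, `distal_ureter`,
#' `urinary_bladder`). By construction every ureter voxel lies inside the
#' axis-aligned bounding cuboid of kidneys plus bladder (the containment
#' property the ROI stage relies on), and adjacent ureter subclasses share a
#' `subclass_overlap_vox`-thick slab at each landmark level.
#'
#' @param config a [phantom_config()].
#' @param id case identifier.
#' @return list with `volume` ([ct_volume()]), `masks` ([mask_set()]),
#'   `landmark_z_mm`, and `config`.
#' @export
generate_phantom <- function(config = phantom_config(), id = "phantom") {
  set.seed(config$seed)
  shape <- config$volume_shape_vox
  sp <- config$spacing_mm
  origin <- c(0, 0, 0)
  extent <- shape * sp
  coords <- grid_coords(shape, sp, origin)
  hu <- config$hu_means

  centre_yx <- extent[2:3] / 2
  kr <- stats::runif(1, config$kidney_radius_mm[1], config$kidney_radius_mm[2])
  br <- stats::runif(1, config$bladder_radius_mm[1], config$bladder_radius_mm[2])
  ur_r <- stats::runif(1, config$ureter_diameter_mm[1],
                       config$ureter_diameter_mm[2]) / 2

  kid_z <- 0.22 * extent[1] + stats::runif(1, -4, 4)
  bla_z <- 0.82 * extent[1] + stats::runif(1, -4, 4)
  kid_dx <- 0.33 * extent[3]
  kid_semi <- kr * c(1.3, 0.7, 0.6)
  kid_centres <- list(
    c(kid_z, centre_yx[1] + stats::runif(1, -3, 3), centre_yx[2] - kid_dx),
    c(kid_z + stats::runif(1, -3, 3), centre_yx[1] + stats::runif(1, -3, 3),
      centre_yx[2] + kid_dx)
  )
  bla_centre <- c(bla_z, centre_yx[1] + stats::runif(1, -3, 3), centre_yx[2])

  lm <- config$landmark_z_mm
  if (!(kid_z < lm[1] && lm[2] < bla_z)) {
    stop("geometry error: landmark levels must lie strictly between kidney and bladder centroids",
         call. = FALSE)
  }
  if (bla_z + br > extent[1] || kid_z - kid_semi[1] < 0 ||
      kid_dx + kid_semi[3] > extent[3] / 2) {
    stop("geometry error: anatomy does not fit inside volume_shape_vox",
         call. = FALSE)
  }

  kidney <- rasterize_ellipsoid(shape, coords, kid_centres[[1]], kid_semi)
  kidney <- kidney | rasterize_ellipsoid(shape, coords, kid_centres[[2]], kid_semi)
  kidney <- array(as.integer(kidney), dim = shape)
  bladder <- rasterize_ellipsoid(shape, coords, bla_centre, br * c(0.9, 1, 1))

  organs <- array(as.integer(kidney | bladder), dim = shape)
  box <- mask_bbox_mm(organs, coords)
  # clamping the centreline by the tube radius keeps every tube voxel centre
  # inside the organ bounding cuboid (the containment guarantee)
  clamp_box <- list(min = box$min + ur_r + 0.1, max = box$max - ur_r - 0.1)

  ureter_full <- array(0L, dim = shape)
  paths <- list()
  for (side in 1:2) {
    kc <- kid_centres[[side]]
    pelvis <- c(kc[1] + 0.4 * kid_semi[1],
                kc[2],
                kc[3] + (if (side == 1) 0.5 else -0.5) * kid_semi[3])
    entry <- c(bla_centre[1] - 0.6 * br,
               bla_centre[2],
               bla_centre[3] + (if (side == 1) -0.4 else 0.4) * br)
    path <- sample_tube_path(pelvis, entry, n_ctrl = 5, jitter_mm = 5,
                             n_samples = 300, clamp_box = clamp_box)
    paths[[side]] <- path
    ureter_full <- ureter_full |
      rasterize_tube(shape, sp, origin, path, ur_r)
  }
  ureter_full <- array(as.integer(ureter_full), dim = shape)

  # subclass split at the landmark z-levels, with an overlap slab
  zc <- coords[[1]]
  ov <- config$subclass_overlap_vox * sp[1]
  in_z <- function(mask, zmin, zmax) {
    keep <- zc >= zmin & zc < zmax
    out <- mask
    out[!keep, , ] <- 0L
    out
  }
  proximal <- in_z(ureter_full, -Inf, lm[1] + ov)
  middle   <- in_z(ureter_full, lm[1], lm[2] + ov)
  distal   <- in_z(ureter_full, lm[2], Inf)

  # ---- image ----
  img <- array(hu$air, dim = shape)
  body <- rasterize_ellipsoid(shape, coords,
                              c(extent[1] / 2, centre_yx[1], centre_yx[2]),
                              c(extent[1], 0.46 * extent[2], 0.48 * extent[3]))
  img[body == 1] <- hu$soft_tissue

  # perirenal/perivesical fat capsules: on non-contrast CT the kidneys and
  # bladder are delineated by the radiodensity difference against adjacent
  # fat, so the capsule is part of the stated anatomy
  for (side in 1:2) {
    shell <- rasterize_ellipsoid(shape, coords, kid_centres[[side]],
                                 kid_semi * 1.25 + 2)
    img[shell == 1 & body == 1] <- hu$fat
  }
  bshell <- rasterize_ellipsoid(shape, coords, bla_centre,
                                br * c(0.9, 1, 1) * 1.15 + 2)
  img[bshell == 1 & body == 1] <- hu$fat

  # retroperitoneal fat sheath around each ureter, then vessel confusers
  for (side in 1:2) {
    sheath <- rasterize_tube(shape, sp, origin, paths[[side]], ur_r + 3)
    img[sheath == 1 & body == 1] <- hu$fat
  }
  vessels <- array(0L, dim = shape)
  for (v in seq_len(config$n_confuser_vessels)) {
    side <- if (v %% 2 == 1) 1 else 2
    ref <- paths[[side]]
    offset_y <- stats::runif(1, 4, 8) * sample(c(-1, 1), 1)
    vpath <- ref
    vpath[, 2] <- vpath[, 2] + offset_y
    vpath[, 3] <- vpath[, 3] + stats::runif(1, -3, 3)
    vr <- stats::runif(1, 1.5, 2.5)
    sheath <- rasterize_tube(shape, sp, origin, vpath, vr + 2.5)
    img[sheath == 1 & body == 1] <- hu$fat
    vtube <- rasterize_tube(shape, sp, origin, vpath, vr)
    vessels <- vessels | vtube
  }
  img[vessels == 1 & body == 1] <- hu$vessel
  img[kidney == 1] <- hu$kidney
  img[ureter_full == 1] <- hu$urine
  img[bladder == 1] <- hu$urine
  img <- img + stats::rnorm(length(img), 0, config$noise_sd_hu)

  masks <- mask_set(list(
    kidney = kidney,
    proximal_ureter = proximal,
    middle_ureter = middle,
    distal_ureter = distal,
    urinary_bladder = array(as.integer(bladder), dim = shape)
  ))
  vol <- ct_volume(img, spacing = sp, origin = origin, id = id)
  list(volume = vol, masks = masks, landmark_z_mm = lm, config = config)
}

#' Generate a cohort of phantom cases on disk
#'
#' Per-case anatomy is jittered by deriving a case seed from `seed`; the
#' same `(n, config, seed)` always reproduces the identical cohort. Each
#' case directory holds `image.nii.gz`, one mask NIfTI per class, and a JSON
#' sidecar with the class names and landmark levels; a `manifest.csv` lists
#' all cases.
#'
#' @param n number of cases (>= 1).
#' @param config a [phantom_config()]; per-case seeds override `config$seed`.
#' @param seed cohort seed.
#' @param out_dir output directory (created if needed).
#' @return the manifest as a data.frame (id, seed, path), invisibly written
#'   to `out_dir/manifest.csv`.
#' @export
generate_cohort <- function(n, config = phantom_config(), seed = 1L,
                            out_dir) {
  stopifnot(n >= 1)
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory %s", out_dir),
                  call. = FALSE)
  }
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_seed <- as.integer(seed * 1000L + i)
    cfg <- config
    cfg$seed <- case_seed
    id <- sprintf("case%03d", i)
    case <- generate_phantom(cfg, id = id)
    cdir <- file.path(out_dir, id)
    dir.create(cdir, showWarnings = FALSE)
    save_volume(case$volume, file.path(cdir, "image.nii.gz"))
    write_mask_set(case$masks, case$volume, file.path(cdir, "mask"))
    write_case_sidecar(file.path(cdir, "case.json"), id,
                       case$masks$class_names, case$landmark_z_mm,
                       extra = list(seed = case_seed))
    rows[[i]] <- data.frame(id = id, seed = case_seed, path = cdir,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Load a cohort case written by [generate_cohort()]
#'
#' @param case_dir one case directory.
#' @return list with `volume`, `masks`, `landmark_z_mm`, `id`.
#' @export
load_case <- function(case_dir) {
  sidecar <- read_case_sidecar(file.path(case_dir, "case.json"))
  vol <- read_nifti(file.path(case_dir, "image.nii.gz"), id = sidecar$id)
  paths <- file.path(case_dir, paste0("mask_", sidecar$class_names, ".nii.gz"))
  names(paths) <- sidecar$class_names
  masks <- read_mask_set(paths)
  list(volume = vol, masks = masks, landmark_z_mm = sidecar$landmark_z_mm,
       id = sidecar$id)
}
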