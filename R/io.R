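#' Load a CT volume from disk
#'
#' @param path a NIfTI file, or a directory holding one DICOM series.
#' @param format `"nifti"` or `"dicom_series"`; default guesses from `path`.
#' @param id optional case identifier.
#' @return a [ct_volume()] in Hounsfield units (DICOM rescale applied).
#' @export
load_volume <- function(path, format = c("auto", "nifti", "dicom_series"),
                        id = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  }
  switch(format,
         nifti = read_nifti(path, id = id),
         dicom_series = read_dicom_series(path, id = id))
}

#' Save a CT volume
#'
#' @param vol a [ct_volume()].
#' @param path output `.nii`/`.nii.gz` path.
#' @param datatype on-disk datatype, see [write_nifti()].
#' @export
save_volume <- function(vol, path, datatype = "float32") {
  write_nifti(vol, path, datatype = datatype)
}

#' Write a mask set as one uint8 NIfTI per class
#'
#' Files are named `<prefix>_<class>.nii.gz`. Because adjacent ureter
#' subclasses may overlap, masks cannot be collapsed into one exclusive label
#' map; see [write_mask_set_multilabel()] for the single-file alternative.
#'
#' @param masks a [mask_set()].
#' @param grid the companion [ct_volume()] supplying spacing/origin.
#' @param prefix path prefix for the per-class files.
#' @return named character vector of written paths.
#' @export
write_mask_set <- function(masks, grid, prefix) {
  paths <- character(0)
  for (nm in masks$class_names) {
    mv <- ct_volume(array(as.double(masks$masks[[nm]]), dim = dim(masks$masks[[nm]])),
                    spacing = grid$spacing, origin = grid$origin,
                    id = paste0(grid$id, "_", nm))
    p <- paste0(prefix, "_", nm, ".nii.gz")
    write_nifti(mv, p, datatype = "uint8")
    paths[nm] <- p
  }
  paths
}

#' Read a mask set stored as one NIfTI per class
#'
#' @param paths named character vector class name -> file path (order kept).
#' @return a [mask_set()].
#' @export
read_mask_set <- function(paths) {
  masks <- lapply(paths, function(p) {
    v <- read_nifti(p)
    m <- v$data
    m[m != 0] <- 1
    storage.mode(m) <- "integer"
    m
  })
  mask_set(masks, class_names = names(paths))
}

#' Write a mask set as a single multi-label bitmask NIfTI
#'
#' Class `i` (in `class_names` order) occupies bit `i - 1` of a uint8 voxel
#' value, so overlapping classes coexist in one file. The bit order is stored
#' in a sidecar JSON next to the image.
#'
#' @inheritParams write_mask_set
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_mask_set_multilabel <- function(masks, grid, path) {
  if (length(masks$class_names) > 8L) {
    stop("multi-label bitmask supports at most 8 classes", call. = FALSE)
  }
  enc <- array(0, dim = dim(masks$masks[[1]]))
  for (i in seq_along(masks$class_names)) {
    enc <- enc + masks$masks[[masks$class_names[i]]] * 2^(i - 1)
  }
  mv <- ct_volume(enc, spacing = grid$spacing, origin = grid$origin,
                  id = paste0(grid$id, "_labels"))
  write_nifti(mv, path, datatype = "uint8")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(class_names = masks$class_names), sidecar,
                       auto_unbox = FALSE)
  invisible(path)
}

#' Read a multi-label bitmask NIfTI written by [write_mask_set_multilabel()]
#'
#' @param path the bitmask NIfTI; its class-name sidecar JSON must sit next
#'   to it (or pass `class_names`).
#' @param class_names optional explicit bit order.
#' @return a [mask_set()].
#' @export
read_mask_set_multilabel <- function(path, class_names = NULL) {
  if (is.null(class_names)) {
    sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
    if (!file.exists(sidecar)) {
      stop(sprintf("class-name sidecar not found: %s", sidecar), call. = FALSE)
    }
    class_names <- unlist(jsonlite::read_json(sidecar)$class_names)
  }
  v <- read_nifti(path)
  enc <- round(v$data)
  masks <- list()
  for (i in seq_along(class_names)) {
    m <- (enc %/% 2^(i - 1)) %% 2
    storage.mode(m) <- "integer"
    masks[[class_names[i]]] <- m
  }
  mask_set(masks, class_names = class_names)
}

#' Write a per-case metadata sidecar
#'
#' @param path output JSON path.
#' @param id case id.
#' @param class_names class order of the case's masks.
#' @param landmark_z_mm the two axial landmark levels (mm) splitting the
#'   ureter into proximal/middle/distal, superior first.
#' @param extra named list of additional fields.
#' @export
write_case_sidecar <- function(path, id, class_names, landmark_z_mm,
                               extra = list()) {
  obj <- c(list(id = jsonlite::unbox(id),
                class_names = class_names,
                landmark_z_mm = as.numeric(landmark_z_mm)),
           extra)
  jsonlite::write_json(obj, path, digits = NA)
  invisible(path)
}

#' Read a per-case metadata sidecar
#' @param path JSON path written by [write_case_sidecar()].
#' @return a list with `id`, `class_names`, `landmark_z_mm` (numeric), plus
#'   any extra fields.
#' @export
read_case_sidecar <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$landmark_z_mm <- as.numeric(obj$landmark_z_mm)
  obj
}
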