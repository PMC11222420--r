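# Minimal NIfTI-1 I/O (single-file .nii / .nii.gz, little-endian).
#
# No NIfTI package ships with this environment, so the subset of the format
# the pipeline needs is implemented here: one 3D image per file, datatypes
# uint8/int16/int32/float32/float64, pixdim spacing, sform affine restricted
# to axis-aligned (diagonal) direction, scl_slope/scl_inter rescaling.
# On-disk voxel order is x-fastest; in memory the package uses (z, y, x).

NIFTI_DTYPES <- list(
  "2"   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  "4"   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  "8"   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  "16"  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  "64"  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  "512" = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

nifti_connection <- function(path, open) {
  # gzfile reads plain files transparently; for writing pick by extension
  if (startsWith(open, "w") && !grepl("\\.gz$", path)) {
    file(path, open)
  } else {
    gzfile(path, open)
  }
}

#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param id case identifier for the returned volume; default the file stem.
#' @return a [ct_volume()] with data indexed (z, y, x), spacing and origin
#'   taken from the header (sform offset when present), and
#'   `scl_slope`/`scl_inter` applied so intensities are in HU.
#' @export
read_nifti <- function(path, id = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  con <- nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header", call. = FALSE)
  rd <- function(off, what, n, size, signed = TRUE) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what, n = n, size = size,
            signed = signed, endian = "little")
  }
  sizeof_hdr <- rd(0L, "integer", 1L, 4L)
  if (sizeof_hdr != 348L) {
    stop("unsupported NIfTI file (not little-endian NIfTI-1)", call. = FALSE)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) {
    stop("missing NIfTI magic string", call. = FALSE)
  }
  dims <- rd(40L, "integer", 8L, 2L)
  ndim <- dims[1]
  if (ndim < 2L || ndim > 4L) {
    stop(sprintf("unsupported NIfTI dimensionality: %d", ndim), call. = FALSE)
  }
  nx <- dims[2]; ny <- dims[3]; nz <- if (ndim >= 3L) dims[4] else 1L
  if (ndim == 4L && dims[5] > 1L) {
    stop("4D NIfTI with multiple volumes is not supported", call. = FALSE)
  }
  datatype <- rd(70L, "integer", 1L, 2L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) {
    stop(sprintf("unsupported NIfTI datatype code %d", datatype), call. = FALSE)
  }
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  sform_code <- rd(254L, "integer", 1L, 2L)
  qoffset <- rd(268L, "double", 3L, 4L)  # qoffset_x, _y, _z
  srow_x <- rd(280L, "double", 4L, 4L)
  srow_y <- rd(296L, "double", 4L, 4L)
  srow_z <- rd(312L, "double", 4L, 4L)

  # header geometry is float32; snap to 7 significant digits so that common
  # mm spacings (0.7, 1.5, ...) round-trip exactly
  spacing_xyz <- signif(abs(pixdim[2:4]), 7)
  origin_xyz <- if (sform_code > 0L) {
    c(srow_x[4], srow_y[4], srow_z[4])
  } else {
    qoffset
  }
  origin_xyz <- ifelse(origin_xyz == 0, 0, signif(origin_xyz, 7))

  skip <- as.integer(round(vox_offset)) - 348L
  if (skip > 0L) readBin(con, "raw", n = skip)
  nvox <- as.double(nx) * ny * nz
  vals <- readBin(con, dt$what, n = nvox, size = dt$size, signed = dt$signed,
                  endian = "little")
  if (length(vals) != nvox) stop("truncated NIfTI data section", call. = FALSE)
  if (!is.na(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  arr_xyz <- array(as.double(vals), dim = c(nx, ny, nz))
  data <- aperm(arr_xyz, c(3L, 2L, 1L))  # -> (z, y, x)
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  ct_volume(data,
            spacing = c(spacing_xyz[3], spacing_xyz[2], spacing_xyz[1]),
            origin = c(origin_xyz[3], origin_xyz[2], origin_xyz[1]),
            id = id)
}

#' Write a volume as NIfTI-1
#'
#' @param vol a [ct_volume()] (or a bare 3D array plus `spacing`/`origin`).
#' @param path output path; gzip-compressed when it ends in `.gz`.
#' @param datatype one of `"float32"`, `"float64"`, `"uint8"`, `"int16"`.
#'   Masks should use `"uint8"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(vol, path, datatype = "float32") {
  stopifnot(inherits(vol, "ct_volume"))
  codes <- c(float32 = 16L, float64 = 64L, uint8 = 2L, int16 = 4L)
  sizes <- c(float32 = 4L, float64 = 8L, uint8 = 1L, int16 = 2L)
  if (!datatype %in% names(codes)) {
    stop(sprintf("unsupported datatype '%s'", datatype), call. = FALSE)
  }
  d <- dim(vol$data)                      # (nz, ny, nx)
  sp_xyz <- vol$spacing[c(3, 2, 1)]
  or_xyz <- vol$origin[c(3, 2, 1)]

  hdr <- raw(348L)
  put <- function(hdr, off, vals, what, size) {
    b <- writeBin(vals, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, d[3], d[2], d[1], 1L, 1L, 1L, 1L)),
             "integer", 2L)
  hdr <- put(hdr, 70L, codes[[datatype]], "integer", 2L)
  hdr <- put(hdr, 72L, 8L * sizes[[datatype]], "integer", 2L)  # bitpix
  hdr <- put(hdr, 76L, c(1, sp_xyz, 1, 1, 1, 1), "double", 4L)
  hdr <- put(hdr, 108L, 352, "double", 4L)   # vox_offset
  hdr <- put(hdr, 112L, c(1, 0), "double", 4L)  # scl_slope, scl_inter
  hdr[124L] <- as.raw(2L)  # xyzt_units: mm
  hdr <- put(hdr, 252L, c(0L, 1L), "integer", 2L)  # qform 0, sform 1
  hdr <- put(hdr, 280L, c(sp_xyz[1], 0, 0, or_xyz[1]), "double", 4L)
  hdr <- put(hdr, 296L, c(0, sp_xyz[2], 0, or_xyz[2]), "double", 4L)
  hdr <- put(hdr, 312L, c(0, 0, sp_xyz[3], or_xyz[3]), "double", 4L)
  hdr[345:348] <- as.raw(c(0x6e, 0x2b, 0x31, 0x00))  # "n+1\0"

  arr_xyz <- aperm(vol$data, c(3L, 2L, 1L))
  vals <- as.vector(arr_xyz)
  con <- nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)  # extension flag: none
  if (datatype %in% c("uint8", "int16")) {
    writeBin(as.integer(round(vals)), con, size = sizes[[datatype]],
             endian = "little")
  } else {
    writeBin(as.double(vals), con, size = sizes[[datatype]], endian = "little")
  }
  invisible(path)
}
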