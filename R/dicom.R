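# Minimal DICOM series reader: uncompressed little-endian (explicit or
# implicit VR), standard axial acquisitions with identity-like direction
# cosines only — anything else raises a format error naming the attribute.

dicom_read_u16 <- function(raw, off) {
  readBin(raw[(off + 1L):(off + 2L)], "integer", size = 2L, signed = FALSE,
          endian = "little")
}
dicom_read_u32 <- function(raw, off) {
  v <- readBin(raw[(off + 1L):(off + 4L)], "integer", size = 4L, endian = "little")
  if (v < 0) v <- v + 2^32
  v
}

# VRs that use a 2-byte reserved field + 4-byte length in explicit VR
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")

parse_dicom_file <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  bytes <- readBin(con, "raw", n = sz)
  if (length(bytes) < 136L || rawToChar(bytes[129:132]) != "DICM") {
    stop(sprintf("not a DICOM part-10 file: %s", path), call. = FALSE)
  }
  pos <- 132L
  elems <- list()
  explicit <- TRUE
  ts_uid <- "1.2.840.10008.1.2.1"
  in_meta_checked <- FALSE

  while (pos + 8L <= length(bytes)) {
    group <- dicom_read_u16(bytes, pos)
    element <- dicom_read_u16(bytes, pos + 2L)
    # after the (group 0002) file meta, switch VR mode per transfer syntax
    if (!in_meta_checked && group != 2L) {
      in_meta_checked <- TRUE
      if (ts_uid == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts_uid != "1.2.840.10008.1.2.1") {
        stop(sprintf("unsupported TransferSyntaxUID '%s' in %s", ts_uid, path),
             call. = FALSE)
      }
    }
    use_explicit <- explicit || group == 2L
    if (use_explicit) {
      vr <- rawToChar(bytes[(pos + 5L):(pos + 6L)])
      if (vr %in% DICOM_LONG_VRS) {
        len <- dicom_read_u32(bytes, pos + 8L)
        hdr_len <- 12L
      } else {
        len <- dicom_read_u16(bytes, pos + 6L)
        hdr_len <- 8L
      }
    } else {
      vr <- NA_character_
      len <- dicom_read_u32(bytes, pos + 4L)
      hdr_len <- 8L
    }
    if (len == 2^32 - 1) {
      stop(sprintf("undefined-length element (%04x,%04x) unsupported in %s",
                   group, element, path), call. = FALSE)
    }
    value_raw <- if (len > 0L) bytes[(pos + hdr_len + 1L):(pos + hdr_len + len)] else raw(0)
    key <- sprintf("%04x,%04x", group, element)
    elems[[key]] <- list(vr = vr, raw = value_raw)
    if (key == "0002,0010") {
      ts_uid <- trimws(rawToChar(value_raw[value_raw != as.raw(0)]))
    }
    pos <- pos + hdr_len + len
  }
  elems
}

dicom_string <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  trimws(rawToChar(e$raw[e$raw != as.raw(0)]))
}
dicom_numbers <- function(elems, key, default = NULL) {
  s <- dicom_string(elems, key)
  if (is.null(s) || !nzchar(s)) return(default)
  as.numeric(strsplit(s, "\\\\")[[1]])
}
dicom_u16_value <- function(elems, key, default = NULL) {
  e <- elems[[key]]
  if (is.null(e)) return(default)
  readBin(e$raw, "integer", size = 2L, signed = FALSE, endian = "little")
}

#' Read an axial DICOM series as a CT volume
#'
#' All `.dcm` files in `dir` are parsed, sorted superior-to-inferior by
#' ImagePositionPatient, checked for consistent geometry, rescaled to HU via
#' RescaleSlope/RescaleIntercept, and stacked into a [ct_volume()].
#'
#' Only uncompressed little-endian transfer syntaxes and axial slices with
#' identity-like ImageOrientationPatient are supported; violations raise an
#' error naming the offending attribute.
#'
#' @param dir directory containing one series (files `*.dcm`).
#' @param id case identifier; default the directory name.
#' @return a [ct_volume()] in HU.
#' @export
read_dicom_series <- function(dir, id = NULL) {
  if (!dir.exists(dir)) stop(sprintf("directory not found: %s", dir), call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.dcm$", full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop(sprintf("no DICOM files in %s", dir), call. = FALSE)

  slices <- lapply(files, function(f) {
    elems <- parse_dicom_file(f)
    rows <- dicom_u16_value(elems, "0028,0010")
    cols <- dicom_u16_value(elems, "0028,0011")
    bits <- dicom_u16_value(elems, "0028,0100", 16L)
    pixrep <- dicom_u16_value(elems, "0028,0103", 1L)
    spacing <- dicom_numbers(elems, "0028,0030")      # (row=y, col=x)
    ipp <- dicom_numbers(elems, "0020,0032")          # (x, y, z)
    iop <- dicom_numbers(elems, "0020,0037", c(1, 0, 0, 0, 1, 0))
    slope <- dicom_numbers(elems, "0028,1053", 1)
    inter <- dicom_numbers(elems, "0028,1052", 0)
    pd <- elems[["7fe0,0010"]]
    if (is.null(rows) || is.null(cols)) {
      stop(sprintf("missing Rows/Columns in %s", f), call. = FALSE)
    }
    if (is.null(spacing)) stop(sprintf("missing PixelSpacing in %s", f), call. = FALSE)
    if (is.null(ipp)) stop(sprintf("missing ImagePositionPatient in %s", f), call. = FALSE)
    if (is.null(pd)) stop(sprintf("missing PixelData in %s", f), call. = FALSE)
    if (bits != 16L) {
      stop(sprintf("unsupported BitsAllocated=%d in %s", bits, f), call. = FALSE)
    }
    if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4) {
      stop(sprintf("non-axial ImageOrientationPatient in %s", f), call. = FALSE)
    }
    stored <- readBin(pd$raw, "integer", n = rows * cols, size = 2L,
                      signed = pixrep == 1L, endian = "little")
    if (pixrep == 0L) stored[stored < 0] <- stored[stored < 0] + 65536
    hu <- stored * slope + inter
    # PixelData is row-major (columns fastest): matrix (x fastest) -> (y, x)
    img_yx <- t(matrix(hu, nrow = cols, ncol = rows))
    list(img = img_yx, ipp = ipp, spacing = spacing, iop = iop)
  })

  ipp_z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  if (anyDuplicated(round(ipp_z, 6))) {
    stop("duplicate slice positions (ImagePositionPatient)", call. = FALSE)
  }
  ord <- order(ipp_z)
  slices <- slices[ord]
  ipp_z <- ipp_z[ord]

  sp0 <- slices[[1]]$spacing
  for (s in slices) {
    if (max(abs(s$spacing - sp0)) > 1e-6) {
      stop("inconsistent PixelSpacing across series", call. = FALSE)
    }
  }
  if (length(slices) > 1L) {
    dz <- diff(ipp_z)
    if (max(dz) - min(dz) > 1e-3 * mean(dz)) {
      stop("non-uniform slice spacing (ImagePositionPatient)", call. = FALSE)
    }
    sz <- mean(dz)
  } else {
    sz <- 1
  }

  ny <- nrow(slices[[1]]$img); nx <- ncol(slices[[1]]$img)
  data <- array(0, dim = c(length(slices), ny, nx))
  for (i in seq_along(slices)) data[i, , ] <- slices[[i]]$img
  ipp0 <- slices[[1]]$ipp
  if (is.null(id)) id <- basename(normalizePath(dir))
  ct_volume(data, spacing = c(sz, sp0[1], sp0[2]),
            origin = c(ipp0[3], ipp0[2], ipp0[1]), id = id)
}
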