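# Minimal DICOM writer (explicit VR little endian) used to build test
# fixtures in code. Only the attributes the reader consumes are emitted.

dcm_elem <- function(group, element, vr, value_raw) {
  if (length(value_raw) %% 2L == 1L) {
    pad <- if (vr %in% c("UI")) as.raw(0) else charToRaw(" ")
    value_raw <- c(value_raw, pad)
  }
  head <- writeBin(c(as.integer(group), as.integer(element)), raw(),
                   size = 2L, endian = "little")
  if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
    c(head, charToRaw(vr), raw(2),
      writeBin(as.integer(length(value_raw)), raw(), size = 4L,
               endian = "little"),
      value_raw)
  } else {
    c(head, charToRaw(vr),
      writeBin(as.integer(length(value_raw)), raw(), size = 2L,
               endian = "little"),
      value_raw)
  }
}

dcm_str <- function(s) charToRaw(s)
dcm_u16 <- function(v) writeBin(as.integer(v), raw(), size = 2L, endian = "little")

write_test_dicom_slice <- function(path, pixel_matrix_yx, pixel_spacing_yx,
                                   ipp_xyz,
                                   iop = c(1, 0, 0, 0, 1, 0),
                                   rescale_slope = 1, rescale_intercept = -1024,
                                   instance = 1L) {
  rows <- nrow(pixel_matrix_yx); cols <- ncol(pixel_matrix_yx)
  stored <- as.integer(round(t(pixel_matrix_yx)))  # row-major on disk
  pix_raw <- writeBin(stored, raw(), size = 2L, endian = "little")

  meta <- c(
    dcm_elem(0x0002, 0x0010, "UI", dcm_str("1.2.840.10008.1.2.1"))
  )
  ds <- c(
    dcm_elem(0x0008, 0x0060, "CS", dcm_str("CT")),
    dcm_elem(0x0020, 0x0013, "IS", dcm_str(as.character(instance))),
    dcm_elem(0x0020, 0x0032, "DS",
             dcm_str(paste(format(ipp_xyz, trim = TRUE), collapse = "\\"))),
    dcm_elem(0x0020, 0x0037, "DS",
             dcm_str(paste(format(iop, trim = TRUE), collapse = "\\"))),
    dcm_elem(0x0028, 0x0010, "US", dcm_u16(rows)),
    dcm_elem(0x0028, 0x0011, "US", dcm_u16(cols)),
    dcm_elem(0x0028, 0x0030, "DS",
             dcm_str(paste(format(pixel_spacing_yx, trim = TRUE),
                           collapse = "\\"))),
    dcm_elem(0x0028, 0x0100, "US", dcm_u16(16L)),
    dcm_elem(0x0028, 0x0103, "US", dcm_u16(1L)),
    dcm_elem(0x0028, 0x1052, "DS", dcm_str(format(rescale_intercept))),
    dcm_elem(0x0028, 0x1053, "DS", dcm_str(format(rescale_slope))),
    dcm_elem(0x7FE0, 0x0010, "OW", pix_raw)
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(meta, con)
  writeBin(ds, con)
  invisible(path)
}

write_test_dicom_series <- function(dir, volume_zyx, spacing_zyx,
                                    origin_zyx = c(0, 0, 0), ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(volume_zyx)[1]
  for (i in seq_len(nz)) {
    # stored value = HU - intercept with slope 1
    stored <- volume_zyx[i, , ] + 1024
    write_test_dicom_slice(
      file.path(dir, sprintf("slice%03d.dcm", i)), stored,
      pixel_spacing_yx = spacing_zyx[2:3],
      ipp_xyz = c(origin_zyx[3], origin_zyx[2],
                  origin_zyx[1] + (i - 1) * spacing_zyx[1]),
      instance = i, ...)
  }
  dir
}
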