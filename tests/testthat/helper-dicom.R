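# Minimal DICOM writer used to build series fixtures at test time
# (explicit VR little endian, single-frame 16-bit grayscale).  Kept
# independent of the package's reader.

uint_raw <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) { out[i] <- as.raw(x %% 256); x <- x %/% 256 }
  out
}

dicom_element <- function(group, elem, vr, value) {
  if (is.character(value)) {
    value <- charToRaw(value)
    if (length(value) %% 2 == 1)
      value <- c(value, if (vr == "UI") as.raw(0) else charToRaw(" "))
  }
  head <- c(uint_raw(group, 2), uint_raw(elem, 2), charToRaw(vr))
  if (vr %in% c("OB", "OW", "SQ", "UN", "UT"))
    c(head, raw(2), uint_raw(length(value), 4), value)
  else
    c(head, uint_raw(length(value), 2), value)
}

write_test_dicom <- function(path, pix, instance = 1, spacing = c(1, 1),
                             slope = NULL, intercept = NULL) {
  stopifnot(is.matrix(pix))
  rows <- nrow(pix); cols <- ncol(pix)
  ## pixel data: row-major, 16-bit unsigned little endian
  vals <- as.integer(round(t(pix)))
  px <- writeBin(vals, raw(), size = 2, endian = "little")
  meta <- c(
    dicom_element(2L, 16L, "UI", "1.2.840.10008.1.2.1"))
  meta <- c(dicom_element(2L, 0L, "UL", uint_raw(length(meta), 4)), meta)
  ds <- c(
    dicom_element(8L, 22L, "UI", "1.2.840.10008.5.1.4.1.1.2"),
    dicom_element(32L, 19L, "IS", as.character(instance)),
    dicom_element(40L, 2L, "US", uint_raw(1, 2)),
    dicom_element(40L, 4L, "CS", "MONOCHROME2"),
    dicom_element(40L, 16L, "US", uint_raw(rows, 2)),
    dicom_element(40L, 17L, "US", uint_raw(cols, 2)),
    dicom_element(40L, 48L, "DS", paste(spacing, collapse = "\\")),
    dicom_element(40L, 256L, "US", uint_raw(16, 2)),
    dicom_element(40L, 257L, "US", uint_raw(16, 2)),
    dicom_element(40L, 258L, "US", uint_raw(15, 2)),
    dicom_element(40L, 259L, "US", uint_raw(0, 2)))
  if (!is.null(intercept))
    ds <- c(ds, dicom_element(40L, 4178L, "DS", as.character(intercept)))
  if (!is.null(slope))
    ds <- c(ds, dicom_element(40L, 4179L, "DS", as.character(slope)))
  ds <- c(ds, dicom_element(32736L, 16L, "OW", px))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta, ds), con)
  invisible(path)
}
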