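# Minimal DICOM reader: uncompressed little-endian transfer syntaxes
# (explicit VR 1.2.840.10008.1.2.1 and implicit VR 1.2.840.10008.1.2),
# single-frame grayscale images.  Written here because no DICOM reader
# is available as an R dependency; compressed syntaxes are rejected
# with a format error.

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

read_uint <- function(raw, signed = FALSE) {
  n <- length(raw)
  val <- sum(as.numeric(raw) * 256^(seq_len(n) - 1))
  if (signed && val >= 256^n / 2) val <- val - 256^n
  val
}

#' Read a single DICOM file
#'
#' Parses an uncompressed little-endian DICOM file and returns the pixel
#' data with rescale slope/intercept applied (when the tags are
#' present), plus the metadata needed for series assembly.
#'
#' @param path DICOM file path.
#' @return List with `image` (an [intensity_image()]), `instance_number`
#'   and `pixel_spacing`.
#' @export
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 140L) stop("'", path, "': not a DICOM file (too short)")
  explicit <- TRUE
  pos <- 1L
  if (length(raw) >= 132L && rawToChar(raw[129:132]) == "DICM") {
    pos <- 133L
    ## file meta group (0002) is always explicit little endian
    meta <- parse_elements(raw, pos, explicit = TRUE, stop_after_group2 = TRUE)
    ts <- meta$elements[["0002,0010"]]
    pos <- meta$pos
    if (!is.null(ts)) {
      ts <- trimws(rawToChar(ts[ts != as.raw(0)]))
      if (ts == "1.2.840.10008.1.2") explicit <- FALSE
      else if (ts != "1.2.840.10008.1.2.1")
        stop("'", path, "': unsupported transfer syntax ", ts,
             " (only uncompressed little endian is supported)")
    }
  }
  parsed <- parse_elements(raw, pos, explicit = explicit)
  el <- parsed$elements
  need <- function(tag, what) {
    v <- el[[tag]]
    if (is.null(v)) stop("'", path, "': missing DICOM tag ", what)
    v
  }
  rows <- read_uint(need("0028,0010", "Rows"))
  cols <- read_uint(need("0028,0011", "Columns"))
  bits <- read_uint(need("0028,0100", "BitsAllocated"))
  pixrep <- if (!is.null(el[["0028,0103"]])) read_uint(el[["0028,0103"]]) else 0
  px <- need("7fe0,0010", "PixelData")
  if (bits == 16L) {
    vals <- readBin(px, "integer", n = rows * cols, size = 2L,
                    signed = pixrep == 1, endian = "little")
    if (pixrep == 0) vals[vals < 0] <- vals[vals < 0] + 65536
  } else if (bits == 8L) {
    vals <- as.integer(px[seq_len(rows * cols)])
  } else stop("'", path, "': unsupported BitsAllocated ", bits)
  if (length(vals) < rows * cols)
    stop("'", path, "': truncated pixel data")
  slope <- dicom_numeric(el[["0028,1053"]], 1)
  inter <- dicom_numeric(el[["0028,1052"]], 0)
  vals <- vals * slope + inter
  ## DICOM stores row-major (column fastest); R arrays are column-major
  a <- t(matrix(vals, nrow = cols, ncol = rows))
  spacing <- el[["0028,0030"]]
  spacing <- if (!is.null(spacing)) {
    s <- as.numeric(strsplit(trimws(rawToChar(spacing[spacing != as.raw(0)])),
                             "\\\\")[[1L]])
    if (length(s) == 2L && all(is.finite(s)) && all(s > 0)) s else c(1, 1)
  } else c(1, 1)
  inst <- dicom_numeric(el[["0020,0013"]], NA_real_)
  thick <- dicom_numeric(el[["0018,0050"]], 1)
  list(image = intensity_image(a, spacing = spacing),
       instance_number = inst, pixel_spacing = spacing,
       slice_thickness = thick)
}

dicom_numeric <- function(v, default) {
  if (is.null(v)) return(default)
  s <- trimws(rawToChar(v[v != as.raw(0)]))
  x <- suppressWarnings(as.numeric(s))
  if (is.na(x)) default else x
}

parse_elements <- function(raw, pos, explicit, stop_after_group2 = FALSE) {
  elements <- list()
  n <- length(raw)
  while (pos + 7L <= n) {
    group <- read_uint(raw[pos:(pos + 1L)])
    elem <- read_uint(raw[(pos + 2L):(pos + 3L)])
    if (stop_after_group2 && group != 2L) break
    tag <- sprintf("%04x,%04x", group, elem)
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(raw[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- read_uint(raw[(pos + 4L):(pos + 7L)])
        pos <- pos + 8L
      } else {
        len <- read_uint(raw[(pos + 2L):(pos + 3L)])
        pos <- pos + 4L
      }
      if (vr == "SQ" || len == 4294967295) {
        if (len == 4294967295)
          stop("DICOM sequences of undefined length are not supported")
        pos <- pos + len
        next
      }
    } else {
      len <- read_uint(raw[pos:(pos + 3L)])
      pos <- pos + 4L
      if (len == 4294967295)
        stop("DICOM sequences of undefined length are not supported")
    }
    if (len > 0) {
      if (pos + len - 1L > n) stop("truncated DICOM element ", tag)
      elements[[tag]] <- raw[pos:(pos + len - 1L)]
      pos <- pos + len
    } else elements[[tag]] <- raw(0)
  }
  list(elements = elements, pos = pos)
}

#' Read a DICOM series directory as a volume
#'
#' Reads every DICOM file in the directory and stacks the slices in
#' ascending instance number into a `(row, column, slice)` volume.
#'
#' @param dir directory containing one DICOM file per slice.
#' @return An [intensity_image()] with `dims = 3`; spacing is
#'   `(row spacing, column spacing, slice thickness)` when tagged.
#' @export
read_dicom_series <- function(dir) {
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0L) stop("no files in DICOM directory '", dir, "'")
  slices <- lapply(files, read_dicom_file)
  shapes <- vapply(slices, function(s) paste(dim(s$image$data),
                                             collapse = "x"), character(1))
  if (length(unique(shapes)) != 1L)
    stop("mixed slice shapes in DICOM series: ",
         paste(unique(shapes), collapse = ", "))
  inst <- vapply(slices, `[[`, numeric(1), "instance_number")
  if (anyNA(inst)) inst[is.na(inst)] <- seq_along(slices)[is.na(inst)]
  ord <- order(inst)
  dm2 <- dim(slices[[1L]]$image$data)
  vol <- array(0, c(dm2, length(slices)))
  for (i in seq_along(ord)) vol[, , i] <- slices[[ord[i]]]$image$data
  sp <- c(slices[[1L]]$pixel_spacing, slices[[1L]]$slice_thickness)
  intensity_image(vol, spacing = sp)
}
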