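#' Load an image or volume into an intensity image
#'
#' Reads PNG/TIFF (2D), NIfTI (`.nii` / `.nii.gz`, 2D or 3D), a single
#' DICOM file, or a directory containing a DICOM series (slices stacked
#' in ascending instance number).  Raw intensities are preserved (DICOM
#' rescale slope/intercept applied when present); spacing is taken from
#' metadata when available, defaulting to 1 per axis.
#'
#' @param path file (or DICOM directory) path.
#' @param format_hint one of `"png"`, `"tiff"`, `"nifti"`, `"dicom"`;
#'   by default inferred from the file extension (a directory implies a
#'   DICOM series).
#' @return An [intensity_image()].
#' @export
load_image <- function(path, format_hint = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  fmt <- format_hint %||% guess_format(path)
  switch(fmt,
    png = {
      a <- png::readPNG(path)
      intensity_image(collapse_channels(a))
    },
    tiff = {
      a <- tiff::readTIFF(path)
      intensity_image(collapse_channels(a))
    },
    nifti = {
      v <- RNifti::readNifti(path)
      sp <- tryCatch(RNifti::pixdim(v), error = function(e) NULL)
      a <- array(as.numeric(v), dim(v))
      if (length(dim(a)) > 3L) stop("NIfTI with more than 3 dimensions")
      intensity_image(a, spacing = if (length(sp) == length(dim(a))) sp)
    },
    dicom = {
      if (dir.exists(path)) read_dicom_series(path)
      else read_dicom_file(path)$image
    },
    stop("unsupported format: ", fmt))
}

guess_format <- function(path) {
  if (dir.exists(path)) return("dicom")
  ext <- tolower(sub(".*\\.", "", sub("\\.gz$", "", basename(path))))
  switch(ext,
         png = "png", tif = "tiff", tiff = "tiff",
         nii = "nifti", dcm = "dicom", ima = "dicom",
         stop("cannot infer format of '", path,
              "'; pass format_hint = \"png\"/\"tiff\"/\"nifti\"/\"dicom\""))
}

collapse_channels <- function(a) {
  if (length(dim(a)) == 3L && dim(a)[3L] %in% c(2L, 3L, 4L)) {
    ## colour/alpha PNG or TIFF: average the colour channels
    a <- apply(a[, , seq_len(min(3L, dim(a)[3L])), drop = FALSE],
               c(1L, 2L), mean)
  }
  if (is.null(dim(a))) stop("could not interpret image data")
  a
}

#' Write a binary mask
#'
#' 2D masks are written as 8-bit PNG (0/255) or TIFF; 3D masks as NIfTI
#' with 0/1 voxels.  The format follows the file extension.
#'
#' @param mask logical array.
#' @param path output path (`.png`, `.tif(f)`, `.nii`, `.nii.gz`).
#' @param spacing optional per-axis spacing stored in NIfTI output.
#' @return `path`, invisibly.
#' @export
save_mask <- function(mask, path, spacing = NULL) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("`mask` must be a logical array")
  fmt <- guess_format(path)
  d <- length(dim(mask))
  if (fmt %in% c("png", "tiff") && d != 2L)
    stop("PNG/TIFF masks must be 2D; use NIfTI for volumes")
  switch(fmt,
    png = png::writePNG(array(as.numeric(mask), dim(mask)), path),
    tiff = tiff::writeTIFF(array(as.numeric(mask), dim(mask)), path),
    nifti = {
      a <- array(as.integer(mask), dim(mask))
      img <- RNifti::asNifti(a)
      if (!is.null(spacing)) RNifti::pixdim(img) <- spacing
      RNifti::writeNifti(img, path)
    },
    stop("unsupported mask format: ", fmt))
  invisible(path)
}

#' Read a binary mask
#'
#' Counterpart of [save_mask()]: nonzero pixels become `TRUE`.
#'
#' @param path mask file path.
#' @return Logical array.
#' @export
load_mask <- function(path) {
  img <- load_image(path)
  img$data > 0.5 * max(img$data, 1e-12)
}
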