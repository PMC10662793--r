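#' Intensity image container
#'
#' A thin container for 2D images and 3D volumes of real-valued
#' intensities, carrying per-axis physical spacing.  All functions in the
#' package address pixels/voxels by 1-based array indices in the storage
#' order of `data` (for arrays built by this package that is
#' `(row, column)` in 2D and `(row, column, slice)` in 3D).
#'
#' @param data numeric matrix (2D) or 3-way array (3D) of intensities.
#' @param spacing numeric vector of per-axis physical sizes, one entry
#'   per array dimension (arbitrary units; default 1 per axis).
#'
#' @return An object of class `intensity_image` with elements `data`,
#'   `spacing` and `dims` (2 or 3).
#' @seealso [normalize_intensity()], [load_image()]
#' @examples
#' img <- intensity_image(matrix(runif(64), 8, 8))
#' img$dims
#' @export
intensity_image <- function(data, spacing = NULL) {
  if (is.null(dim(data))) stop("`data` must be a matrix or 3D array")
  dm <- dim(data)
  if (!length(dm) %in% c(2L, 3L))
    stop("`data` must have rank 2 or 3, got rank ", length(dm))
  if (!is.numeric(data)) stop("`data` must be numeric")
  spacing <- spacing %||% rep(1, length(dm))
  if (length(spacing) != length(dm) || any(!is.finite(spacing)) ||
      any(spacing <= 0))
    stop("`spacing` must be one positive finite value per axis")
  structure(list(data = data, spacing = as.numeric(spacing),
                 dims = length(dm)),
            class = "intensity_image")
}

#' Coerce to an intensity image
#'
#' @param x an `intensity_image`, matrix or 3D array.
#' @param spacing optional per-axis spacing (ignored when `x` already is
#'   an `intensity_image`).
#' @return An `intensity_image`.
#' @export
as_intensity_image <- function(x, spacing = NULL) {
  if (inherits(x, "intensity_image")) return(x)
  intensity_image(x, spacing)
}

#' @export
dim.intensity_image <- function(x) dim(x$data)

#' @export
print.intensity_image <- function(x, ...) {
  rng <- suppressWarnings(range(x$data, finite = TRUE))
  cat(sprintf("<intensity_image> %dD, %s, spacing %s, range [%.4g, %.4g]\n",
              x$dims, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              rng[1], rng[2]))
  invisible(x)
}

#' Min-max normalization of image intensities
#'
#' Linearly maps intensities to `[0, 1]`.  A constant image maps to all
#' zeros: it carries no structure, and the alternative (division by a
#' zero range) is undefined.
#'
#' @param img an [intensity_image()] (or coercible array).
#' @return An `intensity_image` whose data span `[0, 1]` (all zeros for
#'   constant input).  Idempotent on images already spanning `[0, 1]`.
#' @examples
#' normalize_intensity(matrix(c(10, 20, 30, 10), 2, 2))$data
#' @export
normalize_intensity <- function(img) {
  img <- as_intensity_image(img)
  if (any(!is.finite(img$data)))
    stop("image contains NaN/Inf intensities; cannot normalize")
  lo <- min(img$data); hi <- max(img$data)
  img$data <- if (hi > lo) (img$data - lo) / (hi - lo) else
    array(0, dim(img$data))
  img
}

## Internal: validate a binary mask against an image/array shape.
assert_mask <- function(mask, dm, what = "mask") {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop(what, " must be a logical array")
  if (!identical(dim(mask), as.integer(dm)) &&
      !identical(as.integer(dim(mask)), as.integer(dm)))
    stop(what, " shape (", paste(dim(mask), collapse = "x"),
         ") does not match image shape (", paste(dm, collapse = "x"), ")")
  invisible(TRUE)
}

## Internal: validate a point (1-based array index) against a shape.
assert_point <- function(point, dm, what = "point") {
  if (length(point) != length(dm) || any(!is.finite(point)))
    stop(what, " must have one finite coordinate per image axis")
  p <- as.integer(round(point))
  if (any(p < 1L) || any(p > dm))
    stop(what, " c(", paste(point, collapse = ","),
         ") is outside the image (dims ", paste(dm, collapse = "x"), ")")
  p
}
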