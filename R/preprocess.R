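#' Contrast augmentation (quantile stretch)
#'
#' The `imadjust` analogue: intensities at or below the `low_frac`
#' quantile map to 0, at or above the `high_frac` quantile map to 1,
#' linear in between.  For volumes the quantiles are taken over the
#' whole volume (an `imadjust3d`), so slices stay mutually consistent.
#' Defaults saturate 1% of the data at each tail, the MATLAB default.
#'
#' Besides boosting tumour/parenchyma contrast this clips small bright
#' vessel dots toward the white end, which is why it is applied before
#' growth; it can be disabled in the pipeline configuration.
#'
#' @param img an [intensity_image()] (or array) of normalized values.
#' @param low_frac,high_frac saturation quantiles, `0 <= low < high <= 1`.
#' @return The stretched `intensity_image`.  A constant image is
#'   returned unchanged with a warning.
#' @export
augment_contrast <- function(img, low_frac = 0.01, high_frac = 0.99) {
  img <- as_intensity_image(img)
  if (!(low_frac >= 0 && low_frac < high_frac && high_frac <= 1))
    stop("need 0 <= low_frac < high_frac <= 1")
  q <- stats::quantile(img$data, c(low_frac, high_frac), names = FALSE)
  if (q[2] <= q[1]) {
    warning("constant (or degenerate) image: contrast left unchanged")
    return(img)
  }
  y <- (img$data - q[1]) / (q[2] - q[1])
  y[y < 0] <- 0
  y[y > 1] <- 1
  img$data <- y
  img
}

#' Lung-field mask from a chest image
#'
#' Appoints the lung area so that growth can be confined to it (the
#' juxtapleural case: a tumour attached to the chest wall would
#' otherwise let growth leak into the wall).  Procedure: (1) global Otsu
#' split into dark (air-like) and bright (body); (2) dark components
#' connected to the image border are background air and are discarded;
#' (3) remaining dark components of at least `min_component_frac` of the
#' image area are kept as lungs (smaller dark specks are noise);
#' (4) morphological closing (disk/ball of `closing_radius`) followed by
#' hole filling, so bright tumours and vessels enclosed by lung are part
#' of the mask.  The pre-closing mask is always a subset of the result.
#'
#' @param img normalized [intensity_image()] (or array).
#' @param min_component_frac minimum component size as a fraction of the
#'   image area; default 0.005.
#' @param closing_radius radius (pixels) of the closing element; default
#'   5.  The closing must seal the pleural contact of a juxtapleural
#'   tumour so the subsequent hole filling keeps it inside the lung
#'   mask, so the radius should be at least half the expected contact
#'   width.
#' @return An object of class `lung_mask`: `mask` (logical array),
#'   `component_count` (number of retained lung components) and
#'   `otsu_level`.  When no interior dark component survives the mask is
#'   empty and a warning is raised; the caller decides whether to
#'   proceed unconstrained.
#' @export
segment_lung_mask <- function(img, min_component_frac = 0.005,
                              closing_radius = 5) {
  img <- as_intensity_image(img)
  A <- img$data
  dm <- dim(A)
  level <- otsu_level(A)
  dark <- A < level
  out <- array(FALSE, dm)
  count <- 0L
  if (any(dark)) {
    ## face connectivity: dark regions are background-like, and the
    ## complementary connectivity prevents diagonal leaks through thin
    ## bright shells (the thorax wall in 3D)
    labels <- label_components(dark, connectivity = "face")
    border_labs <- unique(labels[border_mask(dm) & dark])
    sizes <- tabulate(labels)
    keep <- setdiff(which(sizes >= min_component_frac * prod(dm)), border_labs)
    keep <- keep[keep > 0L]
    count <- length(keep)
    if (count > 0L) {
      pre <- array(labels %in% keep, dm)
      out <- pre | fill_holes(binary_close(pre, closing_radius) | pre)
    }
  }
  if (!any(out))
    warning("no interior lung-like component found: lung mask is empty")
  structure(list(mask = out, component_count = count, otsu_level = level),
            class = "lung_mask")
}

#' @export
print.lung_mask <- function(x, ...) {
  cat(sprintf("<lung_mask> %d component(s), %d pixel(s), Otsu level %.4g\n",
              x$component_count, sum(x$mask), x$otsu_level))
  invisible(x)
}
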