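#' Colour-intensity centre of a masked region
#'
#' The intensity-weighted centroid of the mask: per axis,
#' `sum(I(p) * coord(p)) / sum(I(p))` — the centre of mass with colour
#' intensity playing the role of mass.
#'
#' @param img an [intensity_image()] (or array).
#' @param mask non-empty logical array of the same shape with positive
#'   total intensity.
#' @return Real-valued point (1-based array-index space), one value per
#'   axis.
#' @export
intensity_center <- function(img, mask) {
  img <- as_intensity_image(img)
  dm <- dim(img$data)
  assert_mask(mask, dm)
  lin <- which(mask)
  if (length(lin) == 0L) stop("intensity_center: empty mask")
  w <- img$data[lin]
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    stop("intensity_center: total intensity must be positive")
  coords <- index_to_coords(lin, dm)
  as.numeric(colSums(coords * w) / tot)
}

#' Local target region around a primary tumour
#'
#' The disk (2D) or sphere (3D) on which the automatic local threshold
#' is computed: centred at the colour-intensity centre of the primary
#' tumour, with radius equal to the maximum distance from that centre to
#' any primary boundary point plus a safety `margin` (default 5 pixels).
#' The primary mask is always contained in the region.
#'
#' @param img an [intensity_image()] (or array).
#' @param primary a `growth_result` (or a logical mask) for the primary
#'   tumour.
#' @param margin pixels added to the maximum boundary distance.
#' @return An object of class `local_target_region`: `center` (real
#'   point), `radius`, and `mask` (the disk/sphere clipped to the
#'   image).
#' @export
build_target_region <- function(img, primary, margin = 5) {
  img <- as_intensity_image(img)
  dm <- dim(img$data)
  if (inherits(primary, "growth_result")) {
    pmask <- primary$mask
    boundary <- primary$boundary
  } else {
    assert_mask(primary, dm, "primary")
    pmask <- primary
    boundary <- index_to_coords(mask_boundary_indices(pmask), dm)
  }
  if (!any(pmask)) stop("build_target_region: empty primary mask")
  center <- intensity_center(img, pmask)
  maxdist <- if (nrow(boundary) > 0L)
    max(dist_from_point(boundary, center)) else 0
  radius <- maxdist + margin
  coords <- index_to_coords(seq_len(prod(dm)), dm)
  mask <- array(dist_from_point(coords, center) <= radius, dm)
  structure(list(center = center, radius = radius, mask = mask),
            class = "local_target_region")
}

#' @export
print.local_target_region <- function(x, ...) {
  cat(sprintf("<local_target_region> center (%s), radius %.2f, %d pixel(s)\n",
              paste(sprintf("%.2f", x$center), collapse = ", "),
              x$radius, sum(x$mask)))
  invisible(x)
}

#' Regrow with an automatically determined local threshold
#'
#' Recomputes the working threshold as `fraction` times the Otsu
#' grey-level of the intensities inside the local target region built
#' around the primary tumour, then re-runs [grow_region()] from the
#' original user seed with that threshold and all other constraints
#' unchanged.  Because the target area excludes most of the scene, its
#' histogram peak shifts toward the bright end and the local grey
#' threshold typically exceeds the global one, widening the acceptance
#' band around the tumour.
#'
#' The local Otsu is computed on the full disk/sphere (the lung mask is
#' not applied there), but the lung mask still constrains the regrowth
#' itself.
#'
#' @param img an [intensity_image()] (or array).
#' @param seed the original user seed point.
#' @param primary `growth_result` of the primary growth pass.
#' @param config [growth_config()] of the primary pass; its threshold is
#'   replaced.
#' @param fraction fraction of the local grey level; default 0.20.
#' @param margin target-region margin in pixels; default 5.
#' @return A `growth_result` with attributes `local_level` (the local
#'   Otsu grey level), `local_threshold` and `target_region`.
#' @export
regrow_with_local_threshold <- function(img, seed, primary, config,
                                        fraction = 0.20, margin = 5) {
  img <- as_intensity_image(img)
  region <- build_target_region(img, primary, margin = margin)
  level <- otsu_level(img$data[region$mask])
  thr <- compute_threshold(level, fraction)
  cfg <- config
  cfg$threshold <- thr
  res <- grow_region(img, seed, cfg)
  attr(res, "local_level") <- level
  attr(res, "local_threshold") <- thr
  attr(res, "target_region") <- region
  res
}
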