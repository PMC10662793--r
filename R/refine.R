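#' Edge-refinement rule constants
#'
#' A candidate subsection grown at the tumour edge is joined to the main
#' area only when (a) its median intensity exceeds the primary tumour's
#' median minus `median_sigma` standard deviations (it is tumour-like,
#' not lung field) and (b) its size relative to the primary tumour is
#' below `area_ratio_max` (it is a rim correction, not a second
#' segmentation).  Growth at the candidate points uses a narrower
#' working threshold, `threshold_fraction` of the local grey level
#' (10% instead of the 20% used for the main growth; one figure caption
#' of the source method says 5%, so the value is configurable).
#'
#' @param median_sigma standard-deviation multiplier; default 3.
#' @param area_ratio_max maximum subsection/primary size ratio;
#'   default 0.2.
#' @param threshold_fraction fraction of the local grey level, in
#'   `(0, 0.2]`; default 0.10.
#' @return A list of class `refine_rule`.
#' @export
refine_rule <- function(median_sigma = 3, area_ratio_max = 0.2,
                        threshold_fraction = 0.10) {
  if (area_ratio_max <= 0) stop("`area_ratio_max` must be positive")
  if (threshold_fraction <= 0 || threshold_fraction > 0.2)
    stop("`threshold_fraction` must be in (0, 0.2]")
  structure(list(median_sigma = median_sigma,
                 area_ratio_max = area_ratio_max,
                 threshold_fraction = threshold_fraction),
            class = "refine_rule")
}

#' Standard refinement directions
#'
#' 2D: the eight angles 0, 45, ..., 315 degrees.  3D: the 16 directions
#' from azimuth {-180, -90, 0, 90} crossed with elevation
#' {-90, -45, 0, 45} degrees (some of which coincide at the poles).
#'
#' @param d image rank (2 or 3).
#' @return Matrix of unit direction vectors (one per row, in array-axis
#'   order).
#' @export
refine_directions <- function(d) {
  if (d == 2L) {
    ang <- seq(0, 315, by = 45) * pi / 180
    cbind(sin(ang), cos(ang))           # (row, col): 0 deg along +column
  } else {
    grid <- expand.grid(az = c(-180, -90, 0, 90) * pi / 180,
                        el = c(-90, -45, 0, 45) * pi / 180)
    cbind(cos(grid$el) * sin(grid$az),  # row
          cos(grid$el) * cos(grid$az),  # col
          sin(grid$el))                 # slice
  }
}

#' Ray-marched edge points
#'
#' For each direction, marches from `center` along the ray, records the
#' last mask pixel met (the boundary intersection), then continues
#' `offset` pixels outward.  Points are rounded and clipped to the image
#' bounds.  A direction along which no mask pixel is found is skipped
#' with a warning.
#'
#' @param mask logical array; `center` must lie inside it.
#' @param center ray origin (real point).
#' @param directions matrix of unit direction vectors (one per row), or
#'   a numeric vector of angles in degrees for 2D (0 degrees along the
#'   +column axis, measured toward +row).
#' @param offset pixels to continue beyond the boundary (outward probes
#'   under-segmented tissue); default 3.  With `offset = 0` the returned
#'   points are boundary pixels of the mask.
#' @return Matrix of integer points, one per surviving direction, with
#'   attribute `"boundary_distance"` (distance from `center` to the
#'   boundary hit).
#' @export
ray_edge_points <- function(mask, center, directions = NULL, offset = 3) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("`mask` must be a logical array")
  dm <- dim(mask); d <- length(dm)
  cpx <- assert_point(center, dm, "center")
  if (!mask[coords_to_index(matrix(cpx, 1L), dm)])
    stop("`center` must lie inside the mask")
  if (is.null(directions)) directions <- refine_directions(d)
  if (is.null(dim(directions)) && d == 2L) {
    ang <- directions * pi / 180
    directions <- cbind(sin(ang), cos(ang))
  }
  directions <- directions / sqrt(rowSums(directions^2))
  tmax <- sqrt(sum(dm^2))
  ts <- seq(0, tmax, by = 0.5)
  pts <- NULL; bdist <- numeric(0)
  for (i in seq_len(nrow(directions))) {
    u <- directions[i, ]
    pos <- outer(ts, u) + matrix(center, length(ts), d, byrow = TRUE)
    px <- round(pos)
    inb <- rep(TRUE, nrow(px))
    for (a in seq_len(d)) inb <- inb & px[, a] >= 1 & px[, a] <= dm[a]
    hit <- inb
    hit[inb] <- mask[coords_to_index(px[inb, , drop = FALSE], dm)]
    if (!any(hit)) {
      warning(sprintf("no mask pixel along direction %d; skipped", i))
      next
    }
    t_last <- ts[max(which(hit))]
    p <- round(center + (t_last + offset) * u)
    p <- pmin(pmax(p, 1), dm)
    pts <- rbind(pts, as.integer(p))
    bdist <- c(bdist, t_last)
  }
  attr(pts, "boundary_distance") <- bdist
  pts
}

#' Rule-gated edge refinement
#'
#' Grows a candidate subsection from each supplied point with a narrow
#' working threshold (`rule$threshold_fraction` of the local grey level
#' of the target region around the primary tumour) and joins it to the
#' primary mask only when both [refine_rule()] conditions hold.
#' Refinement only ever adds pixels: the primary mask is a subset of the
#' result.
#'
#' @param img an [intensity_image()] (or array) of pipeline-current
#'   intensities.
#' @param primary_mask non-empty logical array: the mask to refine.
#' @param points matrix of candidate points (one per row), e.g. from
#'   [ray_edge_points()].
#' @param rule a [refine_rule()].
#' @param config [growth_config()] carrying the lung mask / radius
#'   constraints; its threshold is replaced by the refinement threshold.
#' @param margin target-region margin passed to
#'   [build_target_region()]; default 5.
#' @return The refined logical mask, with attribute `"diagnostics"`: a
#'   data frame with one row per candidate (point, subsection size,
#'   median, size ratio, whether joined, and the reason when not).
#' @export
refine_edges <- function(img, primary_mask, points, rule = refine_rule(),
                         config = growth_config(threshold = 0), margin = 5) {
  img <- as_intensity_image(img)
  dm <- dim(img$data)
  assert_mask(primary_mask, dm, "primary_mask")
  if (!any(primary_mask)) stop("refine_edges: empty primary mask")
  region <- build_target_region(img, primary_mask, margin = margin)
  level <- otsu_level(img$data[region$mask])
  thr <- compute_threshold(level, rule$threshold_fraction)
  cfg <- config
  cfg$threshold <- thr
  vals_p <- img$data[primary_mask]
  med_p <- stats::median(vals_p)
  sd_p <- stats::sd(vals_p)
  if (is.na(sd_p)) sd_p <- 0
  n_p <- sum(primary_mask)

  out <- primary_mask
  diags <- NULL
  if (is.null(points)) points <- matrix(numeric(0), 0L, length(dm))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1L)
  for (i in seq_len(nrow(points))) {
    p <- points[i, ]
    row <- data.frame(t(p))
    names(row) <- paste0("axis", seq_len(ncol(points)))
    sub <- tryCatch(grow_region(img, p, cfg), error = function(e) e)
    if (inherits(sub, "error")) {
      diags <- rbind(diags, cbind(row, size = 0L, median = NA_real_,
                                  ratio = NA_real_, joined = FALSE,
                                  reason = conditionMessage(sub)))
      next
    }
    size <- sum(sub$mask)
    med_s <- stats::median(img$data[sub$mask])
    ratio <- size / n_p
    ok_med <- med_s > med_p - rule$median_sigma * sd_p
    ok_ratio <- ratio < rule$area_ratio_max
    joined <- ok_med && ok_ratio
    if (joined) out <- out | sub$mask
    reason <- if (joined) "" else if (!ok_med) "median below rule" else
      "size ratio too large"
    diags <- rbind(diags, cbind(row, size = size, median = med_s,
                                ratio = ratio, joined = joined,
                                reason = reason))
  }
  attr(out, "diagnostics") <- diags
  attr(out, "local_threshold") <- thr
  out
}
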