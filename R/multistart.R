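#' Geometric centre of a mask
#'
#' Per-axis mean of member coordinates (pixel count as denominator).
#'
#' @param mask non-empty logical array.
#' @return Real-valued point, one value per axis.
#' @export
geometric_center <- function(mask) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("`mask` must be a logical array")
  lin <- which(mask)
  if (length(lin) == 0L) stop("geometric_center: empty mask")
  as.numeric(colMeans(index_to_coords(lin, dim(mask))))
}

#' Sector-sampled start points
#'
#' Partitions the mask into the 4 quadrants (2D) or 8 octants (3D) of
#' the coordinate frame anchored at `center` and draws one mask point
#' uniformly at random from each non-empty sector.  Sectors without mask
#' points simply contribute nothing.
#'
#' @param mask non-empty logical array (the current tumour mask).
#' @param center the sector origin (normally [geometric_center()] of the
#'   mask).
#' @param rng_seed integer seed making the draw reproducible.
#' @return An object of class `sector_sample`: `center`,
#'   `sector_count` (4 or 8) and `points` (matrix, one sampled point per
#'   non-empty sector).
#' @export
sample_sector_points <- function(mask, center = geometric_center(mask),
                                 rng_seed = 1L) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop("`mask` must be a logical array")
  dm <- dim(mask); d <- length(dm)
  lin <- which(mask)
  if (length(lin) == 0L) stop("sample_sector_points: empty mask")
  coords <- index_to_coords(lin, dm)
  ## sector id from the per-axis side of the centre (ties go low)
  sector <- rep(0L, nrow(coords))
  for (a in seq_len(d)) sector <- sector * 2L + (coords[, a] > center[a])
  pts <- with_seed(rng_seed, {
    do.call(rbind, lapply(split(seq_len(nrow(coords)), sector), function(i) {
      coords[i[sample.int(length(i), 1L)], , drop = FALSE]
    }))
  })
  structure(list(center = center, sector_count = 2L^d,
                 points = pts), class = "sector_sample")
}

#' Independent growth from several start points
#'
#' Runs the per-seed growth sequence (by default: braided growth with
#' the given configuration followed by an automatic local-threshold
#' regrowth) independently from each seed.  With the centre point plus
#' one point per sector this is 5 starts in 2D and 9 in 3D.  A seed
#' whose growth fails is dropped with a warning; at least one result is
#' required.
#'
#' @param img an [intensity_image()] (or array).
#' @param seeds matrix of seed points (one row each), or a vector for a
#'   single seed.
#' @param config [growth_config()] used by the default runner.
#' @param runner function `(img, seed, config) -> growth_result`
#'   implementing the per-seed pipeline; the default performs
#'   [grow_region()] then [regrow_with_local_threshold()].
#' @param autothresh_fraction,autothresh_margin parameters of the
#'   default runner's local-threshold pass.
#' @return List of `growth_result`, one per surviving seed.
#' @export
multi_start_growth <- function(img, seeds, config, runner = NULL,
                               autothresh_fraction = 0.20,
                               autothresh_margin = 5) {
  img <- as_intensity_image(img)
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1L)
  if (is.null(runner))
    runner <- function(img, seed, config) {
      g <- grow_region(img, seed, config)
      regrow_with_local_threshold(img, seed, g, config,
                                  fraction = autothresh_fraction,
                                  margin = autothresh_margin)
    }
  results <- list()
  for (i in seq_len(nrow(seeds))) {
    res <- tryCatch(runner(img, seeds[i, ], config), error = function(e) {
      warning(sprintf("growth from seed (%s) failed and was dropped: %s",
                      paste(seeds[i, ], collapse = ","), conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) results[[length(results) + 1L]] <- res
  }
  if (length(results) == 0L)
    stop("multi_start_growth: growth failed from every seed")
  results
}

#' Interpolate several tumour boundaries into one mask
#'
#' Combines the masks grown from different start points.  The default
#' (`"radial"`) is radial-mean shape averaging: for each direction from
#' `center`, every mask contributes the distance to its farthest mask
#' pixel along that ray, the interpolated radius is the mean of the
#' contributing radii, and the output is the filled region inside the
#' resulting (angle, radius) profile.  Directions no mask covers are
#' filled by circular interpolation along the profile.  `"majority"` is
#' a robust alternative for non-star-shaped tumours: a pixel is kept
#' when at least half of the masks contain it.
#'
#' @param masks list of logical arrays of identical shape.
#' @param center interpolation origin; default the geometric centre of
#'   the union of the masks.  Must lie inside at least one mask.
#' @param angular_bins number of angular bins (2D; default 360).  In 3D
#'   the direction grid is `angular_bins_3d` azimuth x elevation bins.
#' @param method `"radial"` or `"majority"`.
#' @param angular_bins_3d azimuth/elevation bin counts for volumes;
#'   default `c(64, 32)`.
#' @return Logical array: the interpolated mask.
#' @export
interpolate_boundaries <- function(masks, center = NULL, angular_bins = 360L,
                                   method = c("radial", "majority"),
                                   angular_bins_3d = c(64L, 32L)) {
  method <- match.arg(method)
  if (!is.list(masks) || length(masks) == 0L) stop("need at least one mask")
  dm <- dim(masks[[1L]])
  for (m in masks) assert_mask(m, dm)
  union <- Reduce(`|`, masks)
  if (!any(union)) stop("all masks are empty")
  if (is.null(center)) center <- geometric_center(union)
  center_px <- round(center)
  inside_any <- any(vapply(masks, function(m) {
    p <- pmin(pmax(center_px, 1), dm)
    m[coords_to_index(matrix(as.integer(p), 1L), dm)]
  }, logical(1L)))
  if (!inside_any) stop("interpolation center lies outside every mask")

  if (method == "majority") {
    k <- length(masks)
    counts <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    return(array(counts >= ceiling(k / 2), dm))
  }
  d <- length(dm)
  if (d == 2L) radial_mean_2d(masks, center, angular_bins, dm)
  else radial_mean_3d(masks, center, angular_bins_3d, dm)
}

radial_mean_2d <- function(masks, center, nbins, dm) {
  nbins <- as.integer(nbins)
  bin_of <- function(coords, nb) {
    ang <- atan2(coords[, 1L] - center[1L], coords[, 2L] - center[2L])
    pmin(floor((ang + pi) / (2 * pi) * nb) + 1L, nb)
  }
  prof <- matrix(NA_real_, length(masks), nbins)
  for (i in seq_along(masks)) {
    coords <- index_to_coords(which(masks[[i]]), dm)
    r <- dist_from_point(coords, center)
    ## bins no finer than the boundary pixel count, else interior pixels
    ## masquerade as the farthest point of their (pixel-free) direction
    nb <- min(nbins, max(16L, as.integer(ceiling(2 * pi * max(r)))))
    mx <- fill_circular(as.numeric(
      tapply(r, factor(bin_of(coords, nb), levels = seq_len(nb)), max)))
    ## resample this mask's profile onto the common grid
    prof[i, ] <- resample_circular(mx, nbins)
  }
  radius <- colMeans(prof, na.rm = TRUE)
  radius[is.nan(radius)] <- NA_real_
  radius <- fill_circular(radius)
  coords <- index_to_coords(seq_len(prod(dm)), dm)
  b <- bin_of(coords, nbins)
  r <- dist_from_point(coords, center)
  array(r <= radius[b] + 0.5, dm)
}

## Interpolate a circular profile of length n onto length m (bin centres).
resample_circular <- function(v, m) {
  n <- length(v)
  if (n == m) return(v)
  x <- (seq_len(n) - 0.5) / n
  xo <- (seq_len(m) - 0.5) / m
  stats::approx(c(x - 1, x, x + 1), rep(v, 3), xout = xo, rule = 2)$y
}

radial_mean_3d <- function(masks, center, bins, dm) {
  naz_t <- as.integer(bins[1L]); nel_t <- as.integer(bins[2L])
  bin_of <- function(coords, naz, nel) {
    dx <- coords[, 2L] - center[2L]
    dy <- coords[, 1L] - center[1L]
    dz <- coords[, 3L] - center[3L]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    az <- atan2(dy, dx)
    el <- ifelse(r > 0, asin(pmin(1, pmax(-1, dz / r))), 0)
    ib_az <- pmin(floor((az + pi) / (2 * pi) * naz) + 1L, naz)
    ib_el <- pmin(floor((el + pi / 2) / pi * nel) + 1L, nel)
    list(r = r, flat = (ib_el - 1L) * naz + ib_az)
  }
  prof <- matrix(NA_real_, length(masks), naz_t * nel_t)
  for (i in seq_along(masks)) {
    coords <- index_to_coords(which(masks[[i]]), dm)
    rmax <- max(dist_from_point(coords, center))
    ## direction grid no finer than the boundary voxel density
    naz <- min(naz_t, max(8L, as.integer(ceiling(2 * pi * rmax))))
    nel <- min(nel_t, max(4L, as.integer(ceiling(pi * rmax / 2))))
    b <- bin_of(coords, naz, nel)
    mx <- matrix(as.numeric(tapply(b$r, factor(b$flat,
                                               levels = seq_len(naz * nel)),
                                   max)), naz, nel)
    for (j in seq_len(nel)) mx[, j] <- fill_circular(mx[, j])
    mx <- fill_rings(mx)
    ## resample az circularly and el linearly onto the common grid
    tmp <- matrix(NA_real_, naz_t, nel)
    for (j in seq_len(nel)) tmp[, j] <- resample_circular(mx[, j], naz_t)
    out <- matrix(NA_real_, naz_t, nel_t)
    xo <- (seq_len(nel_t) - 0.5) / nel_t
    x <- (seq_len(nel) - 0.5) / nel
    for (a in seq_len(naz_t))
      out[a, ] <- stats::approx(x, tmp[a, ], xout = xo, rule = 2)$y
    prof[i, ] <- as.numeric(out)
  }
  radius <- colMeans(prof, na.rm = TRUE)
  radius[is.nan(radius)] <- NA_real_
  rmat <- matrix(radius, naz_t, nel_t)
  for (j in seq_len(nel_t)) rmat[, j] <- fill_circular(rmat[, j])
  rmat <- fill_rings(rmat)
  radius <- as.numeric(rmat)
  coords <- index_to_coords(seq_len(prod(dm)), dm)
  b <- bin_of(coords, naz_t, nel_t)
  array(b$r <= radius[b$flat] + 0.5, dm)
}

## Replace all-NA elevation rings by the nearest informative ring.
fill_rings <- function(rmat) {
  ring_ok <- which(colSums(!is.na(rmat)) > 0L)
  for (j in seq_len(ncol(rmat))) {
    if (all(is.na(rmat[, j])) && length(ring_ok) > 0L) {
      nearest <- ring_ok[which.min(abs(ring_ok - j))]
      rmat[, j] <- rmat[, nearest]
    }
  }
  rmat
}

## Linear interpolation over NA runs on a circular profile.
fill_circular <- function(v) {
  if (!anyNA(v)) return(v)
  ok <- which(!is.na(v))
  if (length(ok) == 0L) return(v)
  n <- length(v)
  x <- c(ok, ok[1L] + n)
  y <- c(v[ok], v[ok[1L]])
  miss <- which(is.na(v))
  pos <- ifelse(miss < ok[1L], miss + n, miss)
  v[miss] <- stats::approx(x, y, xout = pos, rule = 2)$y
  v
}
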