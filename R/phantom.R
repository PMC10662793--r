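#' Chest-phantom specification
#'
#' Parametric description of a synthetic chest CT slice (2D) or volume
#' (3D): a bright thorax ellipse/ellipsoid on a dark background, two
#' dark lung fields, a brighter tumour blob, small bright vessel dots,
#' Gaussian edge smoothing and additive Gaussian noise.  Ground-truth
#' tumour and lung masks are exact by construction, so every stage of
#' the pipeline is testable without external data.
#'
#' Default intensities follow the appearance of a lung-windowed chest CT
#' after min-max normalization: near-black air background (0.05), dark
#' lung parenchyma (0.15), bright chest wall (0.85), a solid mass as
#' bright as the wall (0.85) whose enhancement tapers linearly by
#' `tumor_taper` toward its margin, and near-white vessels (0.90).
#' Noise (sd 0.02) and a sigma = 1 px Gaussian blur give soft edges —
#' the hard case the margin-tracking and edge-refinement stages exist
#' for.
#'
#' A `wall_attached` tumour is placed nearly tangent to the lateral lung
#' border and joined to the chest wall by a short pleural bridge at wall
#' intensity, the juxtapleural geometry that makes unmasked growth leak
#' into the wall.  `fragmented` adds a second detached blob (the
#' single-seed limitation case); `lobe` adds a protruding lobe dim
#' enough (`lobe_intensity`, default `tumor_intensity - 0.175`) to fall
#' below the main acceptance band while passing the edge-refinement
#' median rule.
#'
#' @param shape image dimensions, length 2 or 3; default `c(128, 128)`.
#' @param thorax_intensity,lung_intensity,tumor_intensity,
#'   vessel_intensity,background_intensity mean intensities in `[0, 1]`;
#'   the tumour must be brighter than the lung field.
#' @param noise_sd standard deviation of i.i.d. additive Gaussian noise.
#' @param smooth_sigma Gaussian blur sigma in pixels (0 disables).
#' @param tumor_center tumour centre (array indices) or `NULL` to place
#'   it automatically inside the right lung (or near-tangent to its
#'   lateral border when `wall_attached`).
#' @param tumor_radius tumour radius in pixels.
#' @param tumor_taper linear intensity drop from tumour core to margin
#'   (0 for a uniformly enhancing mass).
#' @param wall_attached,fragmented,lobe feature flags (see above).
#' @param lobe_intensity intensity of the protruding lobe (`NULL` for
#'   the default `tumor_intensity - 0.175`).
#' @param vessel_count,vessel_radius bright vessel dots inside the
#'   lungs.
#' @param rng_seed integer seed; identical specs give bit-identical
#'   phantoms.
#' @return A list of class `phantom_spec`.
#' @seealso [generate_phantom()], [phantom_suite()]
#' @export
phantom_spec <- function(shape = c(128L, 128L),
                         thorax_intensity = 0.85,
                         lung_intensity = 0.15,
                         tumor_intensity = 0.85,
                         vessel_intensity = 0.90,
                         background_intensity = 0.05,
                         noise_sd = 0.02,
                         smooth_sigma = 1,
                         tumor_center = NULL,
                         tumor_radius = 12,
                         tumor_taper = 0.12,
                         wall_attached = FALSE,
                         fragmented = FALSE,
                         lobe = FALSE,
                         lobe_intensity = NULL,
                         vessel_count = 6L,
                         vessel_radius = 1,
                         rng_seed = 1L) {
  if (!length(shape) %in% c(2L, 3L)) stop("`shape` must have length 2 or 3")
  if (tumor_intensity - tumor_taper <= lung_intensity)
    stop("tumour (even at its tapered margin) must be brighter than the lung field")
  spec <- list(shape = as.integer(shape),
               thorax_intensity = thorax_intensity,
               lung_intensity = lung_intensity,
               tumor_intensity = tumor_intensity,
               vessel_intensity = vessel_intensity,
               background_intensity = background_intensity,
               noise_sd = noise_sd, smooth_sigma = smooth_sigma,
               tumor_center = tumor_center, tumor_radius = tumor_radius,
               tumor_taper = tumor_taper,
               wall_attached = isTRUE(wall_attached),
               fragmented = isTRUE(fragmented), lobe = isTRUE(lobe),
               lobe_intensity = lobe_intensity,
               vessel_count = as.integer(vessel_count),
               vessel_radius = vessel_radius,
               rng_seed = as.integer(rng_seed))
  class(spec) <- "phantom_spec"
  spec
}

## Geometry of the phantom anatomy in fractional image coordinates.
phantom_geometry <- function(shape) {
  d <- length(shape)
  ctr <- (shape + 1) / 2
  if (d == 2L) {
    list(thorax_c = ctr, thorax_s = c(0.40, 0.45) * shape,
         lung_s = c(0.28, 0.16) * shape,
         lung_c = list(ctr + c(0, -0.22 * shape[2]),
                       ctr + c(0, 0.22 * shape[2])))
  } else {
    list(thorax_c = ctr, thorax_s = c(0.40, 0.45, 0.48) * shape,
         lung_s = c(0.28, 0.16, 0.30) * shape,
         lung_c = list(ctr + c(0, -0.22 * shape[2], 0),
                       ctr + c(0, 0.22 * shape[2], 0)))
  }
}

inside_ellipse <- function(coords, center, semi) {
  s <- 0
  for (a in seq_len(ncol(coords)))
    s <- s + ((coords[, a] - center[a]) / semi[a])^2
  s <= 1
}

#' Generate a chest phantom with ground truth
#'
#' Renders the scene described by a [phantom_spec()]: anatomy painted at
#' the spec intensities, optional Gaussian smoothing of the whole scene,
#' then i.i.d. Gaussian noise clipped to `[0, 1]`.  The truth masks are
#' the exact pre-smoothing geometry.
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom`: `image` (an [intensity_image()]),
#'   `tumor_truth` and `lung_truth` (logical arrays), `tumor_center`
#'   (the realized centre) and `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(64, 64), tumor_radius = 7))
#' range(ph$image$data)
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  dm <- spec$shape; d <- length(dm)
  geo <- phantom_geometry(dm)
  coords <- index_to_coords(seq_len(prod(dm)), dm)

  thorax <- array(inside_ellipse(coords, geo$thorax_c, geo$thorax_s), dm)
  lung1 <- array(inside_ellipse(coords, geo$lung_c[[1L]], geo$lung_s), dm)
  lung2 <- array(inside_ellipse(coords, geo$lung_c[[2L]], geo$lung_s), dm)
  lungs <- lung1 | lung2

  ## tumour placement (in the second = right-of-array lung by default)
  lc <- geo$lung_c[[2L]]
  r <- spec$tumor_radius
  if (!is.null(spec$tumor_center)) {
    tc <- as.numeric(spec$tumor_center)
  } else if (spec$wall_attached) {
    ## near-tangent laterally: 3 px of parenchyma remain between tumour
    ## and pleura, crossed by the explicit bridge below
    tc <- lc; tc[2L] <- lc[2L] + (geo$lung_s[2L] - r - 3)
  } else {
    tc <- lc
  }
  tumor <- array(dist_from_point(coords, tc) <= r, dm)
  lobe_mask <- NULL
  if (spec$lobe) {
    off <- rep(0, d); off[1L] <- -1.15 * r
    lobe_mask <- array(dist_from_point(coords, tc + off) <= 0.4 * r, dm)
    tumor <- tumor | lobe_mask
  }
  if (spec$fragmented) {
    off <- rep(0, d); off[1L] <- 2 * r
    tumor <- tumor | array(dist_from_point(coords, tc + off) <= 0.5 * r, dm)
  }
  if (!spec$wall_attached && any(tumor & !lungs))
    stop("tumour extends outside the lung field; adjust the spec")

  img <- array(spec$background_intensity, dm)
  img[thorax] <- spec$thorax_intensity
  img[lungs] <- spec$lung_intensity

  ## vessels: small bright dots in the lung field, away from the tumour
  if (spec$vessel_count > 0L) {
    lin_l <- which(lungs & !tumor)
    cl <- index_to_coords(lin_l, dm)
    far <- dist_from_point(cl, tc) > r + 4 * spec$vessel_radius + 2
    lin_l <- lin_l[far]
    picks <- with_seed(substream_seed(spec$rng_seed, "vessels"),
                       sample(lin_l, min(spec$vessel_count, length(lin_l))))
    for (p in picks) {
      pc <- index_to_coords(p, dm)
      dot <- array(dist_from_point(coords, as.numeric(pc)) <=
                     spec$vessel_radius, dm)
      img[dot & lungs & !tumor] <- spec$vessel_intensity
    }
  }

  ## radial taper: solid core at tumor_intensity dimming toward the
  ## margin, the typical enhancement profile of a solid mass (and the
  ## reason the comparison value must track the braid outward)
  tlin <- which(tumor)
  tdist <- dist_from_point(index_to_coords(tlin, dm), tc)
  img[tlin] <- spec$tumor_intensity -
    spec$tumor_taper * pmin(1, tdist / max(r, 1))
  if (!is.null(lobe_mask))
    img[lobe_mask] <- spec$lobe_intensity %||% (spec$tumor_intensity - 0.175)
  if (spec$wall_attached) {
    ## pleural bridge: a short band at wall intensity joining the tumour
    ## edge to the chest wall along the lateral direction
    u <- rep(0, d); u[2L] <- 1
    half_w <- 2
    dd <- coords - matrix(tc, nrow(coords), d, byrow = TRUE)
    along <- as.numeric(dd %*% u)
    perp2 <- rowSums(dd^2) - along^2
    bridge <- array(along >= r - 1 & along <= r + 8 &
                      perp2 <= half_w^2, dm)
    img[bridge & !tumor] <- spec$thorax_intensity
  }

  if (spec$smooth_sigma > 0) img <- gauss_smooth(img, spec$smooth_sigma)
  if (spec$noise_sd > 0) {
    img <- img + with_seed(substream_seed(spec$rng_seed, "noise"),
                           array(stats::rnorm(prod(dm), 0, spec$noise_sd), dm))
  }
  img <- pmin(1, pmax(0, img))
  dim(img) <- dm

  structure(list(image = intensity_image(img),
                 tumor_truth = tumor,
                 lung_truth = lungs | tumor,
                 tumor_center = tc,
                 spec = spec),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %s, tumour %d px at (%s)%s\n",
              paste(dim(x$image$data), collapse = "x"),
              sum(x$tumor_truth),
              paste(sprintf("%.1f", x$tumor_center), collapse = ", "),
              if (x$spec$wall_attached) ", wall-attached" else ""))
  invisible(x)
}

## Separable Gaussian blur with edge replication.
gauss_smooth <- function(a, sigma) {
  dm <- dim(a)
  rad <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-rad:rad, sd = sigma)
  k <- k / sum(k)
  for (axis in seq_along(dm)) {
    out <- array(0, dm)
    for (j in seq_along(k)) {
      off <- rep(0L, length(dm)); off[axis] <- j - rad - 1L
      out <- out + k[j] * shift_clamped(a, off)
    }
    a <- out
  }
  a
}

## Shift with edge replication (clamped indices) along one axis.
shift_clamped <- function(a, off) {
  dm <- dim(a)
  idx <- vector("list", length(dm))
  for (kk in seq_along(dm))
    idx[[kk]] <- pmin(pmax(seq_len(dm[kk]) - off[kk], 1L), dm[kk])
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

#' Reference phantom evaluation suite
#'
#' Twenty 2D phantoms spanning tumour contrast (tumour intensity 0.60 to
#' 0.75 against a 0.15 lung field), tumour size (radius 10 to 16 px) and
#' pleural attachment (four wall-attached cases at intensity 0.80, close
#' to the 0.85 chest wall — the configuration in which unconstrained
#' growth leaks into the wall).  Used to compare the baseline and
#' enhanced algorithms under controlled conditions.
#'
#' @param rng_seed master seed; each phantom draws its own substream.
#' @return List of 20 [phantom_spec()] objects.
#' @export
phantom_suite <- function(rng_seed = 1L) {
  specs <- list()
  radii <- c(12, 14, 16, 18)
  intens <- c(0.75, 0.80, 0.85, 0.90)
  i <- 0L
  for (ti in intens) for (r in radii) {
    i <- i + 1L
    specs[[i]] <- phantom_spec(tumor_intensity = ti, tumor_radius = r,
                               rng_seed = substream_seed(rng_seed,
                                                         paste0("iso", i)))
  }
  for (r in radii) {
    i <- i + 1L
    specs[[i]] <- phantom_spec(tumor_intensity = 0.85, tumor_radius = r,
                               tumor_taper = 0, wall_attached = TRUE,
                               rng_seed = substream_seed(rng_seed,
                                                         paste0("wall", i)))
  }
  specs
}
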