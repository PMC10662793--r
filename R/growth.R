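#' Otsu threshold of a collection of intensities
#'
#' Computes the Otsu grey-level threshold (MATLAB's `graythresh`
#' analogue) on a 256-bin histogram over `[0, 1]`: the cut that
#' maximizes the between-class variance.  Unlike whole-image Otsu
#' helpers, this accepts an arbitrary collection of values, which is what
#' the local target-area thresholding needs.
#'
#' Ties are resolved by averaging all maximizing cut positions.  A
#' constant collection returns that single value (the class split is
#' degenerate and growth then degenerates gracefully).
#'
#' @param values numeric vector (or array) of intensities in `[0, 1]`.
#' @return The threshold, a value in `[0, 1]`.
#' @examples
#' otsu_level(c(rep(0.1, 50), rep(0.9, 50)))
#' @export
otsu_level <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("otsu_level: empty collection")
  if (min(values) < 0 || max(values) > 1)
    stop("otsu_level: values must lie in [0, 1]")
  if (max(values) == min(values)) return(values[1])
  nb <- 256L
  bin <- pmin(floor(values * nb) + 1L, nb)     # bin i covers [(i-1)/nb, i/nb)
  counts <- tabulate(bin, nbins = nb)
  p <- counts / sum(counts)
  centers <- (seq_len(nb) - 0.5) / nb
  w0 <- cumsum(p)[-nb]
  mu0 <- cumsum(p * centers)[-nb]
  mu_t <- sum(p * centers)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, nb - 1L)
  sigma_b[valid] <- (mu_t * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which(sigma_b == max(sigma_b))
  mean(k) / nb
}

#' Working threshold from a grey-level threshold
#'
#' The acceptance half-width used during growth is a fixed fraction
#' (default 20%) of the Otsu grey-level threshold of the relevant region
#' — the whole image for the global pass, the local target area for the
#' automatic pass.
#'
#' @param grey_level the Otsu grey-level threshold (see [otsu_level()]),
#'   or a numeric vector of region intensities from which it is computed.
#' @param fraction fraction of the grey level, in `(0, 1]`; default 0.2.
#' @return `fraction * grey_level`.
#' @examples
#' compute_threshold(0.48, 0.20)  # 0.096
#' compute_threshold(0.64, 0.20)  # 0.128
#' @export
compute_threshold <- function(grey_level, fraction = 0.20) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be a single value in (0, 1]")
  if (length(grey_level) > 1L) grey_level <- otsu_level(grey_level)
  fraction * grey_level
}

#' Comparison-quantity update
#'
#' The reference intensity against which candidate pixels are compared.
#' The baseline algorithm keeps it fixed at the seed value; the enhanced
#' algorithm re-computes it after each braid level as the mean or (more
#' robustly) the median of all points accepted so far.
#'
#' @param tumor_values intensities of all points accepted so far.
#' @param mode `"mean"` or `"median"`.
#' @return The updated comparison value.
#' @export
update_comparison_value <- function(tumor_values, mode = c("mean", "median")) {
  mode <- match.arg(mode)
  tumor_values <- as.numeric(tumor_values)
  if (length(tumor_values) == 0L)
    stop("update_comparison_value: empty collection")
  if (mode == "mean") mean(tumor_values) else stats::median(tumor_values)
}

#' Growth configuration
#'
#' Tunables of the braided region-growth kernel.
#'
#' @param threshold acceptance half-width in normalized intensity units
#'   (a candidate is accepted when its intensity is within `threshold`
#'   of the current comparison value).
#' @param compare_update `"none"` (comparison value fixed at the seed
#'   intensity), `"mean"` or `"median"` (re-computed after each braid
#'   level over all accepted points).
#' @param max_radius maximum expected tumour radius in pixels, or `NULL`
#'   for unconstrained growth.
#' @param radius_factor growth is confined to
#'   `radius_factor * max_radius` around the seed; default 2 ("no more
#'   than twice the maximum radius").  Set to 1 for a strict circle of
#'   the declared radius.
#' @param lung_mask optional logical array (or [segment_lung_mask()]
#'   result): growth never leaves it.
#' @param use_spacing if `TRUE`, radial distances are measured in
#'   physical units using the image spacing; default `FALSE` (pixel
#'   units, as the distances quoted by the method are).
#' @return A list of class `growth_config`.
#' @export
growth_config <- function(threshold, compare_update = c("none", "mean", "median"),
                          max_radius = NULL, radius_factor = 2,
                          lung_mask = NULL, use_spacing = FALSE) {
  compare_update <- match.arg(compare_update)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0)
    stop("`threshold` must be a single non-negative number")
  if (!is.null(max_radius) && (!is.numeric(max_radius) || max_radius <= 0))
    stop("`max_radius` must be NULL or > 0")
  if (inherits(lung_mask, "lung_mask")) lung_mask <- lung_mask$mask
  structure(list(threshold = threshold, compare_update = compare_update,
                 max_radius = max_radius, radius_factor = radius_factor,
                 lung_mask = lung_mask, use_spacing = isTRUE(use_spacing)),
            class = "growth_config")
}

#' Braided (level-synchronous) region growth
#'
#' Grows a connected region from a seed point by breadth-first "braids":
#' level 0 is the seed; at each level every not-yet-examined neighbour
#' (8-neighbourhood in 2D, 26 in 3D) of the current braid is accepted
#' iff (a) its intensity is within `config$threshold` of the current
#' comparison value, (b) it lies inside `config$lung_mask` when one is
#' set, and (c) its Euclidean distance from the seed does not exceed
#' `radius_factor * max_radius` when a radius is set.  After each
#' complete level the comparison value is updated per
#' `config$compare_update` over all accepted points; because the update
#' happens once per level, the result is independent of visit order
#' within a level.  Growth terminates when a level accepts nothing.
#'
#' @param img an [intensity_image()] (or array), normally normalized to
#'   `[0, 1]`.
#' @param seed integer point (1-based array index); must lie inside the
#'   image and inside `lung_mask` when one is set.
#' @param config a [growth_config()].
#' @return An object of class `growth_result`: `mask` (logical array),
#'   `boundary` (matrix of accepted points having at least one neighbour
#'   outside the mask), `trace_frontier` (newly accepted count per
#'   level; final entry 0), `trace_cumulative` (non-decreasing running
#'   total), `final_compare_value`, `seed`, and the `config` used.
#' @examples
#' a <- matrix(0.1, 7, 7); a[3:5, 3:5] <- 0.9
#' g <- grow_region(a, c(4, 4), growth_config(threshold = 0.15))
#' sum(g$mask)   # the 3x3 block
#' @export
grow_region <- function(img, seed, config) {
  img <- as_intensity_image(img)
  if (!inherits(config, "growth_config")) stop("`config` must be a growth_config")
  A <- img$data
  dm <- dim(A)
  d <- length(dm)
  seed <- assert_point(seed, dm, "seed")
  seed_lin <- coords_to_index(matrix(seed, 1L), dm)
  if (!is.finite(A[seed_lin])) stop("seed intensity is not finite")
  lung <- config$lung_mask
  if (!is.null(lung)) {
    assert_mask(lung, dm, "lung_mask")
    if (!lung[seed_lin]) stop("seed lies outside the lung mask")
  }
  spacing <- if (config$use_spacing) img$spacing else NULL
  rmax <- if (!is.null(config$max_radius))
    config$radius_factor * config$max_radius else Inf
  offs <- neighbor_offsets(d)

  visited <- array(FALSE, dm)      # examined at least once (accepted or not)
  accepted <- array(FALSE, dm)
  visited[seed_lin] <- TRUE
  accepted[seed_lin] <- TRUE
  vals <- A[seed_lin]
  compare <- vals
  trace_frontier <- 1L
  frontier <- matrix(seed, 1L)

  repeat {
    cand <- expand_coords(frontier, offs, dm)
    n_new <- 0L
    if (nrow(cand) > 0L) {
      lin <- coords_to_index(cand, dm)
      fresh <- !visited[lin]
      cand <- cand[fresh, , drop = FALSE]
      lin <- lin[fresh]
    }
    if (nrow(cand) > 0L) {
      visited[lin] <- TRUE
      ok <- abs(A[lin] - compare) <= config$threshold & is.finite(A[lin])
      if (!is.null(lung)) ok <- ok & lung[lin]
      if (is.finite(rmax)) ok <- ok & dist_from_point(cand, seed, spacing) <= rmax
      lin <- lin[ok]
      n_new <- length(lin)
      if (n_new > 0L) {
        accepted[lin] <- TRUE
        vals <- c(vals, A[lin])
        frontier <- cand[ok, , drop = FALSE]
      }
    }
    trace_frontier <- c(trace_frontier, n_new)
    if (n_new == 0L) break
    if (config$compare_update != "none")
      compare <- update_comparison_value(vals, config$compare_update)
  }

  boundary <- index_to_coords(mask_boundary_indices(accepted), dm)
  structure(list(mask = accepted,
                 boundary = boundary,
                 trace_frontier = trace_frontier,
                 trace_cumulative = cumsum(trace_frontier),
                 final_compare_value = compare,
                 seed = seed,
                 config = config),
            class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat(sprintf(paste0("<growth_result> %d point(s) in %d level(s), ",
                     "%d boundary point(s)\n  threshold %.4g, compare_update %s, ",
                     "final compare value %.4g\n"),
              sum(x$mask), length(x$trace_frontier), nrow(x$boundary),
              x$config$threshold, x$config$compare_update,
              x$final_compare_value))
  invisible(x)
}

#' @export
as.data.frame.growth_result <- function(x, ...) {
  data.frame(level = seq_along(x$trace_frontier) - 1L,
             frontier = x$trace_frontier,
             cumulative = x$trace_cumulative)
}

#' Plot growth traces
#'
#' Draws the per-level frontier size (pixels newly braided at each
#' level) and the cumulative tumour count.  The frontier curve rises,
#' fluctuates with the roughness of the outer edge, and sinks to zero at
#' termination; the cumulative curve is always non-decreasing.
#'
#' @param x a `growth_result`.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.growth_result <- function(x, ...) {
  tr <- as.data.frame(x)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(tr$level, tr$frontier, type = "b", pch = 20,
                 xlab = "braid level", ylab = "frontier size", ...)
  graphics::plot(tr$level, tr$cumulative, type = "s",
                 xlab = "braid level", ylab = "cumulative tumour count", ...)
  invisible(x)
}

#' Export a growth trace as CSV
#'
#' Writes the per-level `(level, frontier, cumulative)` table.
#'
#' @param result a `growth_result` (or a segmentation report, whose
#'   first-pass growth trace is used).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(result, path) {
  if (inherits(result, "eag_segmentation")) result <- result$growth
  if (!inherits(result, "growth_result"))
    stop("`result` must be a growth_result or eag_segmentation")
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}
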