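#' Pipeline configuration
#'
#' All tunables of the enhanced segmentation pipeline, grouped by stage.
#' Any subset may be overridden; unknown keys are rejected.  Every stage
#' is individually toggleable via `stages`, which reproduces the
#' method's ablations (with/without contrast augmentation, one vs
#' several start points, with/without edge improvement, ...).
#'
#' @param ... named overrides, e.g. `growth = list(compare_update =
#'   "mean")` or `stages = list(refine = FALSE)`.
#' @return Nested list of class `eag_config`:
#' \describe{
#'   \item{contrast}{`low_frac`, `high_frac` saturation quantiles.}
#'   \item{lung}{`min_component_frac`, `closing_radius`, `strict`
#'     (error, rather than warn, on an empty lung mask).}
#'   \item{growth}{`threshold_fraction` (default 0.20), `radius_factor`
#'     (default 2), `compare_update` (default `"median"`),
#'     `use_spacing`.}
#'   \item{autothresh}{`fraction` (default 0.20), `margin` (default 5).}
#'   \item{multistart}{`interpolation` (`"radial"` or `"majority"`),
#'     `angular_bins`, `angular_bins_3d`.}
#'   \item{refine}{`threshold_fraction` (default 0.10), `median_sigma`,
#'     `area_ratio_max`, `offset` (default 3).}
#'   \item{stages}{logical toggles `contrast`, `lung_mask`,
#'     `autothresh`, `multistart`, `refine`.}
#' }
#' @export
eag_config <- function(...) {
  cfg <- list(
    contrast = list(low_frac = 0.01, high_frac = 0.99),
    lung = list(min_component_frac = 0.005, closing_radius = 5,
                strict = FALSE),
    growth = list(threshold_fraction = 0.20, radius_factor = 2,
                  compare_update = "median", use_spacing = FALSE),
    autothresh = list(fraction = 0.20, margin = 5),
    multistart = list(interpolation = "radial", angular_bins = 360L,
                      angular_bins_3d = c(64L, 32L)),
    refine = list(threshold_fraction = 0.10, median_sigma = 3,
                  area_ratio_max = 0.2, offset = 3),
    stages = list(contrast = TRUE, lung_mask = TRUE, autothresh = TRUE,
                  multistart = TRUE, refine = TRUE))
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  for (nm in names(over)) {
    if (!nm %in% names(cfg)) stop("unknown config group: ", nm)
    for (k in names(over[[nm]])) {
      if (!k %in% names(cfg[[nm]]))
        stop("unknown config key: ", nm, ".", k)
      cfg[[nm]][[k]] <- over[[nm]][[k]]
    }
  }
  class(cfg) <- "eag_config"
  cfg
}

new_report <- function(kind, final_mask, primary_mask, lung_mask, growth,
                       per_seed_results, stage_log, rng_seed, seed, config,
                       image) {
  structure(list(kind = kind, final_mask = final_mask,
                 primary_mask = primary_mask, lung_mask = lung_mask,
                 growth = growth, per_seed_results = per_seed_results,
                 stage_log = stage_log, rng_seed = rng_seed, seed = seed,
                 config = config, image = image),
            class = "eag_segmentation")
}

log_stage <- function(log, name, ...) {
  entry <- list(...)
  entry$stage <- name
  log[[name]] <- entry
  log
}

#' Baseline single-start segmentation
#'
#' The primary area-growth algorithm: normalize, optionally confine to
#' the lung field, then a single braided growth from the user seed with
#' the global working threshold (20% of the whole-image Otsu grey level)
#' and a comparison value fixed at the seed intensity.  This is the
#' baseline the enhanced pipeline is measured against.
#'
#' @param img an [intensity_image()] (or array); raw intensities are
#'   min-max normalized first.
#' @param seed user start point (1-based array index).
#' @param config an [eag_config()]; only the lung and growth groups are
#'   used here.
#' @param lung_masking confine growth to the segmented lung field;
#'   default `FALSE` (the baseline as commonly run; enabling it is the
#'   wall-attachment ablation).
#' @param max_radius optional maximum expected tumour radius (pixels).
#' @return An `eag_segmentation` report (see [eag_segment()]).
#' @export
primary_segment <- function(img, seed, config = eag_config(),
                            lung_masking = FALSE, max_radius = NULL) {
  img <- normalize_intensity(as_intensity_image(img))
  dm <- dim(img$data)
  seed <- assert_point(seed, dm, "seed")
  log <- list()
  log <- log_stage(log, "normalize", range = range(img$data))
  lung <- NULL
  if (isTRUE(lung_masking)) {
    lm <- segment_lung_mask(img, config$lung$min_component_frac,
                            config$lung$closing_radius)
    lung <- if (any(lm$mask)) lm$mask else NULL
    log <- log_stage(log, "lung_mask", components = lm$component_count,
                     pixels = sum(lm$mask))
  }
  level <- otsu_level(img$data)
  thr <- compute_threshold(level, config$growth$threshold_fraction)
  log <- log_stage(log, "global_threshold", grey_level = level,
                   threshold = thr)
  g <- grow_region(img, seed,
                   growth_config(threshold = thr, compare_update = "none",
                                 max_radius = max_radius,
                                 radius_factor = config$growth$radius_factor,
                                 lung_mask = lung,
                                 use_spacing = config$growth$use_spacing))
  log <- log_stage(log, "growth", pixels = sum(g$mask),
                   levels = length(g$trace_frontier),
                   final_compare_value = g$final_compare_value)
  new_report("primary", g$mask, g$mask, lung, g, list(g), log,
             rng_seed = NA_integer_, seed = seed, config = config,
             image = img)
}

#' Enhanced area-growth segmentation
#'
#' Runs the full enhanced pipeline on a 2D slice or 3D volume:
#' contrast augmentation; lung-field masking; the radius constraint
#' (growth confined to `radius_factor * max_radius` of the seed); the
#' global 20% working threshold; braided growth with the comparison
#' value updated per level to the median of accepted points; automatic
#' local thresholding on the target region around the primary tumour
#' with regrowth from the seed; multi-start growth (geometric centre
#' plus one random start per quadrant/octant — 5 starts in 2D, 9 in 3D)
#' with radial interpolation of the resulting boundaries; and finally
#' edge refinement from ray-marched candidates (8 directions + centre
#' in 2D, 16 directions in 3D, offset 3 px outward) grown at a 10%
#' threshold and joined under the median/size rules.
#'
#' Identical inputs and `rng_seed` give bit-identical masks; each
#' stochastic stage draws from its own named substream, so toggling one
#' stage does not shift another's draws.
#'
#' @param img an [intensity_image()] (or array); raw intensities are
#'   min-max normalized first.
#' @param seed user start point inside the tumour (1-based array index).
#' @param max_radius maximum expected tumour radius in pixels (> 0).
#' @param config an [eag_config()].
#' @param rng_seed master seed for the stochastic stages.
#' @return An object of class `eag_segmentation`: `final_mask`,
#'   `primary_mask` (the single-start braided-growth mask), `lung_mask`,
#'   `growth` (first-pass `growth_result`), `per_seed_results`,
#'   `stage_log` (one ordered entry per enabled stage), `rng_seed`,
#'   `seed`, `config` and the preprocessed `image`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(96, 96), tumor_radius = 9))
#' seg <- eag_segment(ph$image, round(ph$tumor_center), max_radius = 10)
#' dice(seg$final_mask, ph$tumor_truth)
#' @export
eag_segment <- function(img, seed, max_radius, config = eag_config(),
                        rng_seed = 1L) {
  if (missing(max_radius) || is.null(max_radius) || max_radius <= 0)
    stop("`max_radius` must be a positive tumour radius in pixels")
  img <- normalize_intensity(as_intensity_image(img))
  dm <- dim(img$data)
  d <- length(dm)
  seed <- assert_point(seed, dm, "seed")
  st <- config$stages
  log <- list()

  ## (i) contrast augmentation
  if (isTRUE(st$contrast)) {
    img <- augment_contrast(img, config$contrast$low_frac,
                            config$contrast$high_frac)
    log <- log_stage(log, "contrast", low_frac = config$contrast$low_frac,
                     high_frac = config$contrast$high_frac)
  }

  ## (ii) lung area + seed value
  lung <- NULL
  if (isTRUE(st$lung_mask)) {
    lm <- segment_lung_mask(img, config$lung$min_component_frac,
                            config$lung$closing_radius)
    if (!any(lm$mask)) {
      if (isTRUE(config$lung$strict))
        stop("empty lung mask (strict mode)")
      warning("empty lung mask: proceeding without the lung constraint")
    } else if (!lm$mask[coords_to_index(matrix(seed, 1L), dm)]) {
      stop("seed lies outside the segmented lung field")
    } else {
      lung <- lm$mask
    }
    log <- log_stage(log, "lung_mask", components = lm$component_count,
                     pixels = sum(lm$mask))
  }
  seedval <- img$data[coords_to_index(matrix(seed, 1L), dm)]
  log <- log_stage(log, "seed", point = seed, value = seedval)

  ## (iii) radius constraint; (iv) global threshold
  log <- log_stage(log, "radius", max_radius = max_radius,
                   factor = config$growth$radius_factor)
  level <- otsu_level(img$data)
  thr <- compute_threshold(level, config$growth$threshold_fraction)
  log <- log_stage(log, "global_threshold", grey_level = level,
                   threshold = thr)

  gc0 <- growth_config(threshold = thr,
                       compare_update = config$growth$compare_update,
                       max_radius = max_radius,
                       radius_factor = config$growth$radius_factor,
                       lung_mask = lung,
                       use_spacing = config$growth$use_spacing)

  ## (v-vii) braided growth with per-level median update
  g1 <- grow_region(img, seed, gc0)
  log <- log_stage(log, "growth", pixels = sum(g1$mask),
                   levels = length(g1$trace_frontier),
                   final_compare_value = g1$final_compare_value)

  ## (viii-ix) automatic local threshold + regrowth
  g2 <- g1
  if (isTRUE(st$autothresh)) {
    g2 <- regrow_with_local_threshold(img, seed, g1, gc0,
                                      fraction = config$autothresh$fraction,
                                      margin = config$autothresh$margin)
    log <- log_stage(log, "autothresh",
                     local_grey_level = attr(g2, "local_level"),
                     threshold = attr(g2, "local_threshold"),
                     target_radius = attr(g2, "target_region")$radius,
                     pixels = sum(g2$mask))
  }

  ## (x) multi-start growth + boundary interpolation
  mask_x <- g2$mask
  per_seed <- list(g2)
  if (isTRUE(st$multistart)) {
    center <- geometric_center(g2$mask)
    samp <- sample_sector_points(g2$mask, center,
                                 rng_seed = substream_seed(rng_seed,
                                                           "multistart"))
    seeds <- rbind(round(center), samp$points)
    per_seed <- multi_start_growth(img, seeds, gc0,
                                   autothresh_fraction = config$autothresh$fraction,
                                   autothresh_margin = config$autothresh$margin)
    masks <- lapply(per_seed, `[[`, "mask")
    mask_x <- interpolate_boundaries(
      masks, center = geometric_center(Reduce(`|`, masks)),
      angular_bins = config$multistart$angular_bins,
      method = config$multistart$interpolation,
      angular_bins_3d = config$multistart$angular_bins_3d)
    if (!is.null(lung)) mask_x <- mask_x & lung
    log <- log_stage(log, "multistart", n_seeds = nrow(seeds),
                     n_results = length(per_seed),
                     interpolation = config$multistart$interpolation,
                     pixels = sum(mask_x))
  }

  ## (xi) edge refinement
  final <- mask_x
  if (isTRUE(st$refine)) {
    ctr <- round(geometric_center(mask_x))
    pts <- suppressWarnings(
      ray_edge_points(mask_x, ctr, refine_directions(d),
                      offset = config$refine$offset))
    if (d == 2L) pts <- rbind(pts, ctr)    # centre is the 9th candidate
    rule <- refine_rule(median_sigma = config$refine$median_sigma,
                        area_ratio_max = config$refine$area_ratio_max,
                        threshold_fraction = config$refine$threshold_fraction)
    final <- refine_edges(img, mask_x, pts, rule, gc0,
                          margin = config$autothresh$margin)
    diags <- attr(final, "diagnostics")
    log <- log_stage(log, "refine", candidates = nrow(pts),
                     joined = sum(diags$joined), pixels = sum(final),
                     diagnostics = diags)
  }

  new_report("eag", final, g1$mask, lung, g1, per_seed, log,
             rng_seed = as.integer(rng_seed), seed = seed, config = config,
             image = img)
}

#' @export
print.eag_segmentation <- function(x, ...) {
  cat(sprintf("<eag_segmentation> %s algorithm, image %s\n",
              x$kind, paste(dim(x$image$data), collapse = "x")))
  cat(sprintf("  seed (%s); final mask %d pixel(s)\n",
              paste(x$seed, collapse = ", "), sum(x$final_mask)))
  cat("  stages:", paste(names(x$stage_log), collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.eag_segmentation <- function(object, ...) {
  cat(sprintf("%s segmentation of a %s image\n",
              if (object$kind == "eag") "Enhanced area-growth" else
                "Primary area-growth",
              paste(dim(object$image$data), collapse = "x")))
  cat(sprintf("seed (%s), rng seed %s\n", paste(object$seed, collapse = ", "),
              object$rng_seed))
  for (e in object$stage_log) {
    vals <- e[setdiff(names(e), c("stage", "diagnostics", "point"))]
    vals <- vals[vapply(vals, function(v) is.numeric(v) &&
                          length(v) <= 3, logical(1))]
    cat(sprintf("  %-16s %s\n", e$stage,
                paste(sprintf("%s=%s", names(vals),
                              vapply(vals, function(v)
                                paste(signif(v, 5), collapse = ","),
                                character(1))),
                      collapse = "  ")))
  }
  cat(sprintf("final mask: %d pixel(s); primary pass: %d pixel(s)\n",
              sum(object$final_mask), sum(object$primary_mask)))
  invisible(object)
}

#' Plot a segmentation report
#'
#' Shows the (preprocessed) image with the final mask outline; for a
#' volume, the slice through the seed is shown.
#'
#' @param x an `eag_segmentation`.
#' @param ... passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.eag_segmentation <- function(x, ...) {
  A <- x$image$data
  M <- x$final_mask
  if (length(dim(A)) == 3L) {
    s <- x$seed[3L]
    A <- A[, , s]; M <- M[, , s]
  }
  graphics::image(t(A)[, nrow(A):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(A) / ncol(A), ...)
  graphics::contour(t(M * 1)[, nrow(M):1], levels = 0.5, add = TRUE,
                    drawlabels = FALSE, col = "red", lwd = 2)
  invisible(x)
}

#' Serialize a stage log to JSON
#'
#' @param report an `eag_segmentation`.
#' @param path optional output file; when `NULL` the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
stage_log_json <- function(report, path = NULL) {
  log <- lapply(report$stage_log, function(e) {
    if (!is.null(e$diagnostics)) e$diagnostics <- as.data.frame(e$diagnostics)
    e
  })
  js <- jsonlite::toJSON(log, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
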