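test_that("ray marching finds boundary intersections plus an outward offset", {
  co <- eagseg:::index_to_coords(seq_len(41 * 41), c(41, 41))
  disk <- array(eagseg:::dist_from_point(co, c(21, 21)) <= 10, c(41, 41))

  p0 <- ray_edge_points(disk, c(21, 21), directions = 0, offset = 3)
  expect_equal(nrow(p0), 1)
  expect_equal(eagseg:::dist_from_point(p0, c(21, 21)), 13, tolerance = 1)

  p8 <- ray_edge_points(disk, c(21, 21), offset = 3)
  expect_equal(nrow(p8), 8)
  d8 <- eagseg:::dist_from_point(p8, c(21, 21))
  expect_true(all(abs(d8 - 13) <= 1.3))

  ## offset 0 returns boundary pixels of the mask
  pb <- ray_edge_points(disk, c(21, 21), offset = 0)
  bl <- eagseg:::mask_boundary_indices(disk)
  near_boundary <- eagseg:::binary_dilate(
    array(seq_len(41 * 41) %in% bl, c(41, 41)), 1)
  expect_true(all(near_boundary[eagseg:::coords_to_index(pb, c(41, 41))]))

  expect_error(ray_edge_points(disk, c(1, 1)), "inside the mask")
})

test_that("3D refinement directions number 16 from the azimuth/elevation grid", {
  dirs <- refine_directions(3)
  expect_equal(nrow(dirs), 16)
  expect_equal(rowSums(dirs^2), rep(1, 16), tolerance = 1e-12)
  dirs2 <- refine_directions(2)
  expect_equal(nrow(dirs2), 8)
})

test_that("refinement never removes pixels and honours the join rules", {
  ph <- generate_phantom(phantom_spec(rng_seed = 14))
  img <- augment_contrast(normalize_intensity(ph$image))
  thr <- compute_threshold(otsu_level(img$data), 0.2)
  cfg <- growth_config(thr, "median", max_radius = 12,
                       lung_mask = segment_lung_mask(img)$mask)
  g <- grow_region(img, round(ph$tumor_center), cfg)
  pts <- ray_edge_points(g$mask, round(geometric_center(g$mask)), offset = 3)
  out <- refine_edges(img, g$mask, pts, refine_rule(), cfg)
  expect_true(all(out[g$mask]))
  di <- attr(out, "diagnostics")
  expect_equal(nrow(di), nrow(pts))
  vals_p <- img$data[g$mask]
  floor_med <- stats::median(vals_p) - 3 * stats::sd(vals_p)
  for (i in which(di$joined)) {
    expect_gt(di$median[i], floor_med)
    expect_lt(di$ratio[i], 0.2)
  }
})

test_that("a candidate darker than the median rule is rejected", {
  ## bright tumour beside a dark pocket: the pocket subsection fails the
  ## median test and the output equals the primary mask exactly
  a <- matrix(0.1, 41, 41)
  co <- eagseg:::index_to_coords(seq_len(41 * 41), c(41, 41))
  tum <- eagseg:::dist_from_point(co, c(21, 21)) <= 8
  a[tum] <- 0.9
  primary <- array(tum, c(41, 41))
  dark_pt <- matrix(c(21, 33), 1)       # in the dark field
  out <- refine_edges(a, primary, dark_pt,
                      refine_rule(median_sigma = 3, area_ratio_max = 0.9),
                      growth_config(threshold = 0))
  di <- attr(out, "diagnostics")
  expect_false(di$joined[1])
  expect_match(di$reason[1], "median")
  expect_identical(array(out, dim(out)), primary)
})

test_that("an oversized candidate is rejected by the area-ratio rule", {
  set.seed(6)
  a <- matrix(0.85 + rnorm(31 * 31, 0, 0.01), 31, 31)  # bright scene
  primary <- array(FALSE, c(31, 31)); primary[14:18, 14:18] <- TRUE
  pt <- matrix(c(5, 5), 1)
  out <- refine_edges(a, primary, pt, refine_rule(),
                      growth_config(threshold = 0))
  di <- attr(out, "diagnostics")
  expect_false(di$joined[1])
  expect_match(di$reason[1], "ratio")
  expect_gt(di$ratio[1], 0.2)
})

test_that("refinement recovers a dimmer protruding lobe the main pass missed", {
  ## low-noise construction: the lobe sits below the main acceptance
  ## band but inside the median-rule window, so only the narrow-band
  ## edge growth can claim it
  ph <- generate_phantom(phantom_spec(lobe = TRUE, noise_sd = 0.01,
                                      rng_seed = 17))
  img <- augment_contrast(normalize_intensity(ph$image))
  thr <- compute_threshold(otsu_level(img$data), 0.2)
  cfg <- growth_config(thr, "median", max_radius = 12,
                       lung_mask = segment_lung_mask(img)$mask)
  seed <- round(ph$tumor_center)
  g <- grow_region(img, seed, cfg)
  rg <- regrow_with_local_threshold(img, seed, g, cfg)
  d_before <- dice(rg$mask, ph$tumor_truth)
  pts <- ray_edge_points(rg$mask, round(geometric_center(rg$mask)),
                         offset = 3)
  out <- refine_edges(img, rg$mask, pts, refine_rule(), cfg)
  d_after <- dice(array(out, dim(out)), ph$tumor_truth)
  di <- attr(out, "diagnostics")
  expect_gte(sum(di$joined), 1)
  expect_gt(d_after, d_before)
})
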