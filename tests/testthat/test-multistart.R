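make_disk <- function(n, center, radius) {
  co <- eagseg:::index_to_coords(seq_len(n * n), c(n, n))
  array(eagseg:::dist_from_point(co, center) <= radius, c(n, n))
}

test_that("geometric centre is the coordinate mean", {
  m <- array(FALSE, c(8, 8)); m[3, 4] <- TRUE
  expect_equal(geometric_center(m), c(3, 4))

  sq <- array(FALSE, c(9, 9)); sq[1:5, 1:5] <- TRUE
  expect_equal(geometric_center(sq), c(3, 3))

  l <- array(FALSE, c(4, 4)); l[1, 1] <- l[1, 2] <- l[2, 1] <- TRUE
  expect_equal(geometric_center(l), c(4 / 3, 4 / 3))
  expect_error(geometric_center(array(FALSE, c(3, 3))), "empty")
})

test_that("sector sampling draws one in-mask point per non-empty sector", {
  disk <- make_disk(41, c(21, 21), 12)
  s <- sample_sector_points(disk, rng_seed = 4)
  expect_equal(s$sector_count, 4)
  expect_equal(nrow(s$points), 4)
  for (i in seq_len(4)) {
    p <- s$points[i, ]
    expect_true(disk[p[1], p[2]])
  }
  ## each point in its own quadrant (strictly classified by centre side)
  side <- (s$points[, 1] > s$center[1]) * 2 + (s$points[, 2] > s$center[2])
  expect_equal(length(unique(side)), 4)

  ## reproducibility
  s2 <- sample_sector_points(disk, rng_seed = 4)
  expect_identical(s$points, s2$points)
  s3 <- sample_sector_points(disk, rng_seed = 5)
  expect_false(identical(s$points, s3$points))

  ## degenerate single-pixel mask
  px <- array(FALSE, c(5, 5)); px[2, 2] <- TRUE
  sp <- sample_sector_points(px, rng_seed = 1)
  expect_lte(nrow(sp$points), 1)
  expect_equal(sp$points[1, ], c(2L, 2L), ignore_attr = TRUE)

  ## 3D: octants
  ball <- array(FALSE, c(15, 15, 15))
  co <- eagseg:::index_to_coords(seq_len(15^3), c(15, 15, 15))
  ball[eagseg:::dist_from_point(co, c(8, 8, 8)) <= 5] <- TRUE
  s3d <- sample_sector_points(ball, rng_seed = 2)
  expect_equal(s3d$sector_count, 8)
  expect_equal(nrow(s3d$points), 8)
})

test_that("multi-start growth reduces to single-start and stays seed-contained", {
  ph <- generate_phantom(phantom_spec(rng_seed = 9))
  img <- augment_contrast(normalize_intensity(ph$image))
  thr <- compute_threshold(otsu_level(img$data), 0.2)
  cfg <- growth_config(thr, "median", max_radius = 12)
  seed <- round(ph$tumor_center)

  one <- multi_start_growth(img, seed, cfg)
  expect_length(one, 1)
  solo <- regrow_with_local_threshold(img, seed,
                                      grow_region(img, seed, cfg), cfg)
  expect_identical(one[[1]]$mask, solo$mask)

  g <- grow_region(img, seed, cfg)
  samp <- sample_sector_points(g$mask, rng_seed = 6)
  seeds <- rbind(round(geometric_center(g$mask)), samp$points)
  res <- multi_start_growth(img, seeds, cfg)
  expect_length(res, nrow(seeds))
  for (i in seq_along(res)) {
    p <- seeds[i, ]
    expect_true(res[[i]]$mask[p[1], p[2]])
  }
  ## homogeneous tumour: all starts give near-identical masks
  for (i in 1:(length(res) - 1)) for (j in (i + 1):length(res))
    expect_gte(dice(res[[i]]$mask, res[[j]]$mask), 0.95)
})

test_that("radial interpolation averages boundaries and respects identity", {
  disk4 <- make_disk(41, c(21, 21), 4)
  disk8 <- make_disk(41, c(21, 21), 8)
  disk6 <- make_disk(41, c(21, 21), 6)

  ## identical masks in -> that mask out (up to resampling)
  out_same <- interpolate_boundaries(list(disk8, disk8, disk8))
  expect_gte(dice(out_same, disk8), 0.98)
  out_single <- interpolate_boundaries(list(disk8))
  expect_gte(dice(out_single, disk8), 0.98)

  ## two concentric disks -> radial mean, a disk of radius ~6
  out_mean <- interpolate_boundaries(list(disk4, disk8), center = c(21, 21))
  expect_gte(dice(out_mean, disk6), 0.9)

  ## contained in the union dilated by one pixel
  union_d <- eagseg:::binary_dilate(disk4 | disk8, 1.5)
  expect_true(all(union_d[out_mean]))

  expect_error(interpolate_boundaries(list(disk4), center = c(1, 1)),
               "center")
})

test_that("majority-vote interpolation keeps pixels in at least half the masks", {
  d1 <- make_disk(31, c(16, 16), 6)
  d2 <- make_disk(31, c(16, 18), 6)
  d3 <- make_disk(31, c(16, 14), 6)
  out <- interpolate_boundaries(list(d1, d2, d3), method = "majority")
  counts <- d1 + d2 + d3
  expect_identical(out, array(counts >= 2, dim(d1)))
})

test_that("3D radial interpolation reproduces a ball", {
  ball <- array(FALSE, c(33, 33, 33))
  co <- eagseg:::index_to_coords(seq_len(33^3), c(33, 33, 33))
  d <- eagseg:::dist_from_point(co, c(17, 17, 17))
  ball[d <= 9] <- TRUE
  out <- interpolate_boundaries(list(ball, ball))
  expect_gte(dice(out, ball), 0.95)
})
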