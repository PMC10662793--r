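test_that("intensity centre is the intensity-weighted centroid", {
  ## two pixels in one row, intensities 1 and 3 two columns apart:
  ## centre = (1*c1 + 3*c3) / 4 along the column axis
  a <- matrix(0, 3, 3)
  a[1, 1] <- 1; a[1, 3] <- 3
  m <- a > 0
  expect_equal(intensity_center(a / 3, m), c(1, (1 * 1 + 3 * 3) / 4))

  ## uniform disk: geometric centroid by symmetry
  co <- eagseg:::index_to_coords(seq_len(41 * 41), c(41, 41))
  disk <- array(eagseg:::dist_from_point(co, c(21, 21)) <= 10, c(41, 41))
  u <- array(0.6, c(41, 41))
  expect_equal(intensity_center(u, disk), c(21, 21))

  single <- array(FALSE, c(5, 5)); single[2, 4] <- TRUE
  expect_equal(intensity_center(u[1:5, 1:5, drop = FALSE], single), c(2, 4))

  expect_error(intensity_center(u, array(FALSE, c(41, 41))), "empty")
  z <- array(0, c(5, 5)); zm <- array(TRUE, c(5, 5))
  expect_error(intensity_center(z, zm), "positive")
})

test_that("target region is max boundary distance plus margin", {
  ## disk-shaped tumour radius 10: region = disk radius 15, tumour inside
  co <- eagseg:::index_to_coords(seq_len(61 * 61), c(61, 61))
  disk <- array(eagseg:::dist_from_point(co, c(31, 31)) <= 10, c(61, 61))
  img <- array(0.1, c(61, 61)); img[disk] <- 0.9
  reg <- build_target_region(img, disk, margin = 5)
  expect_equal(reg$center, c(31, 31), tolerance = 0.05)
  expect_equal(reg$radius, 15, tolerance = 0.3)
  expect_true(all(reg$mask[disk]))
  d <- eagseg:::dist_from_point(co, reg$center)
  expect_identical(reg$mask, array(d <= reg$radius, c(61, 61)))

  ## single-pixel tumour: zero max distance, radius = margin
  px <- array(FALSE, c(21, 21)); px[11, 11] <- TRUE
  img1 <- array(0.1, c(21, 21)); img1[11, 11] <- 1
  reg1 <- build_target_region(img1, px, margin = 5)
  expect_equal(reg1$radius, 5)

  ## synthetic boundary at distance 34 from the centre + margin 5 -> 39
  ring <- array(FALSE, c(81, 81))
  co81 <- eagseg:::index_to_coords(seq_len(81 * 81), c(81, 81))
  d81 <- eagseg:::dist_from_point(co81, c(41, 41))
  ring[d81 <= 34] <- TRUE
  img2 <- array(0, c(81, 81)); img2[ring] <- 1
  reg2 <- build_target_region(img2, ring, margin = 5)
  expect_equal(reg2$radius, 39, tolerance = 0.5)
})

test_that("local threshold equals fraction times the region's Otsu level", {
  ph <- generate_phantom(phantom_spec(rng_seed = 3))
  img <- augment_contrast(normalize_intensity(ph$image))
  thr <- compute_threshold(otsu_level(img$data), 0.2)
  g <- grow_region(img, round(ph$tumor_center),
                   growth_config(thr, "median", max_radius = 12))
  rg <- regrow_with_local_threshold(img, round(ph$tumor_center), g,
                                    growth_config(thr, "median",
                                                  max_radius = 12))
  reg <- attr(rg, "target_region")
  expect_equal(attr(rg, "local_level"),
               brute_otsu(img$data[reg$mask]))
  expect_equal(attr(rg, "local_threshold"),
               0.2 * attr(rg, "local_level"))
  expect_true(all(reg$mask[g$mask]))
})

test_that("regrowth reduces to known cases", {
  ## uniform tumour exactly matching the primary mask: mask unchanged
  a <- matrix(0.1, 21, 21)
  co <- eagseg:::index_to_coords(seq_len(21 * 21), c(21, 21))
  disk <- eagseg:::dist_from_point(co, c(11, 11)) <= 5
  a[disk] <- 0.9
  g <- grow_region(a, c(11, 11), growth_config(0.2, "none"))
  rg <- regrow_with_local_threshold(a, c(11, 11), g, growth_config(0.2, "none"))
  expect_identical(rg$mask, g$mask)

  ## target region spanning the whole image reduces to the global case
  gw <- grow_region(a, c(11, 11), growth_config(
    compute_threshold(otsu_level(a), 0.2), "none"))
  whole <- array(TRUE, c(21, 21))
  rw <- regrow_with_local_threshold(a, c(11, 11), whole,
                                    growth_config(0.2, "none"),
                                    margin = 100)
  expect_identical(rw$mask, gw$mask)
})

test_that("local Otsu exceeds the global level when the tumour outshines the scene", {
  ph <- generate_phantom(phantom_spec(tumor_intensity = 0.9,
                                      tumor_radius = 16, rng_seed = 12))
  img <- augment_contrast(normalize_intensity(ph$image))
  global <- otsu_level(img$data)
  thr <- compute_threshold(global, 0.2)
  g <- grow_region(img, round(ph$tumor_center),
                   growth_config(thr, "median", max_radius = 16,
                                 lung_mask = segment_lung_mask(img)$mask))
  rg <- regrow_with_local_threshold(img, round(ph$tumor_center), g,
                                    growth_config(thr, "median",
                                                  max_radius = 16))
  expect_gte(attr(rg, "local_level"), global)
})
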