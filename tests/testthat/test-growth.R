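test_that("otsu_level matches brute-force and EBImage on assorted inputs", {
  v <- c(rep(0.1, 50), rep(0.9, 50))
  lev <- otsu_level(v)
  expect_gt(lev, 0.1); expect_lt(lev, 0.9)
  expect_equal(lev, brute_otsu(v))

  expect_equal(otsu_level(rep(0.37, 10)), 0.37)
  expect_error(otsu_level(numeric(0)), "empty")

  set.seed(31)
  mix <- pmin(1, pmax(0, c(rnorm(500, 0.2, 0.05), rnorm(500, 0.8, 0.05))))
  expect_equal(otsu_level(mix), brute_otsu(mix))
  ## independent implementation: EBImage's Otsu on the same histogram
  expect_equal(otsu_level(mix),
               as.numeric(EBImage::otsu(matrix(mix, 20, 50))),
               tolerance = 1 / 256)

  for (s in 1:5) {
    set.seed(s)
    v <- runif(200)
    expect_equal(otsu_level(v), brute_otsu(v))
  }
})

test_that("the working threshold is the stated fraction of the grey level", {
  expect_equal(compute_threshold(0.48, 0.20), 0.096)
  expect_equal(compute_threshold(0.64, 0.20), 0.128)
  expect_equal(compute_threshold(0.5, 1.0), 0.5)
  ## vector input goes through otsu first
  v <- c(rep(0.1, 50), rep(0.9, 50))
  expect_equal(compute_threshold(v, 0.2), 0.2 * otsu_level(v))
  expect_error(compute_threshold(0.5, 0), "fraction")
  expect_error(compute_threshold(0.5, 1.5), "fraction")
})

test_that("comparison value updates follow mean/median definitions", {
  expect_equal(update_comparison_value(c(0.2, 0.4, 0.6), "mean"), 0.4)
  expect_equal(update_comparison_value(c(0.1, 0.9, 0.5), "median"), 0.5)
  expect_equal(update_comparison_value(0.7, "mean"), 0.7)
  expect_equal(update_comparison_value(0.7, "median"), 0.7)
  expect_error(update_comparison_value(numeric(0), "mean"), "empty")
})

test_that("growth degenerate cases: flood everything or only the seed", {
  const <- matrix(0.5, 9, 9)
  g <- grow_region(const, c(5, 5), growth_config(threshold = 0.1))
  expect_true(all(g$mask))
  expect_equal(g$trace_frontier[length(g$trace_frontier)], 0)

  lung <- matrix(FALSE, 9, 9); lung[3:7, 3:7] <- TRUE
  gl <- grow_region(const, c(5, 5),
                    growth_config(threshold = 0.1, lung_mask = lung))
  expect_identical(gl$mask, lung)

  spike <- matrix(0, 5, 5); spike[3, 3] <- 1
  gs <- grow_region(spike, c(3, 3), growth_config(threshold = 0.2))
  expect_equal(which(gs$mask), which(spike == 1))
  expect_equal(nrow(gs$boundary), 1)
})

test_that("growth on the printed block grid equals brute-force flood fill", {
  a <- block_image()
  g <- grow_region(a, c(4, 4), growth_config(threshold = 0.15))
  expected <- array(FALSE, c(7, 7)); expected[3:5, 3:5] <- TRUE
  expect_identical(g$mask, expected)
  expect_identical(g$mask, brute_flood_fill(a, c(4, 4), 0.15))
  ## boundary of a filled 3x3 block is all 9 pixels except... the centre
  ## has all 8 neighbours inside, so 8 boundary points
  expect_equal(nrow(g$boundary), 8)
})

test_that("growth equals flood fill on random 2D and 3D fields", {
  set.seed(77)
  for (i in 1:12) {
    a <- matrix(runif(16 * 16), 16, 16)
    seed <- c(sample(16, 1), sample(16, 1))
    g <- grow_region(a, seed, growth_config(threshold = 0.15))
    expect_identical(g$mask, brute_flood_fill(a, seed, 0.15))
  }
  for (i in 1:4) {
    a <- array(runif(8^3), c(8, 8, 8))
    seed <- sample(8, 3, replace = TRUE)
    g <- grow_region(a, seed, growth_config(threshold = 0.2))
    expect_identical(g$mask, brute_flood_fill(a, seed, 0.2))
  }
})

test_that("mask grows monotonically with the threshold", {
  set.seed(5)
  a <- matrix(runif(400), 20, 20)
  prev <- NULL
  for (t in c(0.05, 0.1, 0.2, 0.4)) {
    g <- grow_region(a, c(10, 10), growth_config(threshold = t))
    if (!is.null(prev)) expect_true(all(g$mask[prev]))
    prev <- g$mask
  }
})

test_that("lung-mask and radius constraints are never violated", {
  set.seed(8)
  a <- matrix(runif(900, 0.4, 0.6), 30, 30)
  lung <- matrix(FALSE, 30, 30); lung[5:25, 5:25] <- TRUE
  g <- grow_region(a, c(15, 15),
                   growth_config(threshold = 0.5, lung_mask = lung,
                                 max_radius = 4, radius_factor = 2))
  expect_true(all(lung[g$mask]))
  co <- eagseg:::index_to_coords(which(g$mask), dim(a))
  expect_lte(max(eagseg:::dist_from_point(co, c(15, 15))), 8)
  expect_error(grow_region(a, c(1, 1),
                           growth_config(threshold = 0.5, lung_mask = lung)),
               "outside the lung mask")
  expect_error(grow_region(a, c(99, 1), growth_config(threshold = 0.5)),
               "outside the image")
})

test_that("median update barely perturbs growth under symmetric noise", {
  set.seed(21)
  a <- matrix(0.2, 24, 24)
  a[6:18, 6:18] <- 0.7
  a <- a + matrix(rnorm(576, 0, 0.02), 24, 24)
  g0 <- grow_region(a, c(12, 12), growth_config(0.15, "none"))
  gm <- grow_region(a, c(12, 12), growth_config(0.15, "median"))
  differ <- sum(xor(g0$mask, gm$mask))
  expect_lt(differ / sum(g0$mask | gm$mask), 0.05)
})

test_that("traces are well-formed and the boundary is a true boundary", {
  set.seed(13)
  for (i in 1:5) {
    a <- matrix(runif(256), 16, 16)
    g <- grow_region(a, c(8, 8), growth_config(threshold = 0.25,
                                               compare_update = "median"))
    expect_true(all(diff(g$trace_cumulative) >= 0))
    expect_equal(g$trace_frontier[length(g$trace_frontier)], 0)
    expect_equal(g$trace_cumulative[length(g$trace_cumulative)],
                 sum(g$mask))
    ## every boundary point is in the mask with an outside neighbour
    if (nrow(g$boundary) > 0) {
      bl <- eagseg:::coords_to_index(g$boundary, dim(a))
      expect_true(all(g$mask[bl]))
      inner <- g$mask
      offs <- eagseg:::neighbor_offsets(2)
      for (r in seq_len(nrow(offs)))
        inner <- inner & eagseg:::shift_array(g$mask, offs[r, ], fill = FALSE)
      expect_true(all(!inner[bl]))
    }
  }
})

test_that("trace CSV export has the level/frontier/cumulative columns", {
  g <- grow_region(block_image(), c(4, 4), growth_config(threshold = 0.15))
  f <- file.path(tempdir(), "trace.csv")
  write_trace_csv(g, f)
  tr <- utils::read.csv(f)
  expect_equal(names(tr), c("level", "frontier", "cumulative"))
  expect_equal(tr$cumulative, cumsum(tr$frontier))
})
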