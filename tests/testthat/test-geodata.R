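test_that("haversine distance matches hand-evaluated references", {
  expect_identical(haversine_km(0, 0, 0, 0), 0)
  quarter <- 6371 * pi / 2
  expect_equal(haversine_km(0, 0, 90, 0), quarter, tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0, 90), quarter, tolerance = 1e-10)
  expect_equal(haversine_km(0, 0, 0.4, 0), 6371 * pi / 180 * 0.4,
               tolerance = 1e-10)
  expect_equal(round(haversine_km(0, 0, 0.4, 0), 2), 44.48)
  expect_equal(round(haversine_km(0, 0, 0.5, 0), 2), 55.60)
  # symmetry and non-negativity on random points
  set.seed(11)
  for (i in 1:20) {
    p <- c(runif(2, -180, 180), runif(2, -85, 85))
    d1 <- haversine_km(p[1], p[3], p[2], p[4])
    expect_identical(d1, haversine_km(p[2], p[4], p[1], p[3]))
    expect_gte(d1, 0)
  }
  expect_error(haversine_km(0, 95, 0, 0), "latitudes")
})

test_that("haversine agrees with an independent geodesy implementation", {
  set.seed(42)
  lon <- runif(50, -180, 180); lat <- runif(50, -89, 89)
  mine <- haversine_km(lon[1:25], lat[1:25], lon[26:50], lat[26:50])
  ref <- geosphere::distHaversine(cbind(lon[1:25], lat[1:25]),
                                  cbind(lon[26:50], lat[26:50]),
                                  r = 6371000) / 1000
  expect_equal(mine, ref, tolerance = 1e-9)
})

test_that("circular buffer selects cells by centre distance", {
  tmpl <- equator_grid()
  # point at the centre of cell (4,4): rook neighbours ~44.5 km, diagonals
  # ~62.9 km, so a 50-km buffer is the centre cell plus its 4 rook cells
  b50 <- circular_buffer_range(0, 0, tmpl, radius_km = 50)
  expect_s3_class(b50, "binary_range")
  expect_identical(b50$cell_count, 5L)
  expect_identical(which(b50$values == 1, arr.ind = TRUE)[, "row"] |>
                     sort() |> unname(), c(3L, 4L, 4L, 4L, 5L))
  # radius below half the cell diagonal: only the containing cell
  b30 <- circular_buffer_range(0, 0, tmpl, radius_km = 30)
  expect_identical(b30$cell_count, 1L)
  expect_identical(b30$values[4, 4], 1)
  # duplicated point changes nothing
  b_dup <- circular_buffer_range(c(0, 0), c(0, 0), tmpl, radius_km = 50)
  expect_identical(b_dup$values, b50$values)
  expect_error(circular_buffer_range(numeric(0), numeric(0), tmpl),
               "no coordinate-bearing points")
})

test_that("buffers grow monotonically with radius", {
  tmpl <- equator_grid(9)
  set.seed(3)
  for (i in 1:10) {
    pts <- cbind(runif(3, -1, 1), runif(3, -1, 1))
    radii <- sort(runif(2, 10, 150))
    b1 <- circular_buffer_range(pts[, 1], pts[, 2], tmpl, radii[1])
    b2 <- circular_buffer_range(pts[, 1], pts[, 2], tmpl, radii[2])
    expect_true(all(b2$values[b1$values == 1] == 1))
  }
})

test_that("range area follows the cosine-latitude rule", {
  # one full equatorial row of an 0.4-degree grid
  m <- matrix(0, 7, 7); m[4, ] <- 1
  rng <- range_from_matrix(m)
  edge <- 0.4 * pi / 180 * 6371
  expect_equal(rng$area_km2, 7 * edge^2 * cos(0), tolerance = 0.005)
  # off-equator rows weigh less
  m2 <- matrix(0, 7, 7); m2[1, ] <- 1
  expect_lt(range_from_matrix(m2)$area_km2, rng$area_km2)
  # polar rows are rejected
  polar <- grid_layer(matrix(1, 2, 2), 0, 90, 0.5)
  expect_error(cell_area_km2(polar), "89.5")
  # empty range has zero area
  expect_identical(range_from_matrix(matrix(0, 3, 3))$area_km2, 0)
})

test_that("depth-weighted soil mean uses interval thicknesses", {
  tmpl <- equator_grid(3)
  mk <- function(v) {
    l <- tmpl; l$values <- matrix(v, 3, 3); l
  }
  layers <- lapply(1:5, mk)
  out <- depth_weighted_soil(layers)
  expect_equal(unique(as.vector(out$values)),
               (5 * 1 + 10 * 2 + 15 * 3 + 30 * 4 + 40 * 5) / 100)  # 3.9
  # constant profile is preserved
  expect_equal(unique(as.vector(depth_weighted_soil(
    lapply(rep(7, 5), mk))$values)), 7)
  # nodata propagates
  layers[[3]]$values[2, 2] <- NA
  expect_true(is.na(depth_weighted_soil(layers)$values[2, 2]))
  # convex combination property on random stacks
  set.seed(5)
  rnd <- lapply(1:5, function(i) mk(0) |>
                  (\(l) { l$values <- matrix(runif(9, -3, 3), 3, 3); l })())
  dw <- depth_weighted_soil(rnd)$values
  lo <- Reduce(pmin, lapply(rnd, `[[`, "values"))
  hi <- Reduce(pmax, lapply(rnd, `[[`, "values"))
  expect_true(all(dw >= lo - 1e-12 & dw <= hi + 1e-12))
  # misalignment is an error
  off <- grid_layer(matrix(0, 3, 3), 1, 1.4, 0.4)
  expect_error(depth_weighted_soil(c(layers[1:4], list(off))),
               "not aligned")
  # non-contiguous intervals are an error
  expect_error(depth_weighted_soil(layers[1:2],
                                   cbind(c(0, 10), c(5, 20))),
               "contiguous")
})

test_that("exclusion masking drops cells and downstream area", {
  m <- matrix(1, 4, 4)
  rng <- range_from_matrix(m)
  none <- range_from_matrix(matrix(0, 4, 4))
  all1 <- range_from_matrix(matrix(1, 4, 4))
  expect_identical(apply_exclusion_mask(rng, none)$values, rng$values)
  expect_identical(apply_exclusion_mask(rng, all1)$cell_count, 0L)
  half <- matrix(0, 4, 4); half[, 1:2] <- 1
  masked <- apply_exclusion_mask(rng, range_from_matrix(half))
  expect_identical(masked$cell_count, 8L)
  expect_equal(masked$area_km2 / rng$area_km2, 0.5, tolerance = 1e-9)
})

test_that("richness map sums presences cellwise", {
  a <- range_from_matrix(rbind(c(1, 1, 0), c(0, 0, 0), c(0, 0, 0)))
  b <- range_from_matrix(rbind(c(0, 1, 1), c(0, 0, 0), c(0, 0, 0)))
  r <- richness_map(list(a, b))
  expect_identical(r$values[1, ], c(1, 2, 1))
  expect_identical(richness_map(list(a))$values, a$values)
  expect_setequal(unique(as.vector(richness_map(list(a, a))$values)),
                  c(0, 2))
  # k copies scale the single-range map by k
  expect_identical(richness_map(list(b, b, b))$values, 3 * b$values)
  expect_error(richness_map(list()), "non-empty")
})

test_that("ASCII grid round-trips values, georeferencing and nodata", {
  l <- equator_grid(5)
  set.seed(9)
  l$values <- matrix(rnorm(25), 5, 5)
  l$values[2, 3] <- NA
  f <- tempfile(fileext = ".asc")
  write_ascii_grid(l, f)
  back <- read_ascii_grid(f)
  expect_equal(back$values, l$values, tolerance = 1e-15)
  expect_equal(back$origin_lon, l$origin_lon)
  expect_equal(back$origin_lat, l$origin_lat)
  expect_equal(back$cell_size, l$cell_size)
  expect_true(is.na(back$values[2, 3]))
  expect_error(read_ascii_grid({
    f2 <- tempfile(); writeLines(c("garbage", "1 2 3"), f2); f2
  }), "ESRI ASCII")
})

test_that("alignment is enforced, never resampled", {
  a <- equator_grid(5)
  b <- equator_grid(6)
  expect_false(grids_aligned(a, b))
  shifted <- grid_layer(a$values, a$origin_lon + 0.1, a$origin_lat,
                        a$cell_size)
  expect_false(grids_aligned(a, shifted))
  expect_true(grids_aligned(a, equator_grid(5)))
})
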