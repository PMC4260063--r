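test_that("count standardization rescales by area", {
  expect_equal(standardize_count(50, 1)$per_circle, 50)
  s <- standardize_count(12, 2)
  expect_equal(s$per_circle, 3)
  expect_equal(s$per_sqmi, 12 / (4 * pi))
  expect_equal(s$per_circle, s$per_sqmi * pi)
  z <- standardize_count(0, 2)
  expect_equal(z$per_circle, 0)
  expect_equal(z$per_sqmi, 0)
  expect_error(standardize_count(5, 0), class = "invalid_radius")
})

test_that("a single point's peak matches the bivariate normal closed form", {
  # grid with a cell centered exactly on the point
  g <- grid_spec(-2.05, -2.05, 0.1, 41, 41)
  smp <- make_samples(0, 0, 1, 10)
  surf <- kernel_density(smp, "total", bandwidth_mi = 1, grid = g,
                         weight_mode = "raw")
  center <- surf$values[21, 21]
  # exact: truncated-renormalized gaussian peak
  expect_equal(center, 10 / (2 * pi * (1 - exp(-4.5))), tolerance = 1e-12)
  # untruncated limit w / (2 pi h^2), recovered within the 1.2%
  # renormalization factor
  expect_equal(center, 10 / (2 * pi), tolerance = 0.02)
})

test_that("zero weights give an all-zero surface, not an error", {
  g <- grid_spec(0, 0, 0.5, 10, 10)
  smp <- make_samples(c(1, 3), c(1, 3), c(2, 2), c(0, 0))
  surf <- kernel_density(smp, "total", bandwidth_mi = 2, grid = g)
  expect_true(all(surf$values == 0))
})

test_that("optimized surface equals the naive double-loop oracle", {
  set.seed(21)
  n <- 5
  x <- runif(n, 2, 8); y <- runif(n, 2, 8)
  counts <- sample(5:60, n); radius <- runif(n, 0.5, 2)
  g <- grid_spec(0, 0, 0.25, 40, 40)
  w <- counts / radius^2  # standardized per-1-mile-circle weights
  for (kern in c("gaussian", "quartic")) {
    surf <- kernel_density(make_samples(x, y, radius, counts), "total",
                           bandwidth_mi = 2, grid = g, kernel = kern)
    oracle <- naive_kde_values(x, y, w, 2, g, kernel = kern)
    expect_equal(surf$values, oracle, tolerance = 1e-10)
  }
})

test_that("surface volume conserves the total weight for interior points", {
  set.seed(22)
  # points at least 3 bandwidths (3 mi) from every grid edge
  g <- grid_spec(0, 0, 0.1, 120, 120)
  n <- 6
  x <- runif(n, 3.5, 8.5); y <- runif(n, 3.5, 8.5)
  counts <- sample(10:50, n); radius <- runif(n, 0.5, 2)
  surf <- kernel_density(make_samples(x, y, radius, counts), "total",
                         bandwidth_mi = 1, grid = g)
  volume <- sum(surf$values) * g$cell_size^2
  expect_equal(volume, sum(counts / radius^2), tolerance = 0.01)
})

test_that("kernel densities are linear in the stratum counts", {
  set.seed(23)
  g <- grid_spec(0, 0, 0.2, 30, 30)
  x <- runif(4, 1, 5); y <- runif(4, 1, 5); radius <- runif(4, 0.5, 2)
  ca <- sample(0:30, 4); cb <- sample(0:30, 4)
  f <- function(counts) {
    kernel_density(make_samples(x, y, radius, counts), "total",
                   bandwidth_mi = 1.5, grid = g)$values
  }
  expect_equal(f(ca) + f(cb), f(ca + cb))
})

test_that("surfaces are equivariant under joint translation", {
  set.seed(24)
  x <- runif(3, 1, 4); y <- runif(3, 1, 4)
  counts <- c(12, 30, 7); radius <- c(1, 2, 0.6)
  g1 <- grid_spec(0, 0, 0.25, 20, 20)
  shift <- c(5.25, -3.5)
  g2 <- grid_spec(0 + shift[1], 0 + shift[2], 0.25, 20, 20)
  s1 <- kernel_density(make_samples(x, y, radius, counts), "total",
                       bandwidth_mi = 1, grid = g1)
  s2 <- kernel_density(make_samples(x + shift[1], y + shift[2], radius, counts),
                       "total", bandwidth_mi = 1, grid = g2)
  expect_equal(s1$values, s2$values)
})

test_that("narrower bandwidths concentrate the surface (higher peak)", {
  sc <- demo_scenario()
  g <- region_grid(sc$region, 0.1)
  s1 <- kernel_density(sc$tab, "total", bandwidth_mi = 1, grid = g)
  s2 <- kernel_density(sc$tab, "total", bandwidth_mi = 2, grid = g)
  expect_gte(max(s1$values), max(s2$values))
})

test_that("raw-count weighting is available and differs from standardized", {
  smp <- make_samples(c(2, 4), c(2, 2), c(0.5, 2), c(10, 10))
  g <- grid_spec(0, 0, 0.2, 20, 30)
  std <- kernel_density(smp, "total", bandwidth_mi = 1, grid = g)
  raw <- kernel_density(smp, "total", bandwidth_mi = 1, grid = g,
                        weight_mode = "raw")
  # standardized weighting upweights the small-radius stop 4x
  expect_gt(max(std$values), max(raw$values))
  expect_false(isTRUE(all.equal(std$values, raw$values)))
})

test_that("per-point density summaries compute order statistics", {
  smp <- make_samples(1:3, 1, c(1, 1, 1), c(1, 2, 3))
  sm <- per_point_density_summary(smp, "total", measure = "per_circle")
  expect_equal(sm$mean, 2)
  expect_equal(sm$median, 2)
  expect_equal(c(sm$min, sm$max), c(1, 3))
  skew <- make_samples(1:3, 1, c(1, 1, 1), c(1, 1, 100))
  sk <- per_point_density_summary(skew, "total", measure = "per_circle")
  expect_equal(sk$median, 1)
  expect_equal(sk$mean, 34)
  expect_gt(sk$mean, sk$median)   # right skew
  expect_error(per_point_density_summary(smp[0, ], "total"),
               class = "empty_input")
})

test_that("the heterogeneous demo scenario shows the field's right skew", {
  sc <- demo_scenario()
  sm <- per_point_density_summary(sc$tab, "total")
  expect_gt(sm$mean, sm$median)
  expect_equal(sum(sm$histogram$count), nrow(sc$tab))
})

test_that("ASC grids round-trip byte-identically with NODATA preserved", {
  g <- grid_spec(-1.5, 2, 0.25, 6, 4)
  vals <- matrix(runif(24, 0, 50), 4, 6)
  vals[2, 3] <- NA
  vals[1, 1] <- NA
  surf <- density_surface(g, vals)
  p1 <- withr::local_tempfile(fileext = ".asc")
  p2 <- withr::local_tempfile(fileext = ".asc")
  write_asc(surf, p1)
  back <- read_asc(p1)
  expect_identical(is.na(back$values), is.na(vals))
  expect_equal(unclass(back$grid), unclass(g))
  write_asc(back, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("malformed ASC files name the offending line", {
  p <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 0", "yllcorner 0",
               "cellsize 1", "NODATA_value -9999", "1 2", "3"), p)
  expect_error(read_asc(p), "8", class = "parse_error")
  writeLines(c("ncols 2", "bogus"), p)
  expect_error(read_asc(p), class = "parse_error")
})

test_that("region masking sets NODATA outside and keeps values inside", {
  region <- study_region(cbind(c(0, 4, 4, 0), c(0, 0, 4, 4)))
  g <- grid_spec(-1, -1, 0.5, 12, 12)
  smp <- make_samples(2, 2, 1, 20)
  surf <- kernel_density(smp, "total", bandwidth_mi = 1, grid = g,
                         region = region)
  cc <- grid_cell_centers(surf$grid)
  outside <- outer(cc$y, cc$x, function(y, x) x < 0 | x > 4 | y < 0 | y > 4)
  expect_true(all(is.na(surf$values[outside])))
  expect_true(all(!is.na(surf$values[!outside])))
})
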