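test_that("surface statistics use the population standard deviation", {
  s <- make_surface(matrix(c(0, 10), 1))
  st <- surface_stats(s)
  expect_equal(st$mean, 5)
  expect_equal(st$sd, 5)          # divide-by-N, not N-1
  expect_equal(st$threshold, 15)
  expect_equal(st$n_cells, 2L)
  const <- surface_stats(make_surface(matrix(3, 4, 4)))
  expect_equal(const$sd, 0)
  expect_equal(const$threshold, 3)
  # threshold scales with n_sd
  expect_equal(surface_stats(s, n_sd = 3)$threshold, 20)
})

test_that("an all-NODATA surface cannot be summarized", {
  g <- grid_spec(0, 0, 1, 2, 2)
  s <- density_surface(g, matrix(NA_real_, 2, 2))
  expect_error(surface_stats(s), class = "empty_surface")
})

test_that("surface difference is cellwise, null at zero, antisymmetric", {
  a <- make_surface(matrix(c(5, 2, 0, 7), 2))
  b <- make_surface(matrix(c(3, 2, 1, 9), 2))
  d <- surface_difference(a, b)
  expect_equal(d$values, a$values - b$values)
  expect_equal(d$values[1, 1], 2)  # positive: higher density in a
  same <- surface_difference(a, a)
  expect_true(all(same$values == 0))
  expect_equal(surface_difference(a, b)$values,
               -surface_difference(b, a)$values)
})

test_that("surface ratio is null at one and NODATA at zero denominators", {
  a <- make_surface(matrix(c(4, 3, 6, 0), 2))
  b <- make_surface(matrix(c(2, 0, 6, 5), 2))
  r <- surface_ratio(a, b)
  expect_equal(r$values[1, 1], 2)
  expect_true(is.na(r$values[2, 1]))  # b = 0 there
  expect_equal(r$values[1, 2], 1)
  unity <- surface_ratio(a, a)
  pos <- !is.na(unity$values)
  expect_true(all(unity$values[pos] == 1))
  # reciprocal identity where both defined
  rr <- surface_ratio(b, a)
  both <- !is.na(r$values) & !is.na(rr$values)
  expect_equal((r$values * rr$values)[both], rep(1, sum(both)))
})

test_that("mismatched grids are refused", {
  a <- make_surface(matrix(1, 2, 2))
  b <- make_surface(matrix(1, 2, 2), cell_size = 0.5)
  expect_error(surface_difference(a, b), class = "incompatible_grids")
  expect_error(surface_ratio(a, b), class = "incompatible_grids")
  expect_error(indicator_difference(a, b), class = "incompatible_grids")
})

test_that("extreme mask applies a strict mean + 2 SD cut", {
  # constant surface: sd 0, strict inequality fails everywhere
  expect_true(all(extreme_mask(make_surface(matrix(3, 3, 3)))$values == 0))
  # {0,0,0,100}: mean 25, population sd ~43.3, threshold ~111.6 -> no cell
  m4 <- extreme_mask(make_surface(matrix(c(0, 0, 0, 100), 2)))
  expect_true(all(m4$values == 0))
  expect_equal(m4$parent_stats[[1]]$threshold, 25 + 2 * sqrt(1875),
               tolerance = 1e-12)
  # 99 zeros and one 100: mean 1, sd ~9.95, threshold ~20.9 -> only the spike
  vals <- matrix(0, 10, 10); vals[4, 7] <- 100
  m100 <- extreme_mask(make_surface(vals))
  expect_equal(sum(m100$values), 1)
  expect_equal(m100$values[4, 7], 1)
})

test_that("extreme mask is invariant under positive rescaling", {
  set.seed(31)
  vals <- matrix(rexp(64, 1 / 10), 8)
  s <- make_surface(vals)
  for (c in c(0.2, 3, 117)) {
    expect_equal(extreme_mask(make_surface(c * vals))$values,
                 extreme_mask(s)$values)
  }
})

test_that("indicator difference enumerates to exactly {-1, 0, 1}", {
  # 97 background cells pin each surface's threshold low; spikes at
  # four cells realize all exceed/not-exceed combinations:
  # both extreme / only a / only b / neither
  base <- matrix(0, 10, 10)
  av <- base; av[1, 1] <- 100; av[1, 2] <- 100
  bv <- base; bv[1, 1] <- 80;  bv[1, 3] <- 80
  a <- make_surface(av); b <- make_surface(bv)
  ind <- indicator_difference(a, b)
  expect_equal(ind$values[1, 1], 0)    # extreme in both
  expect_equal(ind$values[1, 2], 1)    # only a
  expect_equal(ind$values[1, 3], -1)   # only b
  expect_equal(ind$values[2, 2], 0)    # neither
  expect_true(all(ind$values %in% c(-1, 0, 1)))
  # each surface is thresholded against its OWN stats
  expect_equal(ind$parent_stats[[1]]$threshold,
               surface_stats(a)$threshold)
  expect_equal(ind$parent_stats[[2]]$threshold,
               surface_stats(b)$threshold)
})

test_that("indicator values stay in {-1, 0, 1} for random surfaces", {
  for (s in 1:20) {
    set.seed(400 + s)
    a <- make_surface(matrix(rexp(100, 1 / 5), 10))
    b <- make_surface(matrix(rexp(100, 1 / 5), 10))
    ind <- indicator_difference(a, b)
    expect_true(all(ind$values %in% c(-1, 0, 1)))
  }
})

test_that("NODATA propagates through all comparison operations", {
  av <- matrix(c(1, 2, NA, 4), 2); bv <- matrix(c(2, NA, 3, 4), 2)
  a <- make_surface(av); b <- make_surface(bv)
  expect_true(is.na(surface_difference(a, b)$values[2, 1]))
  expect_true(is.na(surface_difference(a, b)$values[1, 2]))
  expect_true(is.na(surface_ratio(a, b)$values[1, 2]))
  expect_true(is.na(extreme_mask(a)$values[1, 2]))
  expect_true(is.na(indicator_difference(a, b)$values[1, 2]))
})

test_that("a nested stratum's surface never exceeds its superset's", {
  sc <- demo_scenario()
  young_black <- function(race, age_group, age) {
    race == "black" & !is.na(age) & age < 25
  }
  tab <- sample_points_table(sc$run,
                             extra_strata = list(black_u25 = young_black))
  g <- region_grid(sc$region, 0.2)
  s_black <- kernel_density(tab, "black", bandwidth_mi = 2, grid = g)
  s_young <- kernel_density(tab, "black_u25", bandwidth_mi = 2, grid = g)
  expect_true(all(tab$n_black_u25 <= tab$n_black))
  expect_true(all(s_young$values <= s_black$values + 1e-12))
})
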