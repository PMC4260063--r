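test_that("observe captures everyone within r_max when fewer than k", {
  set.seed(1)
  pop <- random_population(10, c(4, 6), c(4, 6))  # all within 2 mi of center
  sp <- observe(c(5, 5), pop, k = 50, r_max = 2)
  expect_equal(nrow(sp$captured), 10L)
  expect_equal(sp$radius_mi, 2.0)
})

test_that("observe takes exactly the k nearest when over-subscribed", {
  set.seed(2)
  pop <- random_population(80, c(4, 6), c(4, 6))
  sp <- observe(c(5, 5), pop, k = 50, r_max = 2)
  oracle <- brute_observe(c(5, 5), pop, k = 50, r_max = 2)
  expect_equal(nrow(sp$captured), 50L)
  expect_equal(sp$radius_mi, oracle$radius)
  expect_identical(sort(sp$captured$id), oracle$ids)
  expect_true(all(diff(sp$captured$distance_mi) >= 0))
  expect_true(all(sp$captured$distance_mi <= sp$radius_mi))
})

test_that("observe on an empty population returns radius r_max", {
  sp <- observe(c(5, 5), random_population(0), k = 50, r_max = 2)
  expect_equal(nrow(sp$captured), 0L)
  expect_equal(sp$radius_mi, 2.0)
})

test_that("ties at the k-th distance are all captured", {
  # 4 users at distance 1, k = 3: all four come in, radius 1
  pop <- data.frame(id = sprintf("u%d", 1:4),
                    x_mi = c(1, -1, 0, 0), y_mi = c(0, 0, 1, -1),
                    race = "white", age = 30)
  sp <- observe(c(0, 0), pop, k = 3, r_max = 2)
  expect_equal(nrow(sp$captured), 4L)
  expect_equal(sp$radius_mi, 1)
})

test_that("observe equals the exhaustive sort oracle on random populations", {
  for (s in 1:30) {
    set.seed(1000 + s)
    pop <- random_population(sample(1:500, 1))
    pt <- runif(2, 0, 10)
    k <- sample(c(3, 25, 50), 1)
    sp <- observe(pt, pop, k = k, r_max = 2)
    oracle <- brute_observe(pt, pop, k = k, r_max = 2)
    expect_identical(sort(sp$captured$id), oracle$ids)
    expect_equal(sp$radius_mi, oracle$radius)
  }
})

test_that("distance quantization mimics the app display granularity", {
  pop <- data.frame(id = c("a", "b"),
                    x_mi = c(1258.4 / 5280, 1.4567), y_mi = 0,
                    race = "white", age = 30)
  sp <- observe(c(0, 0), pop, quantize = TRUE, r_max = 2)
  expect_equal(sp$captured$distance_mi, c(1258 / 5280, 1.46))
})

test_that("an empty population yields stops at exact 2-mile intervals", {
  rt <- route(cbind(c(0, 10), c(0, 0)))
  run <- run_route(rt, random_population(0), k = 50, r_max = 2)
  expect_length(run, 6L)
  expect_equal(attr(run, "arc"), c(0, 2, 4, 6, 8, 10))
  expect_true(all(vapply(run, `[[`, 0, "radius_mi") == 2))
  # stops lie on the polyline (y = 0)
  expect_equal(vapply(run, `[[`, 0, "y"), rep(0, 6))
})

test_that("a dense cluster shrinks the inter-stop spacing below 2 miles", {
  set.seed(9)
  cluster <- random_population(120, c(4.8, 5.2), c(-0.2, 0.2))
  rt <- route(cbind(c(0, 10), c(0, 0)))
  run <- run_route(rt, cluster, k = 50, r_max = 2)
  arcs <- attr(run, "arc")
  steps <- diff(arcs)
  expect_true(any(steps < 2))        # tighter sampling near the cluster
  expect_true(all(steps > 0))        # strictly increasing arc positions
  mid <- which(arcs > 3 & arcs < 7)
  expect_true(min(steps[pmin(mid, length(steps))]) < 2)
})

test_that("a very short route yields exactly one stop", {
  rt <- route(cbind(c(0, 1e-3), c(0, 0)))
  run <- run_route(rt, random_population(0))
  expect_length(run, 1L)
})

test_that("a route shorter than the start offset warns and returns no stops", {
  rt <- route(cbind(c(0, 1), c(0, 0)), start_offset = 5)
  expect_warning(run <- run_route(rt, random_population(0)),
                 "shorter than start_offset")
  expect_length(run, 0L)
})

test_that("profile categorization follows the missing-data rules", {
  expect_equal(categorize_profile("missing", 25),
               data.frame(race = "other", age_group = "25-30"))
  expect_equal(categorize_profile("black", NA),
               data.frame(race = "black", age_group = "unknown"))
  expect_equal(categorize_profile("white", 33),
               data.frame(race = "white", age_group = ">30"))
  expect_equal(categorize_profile("white", c(18, 24, 25, 30, 31))$age_group,
               c("18-24", "18-24", "25-30", "25-30", ">30"))
  expect_error(categorize_profile("white", 17), class = "out_of_domain")
})

test_that("the alternative age-bin convention is expressible", {
  rules <- categorization_rules(age_breaks = c(18, 26, 31, Inf))
  expect_equal(rules$age_labels, c("18-25", "26-30", ">30"))
  expect_equal(categorize_profile("white", c(25, 26), rules)$age_group,
               c("18-25", "26-30"))
  expect_error(categorization_rules(age_breaks = c(20, 30, Inf)),
               class = "invalid_parameter")
})

test_that("coverage_fraction matches geometric expectations", {
  unit <- study_region(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))
  # circle larger than the region, centered inside -> full coverage
  one_big <- data.frame(x_mi = 0.5, y_mi = 0.5, radius_mi = 10)
  expect_equal(coverage_fraction(one_big, unit, 0.02), 1.0)
  # no sample points -> zero
  expect_equal(coverage_fraction(one_big[0, ], unit, 0.02), 0.0)
  # huge circle whose boundary bisects the square -> about one half
  half <- data.frame(x_mi = 0.5 - 1000, y_mi = 0.5, radius_mi = 1000)
  expect_lt(abs(coverage_fraction(half, unit, 0.01) - 0.5), 0.02)
  # monotone non-decreasing as circles are added
  set.seed(3)
  circ <- data.frame(x_mi = runif(8), y_mi = runif(8), radius_mi = 0.15)
  covs <- vapply(1:8, function(m) {
    coverage_fraction(circ[seq_len(m), ], unit, 0.02)
  }, 0)
  expect_true(all(diff(covs) >= 0))
})

test_that("sample table counts are consistent with captures", {
  sc <- demo_scenario()
  tab <- sc$tab
  expect_equal(tab$n_white + tab$n_black + tab$n_other, tab$n_total)
  expect_equal(tab$n_age_18_24 + tab$n_age_25_30 + tab$n_age_gt30 +
                 tab$n_age_unknown, tab$n_total)
  expect_equal(tab$n_total,
               vapply(sc$run, function(s) nrow(s$captured), 0L))
  expect_true(all(tab$radius_mi > 0 & tab$radius_mi <= 2))
  # stops with fewer than k captures carry the maximum radius
  expect_true(all(tab$radius_mi[tab$n_total < 50] == 2))
  # zero-capture stops are retained
  expect_true(all(tab$n_total >= 0))
})
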