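test_that("condition grid crosses factors with exact derived quantities", {
  grid <- condition_grid()
  expect_s3_class(grid, "stimulus_set")
  expect_equal(nrow(grid), 18)
  expect_identical(grid$total_surface_area, grid$number * grid$avg_item_area)
  expect_identical(grid$density, grid$number / grid$total_field_area)
  expect_true(all(unlist(grid[quantity_dimensions]) > 0))
  # order: number slowest, then item area, then field area
  expect_equal(grid$number, rep(c(6, 10, 17), each = 6))
  expect_equal(grid$label[1:3], c("N1-S1-TFA1", "N1-S1-TFA2", "N1-S2-TFA1"))

  one <- condition_grid(6, 0.04, 20)
  expect_equal(nrow(one), 1)
  expect_equal(one$total_surface_area, 0.24)
  expect_equal(one$density, 0.30)

  # densities at the small field area
  d20 <- grid$density[grid$total_field_area == 20]
  expect_setequal(round(unique(d20), 2), c(0.30, 0.50, 0.85))
})

test_that("grid construction validates its levels", {
  expect_error(condition_grid(numeric(0), 0.04, 20), "at least one")
  expect_error(condition_grid(c(6, -1), 0.04, 20), "positive")
  expect_error(condition_grid(c(6, 6), 0.04, 20), "distinct")
})

test_that("grid construction is idempotent and survives CSV round-trip", {
  a <- condition_grid()
  b <- condition_grid()
  expect_identical(as.data.frame(a), as.data.frame(b))
  path <- tempfile(fileext = ".csv")
  write_stimulus_set(a, path)
  c <- read_stimulus_set(path)
  expect_equal(as.data.frame(c), as.data.frame(a))
  expect_equal(attr(c, "factor_levels"), attr(a, "factor_levels"))
})

test_that("dimension correlations reflect the orthogonal manipulation", {
  grid <- condition_grid()
  expect_equal(dimension_correlation(grid, "number", "number"), 1.0)
  expect_lt(abs(dimension_correlation(grid, "number", "avg_item_area")), 1e-12)
  expect_lt(abs(dimension_correlation(grid, "number", "total_field_area")), 1e-12)
  expect_gt(dimension_correlation(grid, "number", "total_surface_area"), 0)
  expect_gt(dimension_correlation(grid, "number", "density"), 0)

  # brute-force product-moment oracle over the 18 (N, D) pairs
  n <- grid$number; d <- grid$density
  num <- sum((n - mean(n)) * (d - mean(d)))
  den <- sqrt(sum((n - mean(n))^2) * sum((d - mean(d))^2))
  expect_equal(dimension_correlation(grid, "number", "density"), num / den,
               tolerance = 1e-12)

  expect_error(dimension_correlation(condition_grid(c(6, 10), 0.04, 20),
                                     "avg_item_area", "number"),
               "zero variance")
})

test_that("explicit TSA tables can replace the nominal N x S products", {
  grid <- condition_grid()
  tsa_tab <- c(`6_0.04` = 0.25, `10_0.04` = 0.42, `17_0.04` = 0.71,
               `6_0.07` = 0.42, `10_0.07` = 0.71, `17_0.07` = 1.19,
               `6_0.12` = 0.72, `10_0.12` = 1.19, `17_0.12` = 2.03)
  tsa <- tsa_tab[paste(grid$number, grid$avg_item_area, sep = "_")]
  r <- dimension_correlation(grid, "number", "total_surface_area",
                             tsa_values = unname(tsa))
  expect_equal(round(r, 2), 0.68)
  expect_error(dimension_correlation(grid, "number", "total_surface_area",
                                     tsa_values = 1:3), "per condition")
})

test_that("rendered dot arrays satisfy the geometric contract", {
  grid <- condition_grid()
  for (i in c(1, 8, 18)) {
    cond <- grid[i, ]
    arr <- render_dot_array(cond, seed = 11 + i)
    n <- cond$number
    expect_equal(nrow(arr$centers), n)
    # mean item area exact, sum = N x S
    expect_equal(mean(arr$item_areas), cond$avg_item_area, tolerance = 1e-9)
    expect_equal(sum(arr$item_areas), n * cond$avg_item_area,
                 tolerance = 1e-9)
    # all disks inside the virtual field circle
    radii <- sqrt(arr$item_areas / pi)
    expect_true(all(sqrt(rowSums(arr$centers^2)) + radii <=
                      arr$field_radius + 1e-12))
    # no overlapping disks
    dmat <- as.matrix(dist(arr$centers))
    need <- outer(radii, radii, "+")
    diag(dmat) <- Inf
    expect_true(all(dmat >= need - 1e-12))
    # half black / half white, extra dot black
    expect_equal(sum(arr$colors == "black"), ceiling(n / 2))
    expect_equal(sum(arr$colors == "white"), floor(n / 2))
  }
})

test_that("rendering is deterministic in the seed, variable across seeds", {
  cond <- condition_grid()[5, ]
  a <- render_dot_array(cond, seed = 7)
  b <- render_dot_array(cond, seed = 7)
  c <- render_dot_array(cond, seed = 8)
  expect_identical(a$centers, b$centers)
  expect_identical(a$item_areas, b$item_areas)
  expect_false(isTRUE(all.equal(a$centers, c$centers)))
  # condition-level quantities unchanged by the seed
  expect_equal(mean(c$item_areas), cond$avg_item_area, tolerance = 1e-9)
})

test_that("infeasible packing fails with a condition-naming error", {
  tight <- list(label = "tight", number = 40, avg_item_area = 0.3,
                total_field_area = 13, density = 40 / 13,
                total_surface_area = 12)
  expect_error(render_dot_array(tight, seed = 1, max_attempts = 200),
               "tight")
})

test_that("convex hull area matches closed forms and a Monte-Carlo oracle", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(convex_hull_area(tri), 0.5)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(3, 4))), 0)
  expect_equal(convex_hull_area(rbind(c(0, 0), c(1, 1), c(2, 2))), 0)

  arr <- render_dot_array(condition_grid()[8, ], seed = 21)
  a <- convex_hull_area(arr)
  expect_equal(a, mc_hull_area(arr$centers), tolerance = 0.01)
  # edge convention encloses the center hull
  expect_gt(convex_hull_area(arr, boundary = "edge"), a)
})
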