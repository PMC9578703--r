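test_that("grid counts are conserved and anchored half-open", {
  # 4 trees at the corners of a 0.01 x 0.01 box: max-edge points open new cells
  inv <- toy_inventory(4, lat = c(40, 40, 40.01, 40.01),
                       lon = c(-80, -79.99, -80, -79.99))
  cells <- grid_partition(inv, cell_size = 0.005)
  expect_equal(sum(cells$raw_count), 4L)
  expect_equal(sum(cells$raw_count > 0), 4L)  # each corner in its own cell
  # interior-edge tree goes to the upper/right cell
  inv2 <- toy_inventory(3, lat = c(40, 40.005, 40.0099),
                        lon = c(-80, -80, -80))
  cells2 <- grid_partition(inv2, cell_size = 0.005)
  counts_by_row <- tapply(cells2$raw_count, cells2$row, sum)
  expect_equal(as.integer(counts_by_row[c("0", "1")]), c(1L, 2L))
})

test_that("boundary clipping scales cell areas and excludes outside trees", {
  # boundary covers exactly the lower half (in latitude) of a full-cell column
  inv <- toy_inventory(4, lat = c(40.001, 40.002, 40.008, 40.0074),
                       lon = rep(-79.9975, 4))
  boundary <- data.frame(lat = c(40, 40.0075, 40.0075, 40),
                         lon = c(-80, -80, -79.995, -79.995))
  cells <- grid_partition(inv, cell_size = 0.005, boundary = boundary)
  expect_equal(attr(cells, "n_outside"), 1L)  # the 40.008 tree is outside
  expect_equal(sum(cells$raw_count), 3L)
  full <- cells[cells$row == 0, ]
  clipped <- cells[cells$row == 1, ]
  expect_equal(full$area_fraction, 1)
  expect_equal(clipped$area_fraction, 0.5, tolerance = 1e-6)
  expect_equal(clipped$adjusted_count, clipped$raw_count * 0.5,
               tolerance = 1e-6)
  # density adjustment divides instead
  cells_d <- grid_partition(inv, cell_size = 0.005, boundary = boundary,
                            adjust = "density")
  expect_equal(cells_d$adjusted_count[cells_d$row == 1],
               cells_d$raw_count[cells_d$row == 1] / 0.5, tolerance = 1e-6)
  expect_error(grid_partition(inv, boundary = boundary[c(1, 1, 1), ]),
               "degenerate")
})

test_that("coverage moments match hand-computed central-moment ratios", {
  cells <- data.frame(raw_count = c(1, 2, 3, 0, 0),
                      adjusted_count = c(1, 2, 3, 0, 0))
  rep <- coverage_stats(cells)
  expect_equal(rep$pct_empty, 40)
  expect_equal(rep$skewness, 0)       # symmetric [1,2,3]
  expect_equal(rep$kurtosis, 1.5)     # m2 = 2/3, m4 = 2/3 -> (2/3)/(4/9)
  # ten cells, four empty
  cells2 <- data.frame(raw_count = c(rep(1, 6), rep(0, 4)),
                       adjusted_count = c(rep(1, 6), rep(0, 4)))
  expect_equal(coverage_stats(cells2)$pct_empty, 40)
  expect_false(coverage_stats(cells2)$moments_defined)  # zero variance
})

test_that("the report is invariant to whole-cell translations", {
  inv <- simulate_city(n_trees = 800, seed = 15)
  r1 <- coverage_stats(grid_partition(inv, cell_size = 0.005))
  shifted <- as.data.frame(inv)
  shifted$latitude <- shifted$latitude + 0.005 * 7
  shifted$longitude <- shifted$longitude - 0.005 * 3
  inv2 <- as_inventory(shifted)
  r2 <- coverage_stats(grid_partition(inv2, cell_size = 0.005))
  expect_equal(r1$pct_empty, r2$pct_empty)
  expect_equal(r1$skewness, r2$skewness)
  expect_equal(r1$kurtosis, r2$kurtosis)
})

test_that("normally distributed occupied-cell counts show kurtosis near 3", {
  # validates the non-excess (Pearson) convention: b2 of a normal sample -> 3
  set.seed(88)
  counts <- rnorm(100000, mean = 50, sd = 5)
  cells <- data.frame(raw_count = 1, adjusted_count = counts)
  rep <- coverage_stats(cells)
  expect_lt(abs(rep$kurtosis - 3), 0.1)
  expect_lt(abs(rep$skewness), 0.05)
})
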