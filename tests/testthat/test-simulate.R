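test_that("a fixed seed reproduces the inventory exactly", {
  a <- simulate_city(n_trees = 500, mixing_rho = 0.4, seed = 10)
  b <- simulate_city(n_trees = 500, mixing_rho = 0.4, seed = 10)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- simulate_city(n_trees = 500, mixing_rho = 0.4, seed = 11)
  expect_false(identical(a$scientific_name, c$scientific_name))
})

test_that("uniform abundance with no mixing gives multinomially even counts", {
  inv <- simulate_city(n_trees = 5000, n_species = 5, abundance_shape = 1,
                       mixing_rho = 0, native_fraction = 0, seed = 2)
  counts <- table(inv$scientific_name)
  expect_equal(length(counts), 5L)
  # each count ~ Binomial(5000, 1/5): 5 sigma ~ 200
  expect_true(all(abs(counts - 1000) < 200))
})

test_that("the realized rank-abundance follows the geometric series", {
  shape <- 0.7
  inv <- simulate_city(n_trees = 20000, n_species = 10, abundance_shape = shape,
                       mixing_rho = 0, native_fraction = 0, seed = 3)
  counts <- sort(table(inv$scientific_name), decreasing = TRUE)
  expected <- shape^(0:9) / sum(shape^(0:9)) * 20000
  # chi-square goodness of fit against the geometric expectation
  chi2 <- sum((as.numeric(counts) - expected)^2 / expected)
  expect_lt(chi2, qchisq(0.999, df = 9))
})

test_that("full mixing propagates a single species through the city", {
  inv <- simulate_city(n_trees = 300, mixing_rho = 1, seed = 4)
  expect_equal(length(unique(inv$scientific_name)), 1L)
})

test_that("the realized native fraction sits within binomial noise of target", {
  inv <- simulate_city(n_trees = 10000, native_fraction = 0.35, mixing_rho = 0,
                       seed = 5)
  frac <- mean(inv$native_status == "naturally_occurring")
  expect_lt(abs(frac - 0.35), 5 * sqrt(0.35 * 0.65 / 10000))
})

test_that("overlapping species pools are rejected", {
  expect_error(simulate_city(native_pool = c("Acer rubrum", "Quercus alba"),
                             introduced_pool = c("acer rubrum"), seed = 1),
               "overlap")
})

test_that("city sets share the introduced pool and separate native pools", {
  cs <- simulate_city_set(n_cities = 3, n_trees = 800, seed = 6)
  expect_length(cs$inventories, 3L)
  pools <- cs$truth$native_pools
  expect_length(intersect(pools[[1]], pools[[2]]), 0L)
  intro <- cs$truth$introduced_pool
  for (i in 1:3) {
    sp <- unique(cs$inventories[[i]]$scientific_name)
    expect_true(all(sp %in% c(pools[[i]], intro)))
    expect_gt(length(intersect(sp, intro)), 0L)
  }
  expect_equal(dim(cs$climate), c(3L, 20L))
  # two cities with disjoint native pools: native-only similarity is 0,
  # introduced-only similarity is high (same pool, same weights)
  s_nat <- paired_city_similarity(cs$inventories[[1]], cs$inventories[[2]],
                                  condition = "naturally_occurring",
                                  reps = 10, seed = 1)
  expect_equal(s_nat$similarity, 0)
  s_int <- paired_city_similarity(cs$inventories[[1]], cs$inventories[[2]],
                                  condition = "introduced", reps = 10, seed = 2)
  expect_gt(s_int$similarity, 0.8)
})

test_that("native pools can be made to overlap along the climate gradient", {
  cs <- simulate_city_set(n_cities = 5, n_trees = 500, native_overlap_span = 2,
                          seed = 7)
  pools <- cs$truth$native_pools
  near <- length(intersect(pools[[1]], pools[[2]]))
  far <- length(intersect(pools[[1]], pools[[5]]))
  expect_gt(near, far)
})
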