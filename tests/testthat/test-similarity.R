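test_that("chi-square similarity matches hand-evaluated cases", {
  expect_equal(chisq_similarity(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 1.0)
  expect_equal(chisq_similarity(c(1, 0), c(0, 1)), 0.0)
  # terms (0.5-1)^2/1.5 /2 and (0.5-0)^2/0.5 /2 sum to 1/3
  expect_equal(chisq_similarity(c(0.5, 0.5), c(1, 0)), 2 / 3)
  # named vectors align on the union; absent species count as zeros
  expect_equal(chisq_similarity(c(a = 0.5, b = 0.5), c(b = 0.5, c = 0.5)), 0.5)
  expect_error(chisq_similarity(c(0.5, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("similarity is symmetric, bounded, and 1 only at equality", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(2:40, 1)
    x <- as.numeric(rmultinom(1, 500, runif(k))) / 500
    y <- as.numeric(rmultinom(1, 500, runif(k))) / 500
    s <- chisq_similarity(x, y)
    expect_gte(s, 0); expect_lte(s, 1)
    expect_equal(s, chisq_similarity(y, x))
    if (!isTRUE(all.equal(x, y))) expect_lt(s, 1)
  }
})

test_that("paired city similarity handles equal, disjoint, and subsampled cases", {
  a <- rep(sprintf("sp%02d", 1:10), times = 10:1)
  inv_a <- toy_inventory(length(a), species = a)
  expect_equal(paired_city_similarity(inv_a, inv_a)$similarity, 1.0)

  b <- rep(sprintf("other%02d", 1:10), times = 10:1)
  inv_b <- toy_inventory(length(b), species = b)
  s <- paired_city_similarity(inv_a, inv_b, reps = 10, seed = 1)
  expect_equal(s$similarity, 0.0)
  expect_true(all(s$per_rep == 0))

  # two multinomial draws from one frequency vector differ only by noise
  set.seed(2)
  p <- 0.8^(0:19); p <- p / sum(p)
  big <- sample(sprintf("sp%02d", 1:20), 20000, replace = TRUE, prob = p)
  small <- sample(sprintf("sp%02d", 1:20), 5000, replace = TRUE, prob = p)
  s2 <- paired_city_similarity(toy_inventory(20000, species = big),
                               toy_inventory(5000, species = small),
                               reps = 50, seed = 3)
  expect_gt(s2$similarity, 0.9)
  expect_equal(s2$similarity, median(s2$per_rep))
  expect_equal(length(s2$per_rep), 50L)
})

test_that("subsampled similarity converges to the population value", {
  set.seed(9)
  p <- 0.7^(0:14); p <- p / sum(p)
  q <- rev(p)
  pop_sim <- chisq_similarity(p, q)
  sizes <- c(200, 2000, 20000)
  err <- vapply(sizes, function(n) {
    a <- sample(sprintf("s%02d", 1:15), n, replace = TRUE, prob = p)
    b <- sample(sprintf("s%02d", 1:15), 4 * n, replace = TRUE, prob = q)
    s <- paired_city_similarity(a, b, reps = 25, seed = n)
    abs(s$similarity - pop_sim)
  }, numeric(1))
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.02)
})

test_that("nativity filters make empty communities incomparable", {
  inv <- toy_inventory(10, species = "Acer rubrum",
                       native_status = "naturally_occurring")
  s <- paired_city_similarity(inv, inv, condition = "introduced")
  expect_false(s$comparable)
  expect_true(is.na(s$similarity))
})

test_that("the homogenization paired test behaves at the null and rejects misuse", {
  x <- c(0.5, 0.6, 0.7, 0.4)
  h <- homogenization_test(x, x)
  expect_equal(h$mean_diff, 0)
  expect_equal(h$t, 0)
  expect_error(homogenization_test(1, 1), "at least 2")
  expect_error(homogenization_test(c(1, 2), c(1, 2, 3)), "length")
})

test_that("environmental similarity normalizes PC distances", {
  # three collinear cities at PC distances 1 and 2 from the anchor
  pca <- structure(list(scores = cbind(PC1 = c(0, 1, 2), PC2 = c(0, 0, 0)),
                        cities = c("a", "b", "c")), class = "env_pca")
  rownames(pca$scores) <- pca$cities
  sim <- env_similarity(pca)
  expect_equal(diag(sim), c(a = 1, b = 1, c = 1))
  expect_equal(sim["a", "b"], 0.5)
  expect_equal(sim["a", "c"], 0)   # maximal pair
  # identical climates across the board: warn, all ones
  clim <- data.frame(city = c("x", "y", "z"),
                     matrix(rep(1:19, each = 3), nrow = 3,
                            dimnames = list(NULL, paste0("bio", 1:19))))
  expect_warning(s2 <- env_similarity(clim), "identical")
  expect_true(all(s2 == 1))
})

test_that("PCA orients components with positive dominant loadings", {
  set.seed(23)
  clim <- data.frame(city = sprintf("c%02d", 1:12))
  t <- seq(0, 1, length.out = 12)
  for (j in 1:19) clim[[paste0("bio", j)]] <- j * t * (-1)^j + rnorm(12, 0, 0.1)
  pca <- env_pca(clim)
  for (j in seq_len(ncol(pca$loadings)))
    expect_gt(pca$loadings[which.max(abs(pca$loadings[, j])), j], 0)
})

test_that("Pearson-Filon z matches an independent transcription and its null", {
  # identical correlation vectors: z must be exactly 0
  set.seed(12)
  e <- runif(30); v <- runif(30)
  cc <- correlation_comparison(e, v, v)
  expect_equal(cc$z, 0)
  # reference values: independent transcription of the published statistic
  pf_oracle <- function(r12, r13, r23, n) {
    det_part <- 1 - r12^2 - r13^2
    k <- r23 * det_part - 0.5 * r12 * r13 * (det_part - r23^2)
    (r12 - r13) * sqrt(n) / sqrt((1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k)
  }
  # build vectors with the requested correlation structure via Cholesky
  r12 <- 0.8; r13 <- 0.5; r23 <- 0.6; n <- 200
  S <- matrix(c(1, r12, r13, r12, 1, r23, r13, r23, 1), 3)
  set.seed(42)
  z <- matrix(rnorm(3 * n), ncol = 3) %*% chol(S)
  cc2 <- correlation_comparison(z[, 1], z[, 2], z[, 3])
  expect_equal(cc2$z,
               pf_oracle(cc2$r_env_native, cc2$r_env_all, cc2$r_native_all,
                         n),
               tolerance = 1e-6)
  expect_lt(cc2$p, 1); expect_gt(cc2$p, 0)
  # guards
  expect_true(correlation_comparison(runif(3), runif(3), runif(3))$low_n)
  expect_error(correlation_comparison(rep(1, 10), runif(10), runif(10)),
               "constant")
})
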