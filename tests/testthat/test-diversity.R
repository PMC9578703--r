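test_that("effective species count matches closed-form values", {
  expect_equal(effective_species_count(c(A = 50)), 1.0)
  expect_equal(effective_species_count(c(A = 10, B = 10, C = 10, D = 10)), 4.0)
  # hand evaluation of exp(-(0.7 ln 0.7 + 0.2 ln 0.2 + 0.1 ln 0.1))
  expect_equal(effective_species_count(c(A = 70, B = 20, C = 10)), 2.2296,
               tolerance = 1e-4)
  expect_error(effective_species_count(character(0)))
})

test_that("effective species count is bounded by richness and scale invariant", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:30, 1)
    counts <- stats::setNames(sample(1:200, k, replace = TRUE), paste0("sp", 1:k))
    es <- effective_species_count(counts)
    expect_gte(es, 1)
    expect_lte(es, k + 1e-12)
    expect_equal(effective_species_count(counts * 7), es)
  }
  # equality with richness iff uniform
  expect_lt(effective_species_count(c(A = 5, B = 1)), 2)
  expect_equal(effective_species_count(c(A = 5, B = 5)), 2)
})

test_that("Santamour 10/20/30 checks flag the right ranks", {
  counts <- stats::setNames(c(9, rep(7, 13)), c("Acer one",
                                                paste("Genus", letters[1:13])))
  rule <- max_abundance_rule(counts)  # species max 9%
  expect_true(rule$pass[rule$rank == "species"])
  # genus aggregation: two congeners over 20%
  counts2 <- c("Acer rubrum" = 13, "Acer saccharum" = 12, "Quercus alba" = 75)
  rule2 <- max_abundance_rule(counts2)
  expect_false(rule2$pass[rule2$rank == "genus"])
  expect_true(is.na(rule2$pass[rule2$rank == "family"]))  # no lookup -> unavailable
  fam <- c(Acer = "Sapindaceae", Quercus = "Fagaceae")
  rule3 <- max_abundance_rule(counts2, family_lookup = fam)
  expect_false(rule3$pass[rule3$rank == "family"])  # Fagaceae at 75%
  # single-species community fails everything
  rule4 <- max_abundance_rule(c("Acer rubrum" = 10), family_lookup = fam)
  expect_false(any(rule4$pass))
})

test_that("standardization at the full sample returns the raw diversity", {
  counts <- c(A = 30, B = 15, C = 5)
  sd_full <- standardized_diversity(counts, target_size = 50, reps = 20, seed = 1)
  expect_false(sd_full$extrapolated)
  expect_equal(unique(round(sd_full$per_rep, 12)),
               round(effective_species_count(counts), 12))
  # a single tree always carries exactly one species
  sd_one <- standardized_diversity(c(A = 10, B = 10), 1, reps = 50, seed = 2)
  expect_true(all(sd_one$per_rep == 1))
  expect_error(standardized_diversity(counts, 0))
})

test_that("subsampled diversity matches a brute-force oracle", {
  # oracle: direct Monte-Carlo over raw tree labels, coded independently
  counts <- c(A = 900, B = 100)
  set.seed(99)
  labels <- rep(c("A", "B"), c(900, 100))
  oracle <- mean(replicate(20000, {
    tab <- table(sample(labels, 50))
    p <- tab / 50
    exp(-sum(p * log(p)))
  }))
  est <- standardized_diversity(counts, 50, reps = 500, seed = 7)
  expect_lt(abs(est$estimate - oracle), 0.05)
  expect_true(est$ci95[1] <= est$estimate && est$estimate <= est$ci95[2])
})

test_that("rarefaction is monotone non-decreasing in target size", {
  set.seed(13)
  counts <- stats::setNames(sort(rmultinom(1, 2000, prob = 0.7^(0:14))[, 1],
                                 decreasing = TRUE), paste0("sp", 1:15))
  counts <- counts[counts > 0]
  sizes <- c(10, 50, 200, 800, 2000)
  fits <- lapply(seq_along(sizes), function(i)
    standardized_diversity(counts, sizes[i], reps = 2000, seed = 100 + i))
  means <- vapply(fits, `[[`, numeric(1), "estimate")
  ses <- vapply(fits, function(f) stats::sd(f$per_rep) / sqrt(f$reps), numeric(1))
  for (i in seq_len(length(sizes) - 1))
    expect_gte(means[i + 1] - means[i], -2 * sqrt(ses[i]^2 + ses[i + 1]^2))
})

test_that("sampling beyond the community size is flagged as extrapolation", {
  est <- standardized_diversity(c(A = 5, B = 5), 40, reps = 50, seed = 3)
  expect_true(est$extrapolated)
})

test_that("park-urban comparison detects constructed diversity differences", {
  rich <- sprintf("Species r%02d", 1:20)
  poor <- sprintf("Species p%02d", 1:5)
  invs <- lapply(1:12, function(i)
    stratified_inventory(400, 600, rich, poor, city = paste0("C", i), seed = i))
  res <- park_urban_comparison(invs, reps = 200, seed = 5)
  expect_gt(res$mean_diff, 0)
  expect_lt(res$p, 0.05)
  expect_equal(res$df, 11)

  # null case: identical compositions in both strata
  invs0 <- lapply(1:6, function(i)
    stratified_inventory(500, 500, rich, rich, city = paste0("N", i), seed = i))
  res0 <- park_urban_comparison(invs0, reps = 200, seed = 6)
  expect_lt(abs(res0$mean_diff), 1)
})

test_that("cities lacking a stratum are excluded; one usable city is an error", {
  rich <- sprintf("Species r%02d", 1:8)
  both <- stratified_inventory(100, 100, rich, rich, city = "Both")
  urban_only <- toy_inventory(50, species = rich, location = "built_environment",
                              city = "UrbanOnly")
  expect_error(park_urban_comparison(list(both, urban_only), reps = 50, seed = 1),
               "at least two")
})
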