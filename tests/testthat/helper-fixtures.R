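# fixtures are built in code; nothing is read from disk

toy_inventory <- function(n = 10, species = rep(c("Acer rubrum", "Quercus alba"),
                                                length.out = n),
                          lat = NULL, lon = NULL, location = "built_environment",
                          city = "Testville", state = "TS", ...) {
  df <- data.frame(
    city = city, state = state,
    tree_id = sprintf("t%03d", seq_len(n)),
    scientific_name = rep(species, length.out = n),
    latitude = lat %||% (40 + seq_len(n) * 1e-4),
    longitude = lon %||% (-80 + seq_len(n) * 1e-4),
    location_type = rep(location, length.out = n),
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nmx in names(extra)) df[[nmx]] <- extra[[nmx]]
  as_inventory(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two tight blobs far apart plus stray points: unambiguous density structure
blob_points <- function(seed = 7) {
  set.seed(seed)
  rbind(cbind(rnorm(100, 0, 5), rnorm(100, 0, 5)),
        cbind(rnorm(100, 200, 5), rnorm(100, 200, 5)),
        cbind(runif(10, -50, 250), runif(10, -50, 250)))
}

# inventory with park and urban strata of controlled species richness
stratified_inventory <- function(n_park, n_urban, park_species, urban_species,
                                 city = "Strat", seed = 1) {
  set.seed(seed)
  df <- data.frame(
    city = city, state = "TS",
    tree_id = sprintf("%s%04d", city, seq_len(n_park + n_urban)),
    scientific_name = c(sample(park_species, n_park, replace = TRUE),
                        sample(urban_species, n_urban, replace = TRUE)),
    latitude = 40 + runif(n_park + n_urban) * 0.01,
    longitude = -80 + runif(n_park + n_urban) * 0.01,
    location_type = c(rep("green_space", n_park),
                      rep("built_environment", n_urban)),
    stringsAsFactors = FALSE)
  as_inventory(df)
}
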