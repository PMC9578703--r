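#' Simulate a city tree inventory with known structure
#'
#' Generates an [inventory] whose structure is controlled: trees are placed
#' along a street grid (built environment) and inside rectangular park
#' polygons (green space); species follow a geometric rank-abundance series;
#' and spatial aggregation by species is tuned by `mixing_rho`, the
#' probability that a tree copies the species of its nearest already-planted
#' neighbour instead of drawing from the abundance distribution. At
#' `mixing_rho = 0` species are spatially random; at 1 each contiguous patch
#' is monospecific.
#'
#' Nativity is a species-level property: a native and an introduced species
#' pool are built (or supplied), and the base draw picks a native-pool
#' species with probability `native_fraction`, so the realized native tree
#' fraction is within sampling noise of the target at `mixing_rho = 0`.
#'
#' @param n_trees number of trees.
#' @param n_species total species (split between pools when none supplied).
#' @param abundance_shape geometric-series ratio in (0, 1]; rank-k species
#'   weight is proportional to `abundance_shape^(k-1)`, so 1 gives uniform
#'   frequencies and smaller values a steeper, more realistic dominance.
#' @param mixing_rho neighbour-copying probability in \[0, 1\].
#' @param native_fraction target fraction of native trees.
#' @param street_grid `c(rows, cols)` of streets crossing the city square.
#' @param park_fraction fraction of trees placed in parks.
#' @param n_parks number of rectangular parks.
#' @param center `c(lat, lon)` of the city square's center.
#' @param extent side of the city square, degrees.
#' @param city,state identifiers.
#' @param native_pool,introduced_pool optional character vectors of binomials
#'   (must be disjoint); defaults are generated from the city name.
#' @param seed RNG seed; the inventory is byte-identical under the same seed.
#' @return an [inventory] with attribute `truth` (the generating parameters
#'   and pools).
#' @export
simulate_city <- function(n_trees = 5000L, n_species = 40L,
                          abundance_shape = 0.85, mixing_rho = 0,
                          native_fraction = 0.5, street_grid = c(12L, 12L),
                          park_fraction = 0.15, n_parks = 3L,
                          center = c(40, -80), extent = 0.06,
                          city = "Simville", state = "SV",
                          native_pool = NULL, introduced_pool = NULL,
                          seed = NULL) {
  stopifnot(n_trees >= 1L, n_species >= 1L, n_species <= n_trees,
            abundance_shape > 0, abundance_shape <= 1,
            mixing_rho >= 0, mixing_rho <= 1,
            native_fraction >= 0, native_fraction <= 1, extent > 0)
  if (any(street_grid < 1L)) stop("street grid must have at least one street")
  if (is.null(native_pool) || is.null(introduced_pool)) {
    n_nat <- if (native_fraction == 0) 0L else
      max(1L, round(n_species * native_fraction))
    if (native_fraction == 1) n_nat <- n_species
    n_int <- n_species - n_nat
    native_pool <- native_pool %||%
      sprintf("Nativus %s%02d", tolower(gsub("[^A-Za-z]", "", city)), seq_len(n_nat))
    introduced_pool <- introduced_pool %||%
      sprintf("Introducta communis%02d", seq_len(n_int))
  }
  if (length(intersect(normalize_binomial(native_pool),
                       normalize_binomial(introduced_pool))))
    stop("native and introduced pools overlap")

  with_seed(seed, {
    lat0 <- center[1] - extent / 2; lon0 <- center[2] - extent / 2
    n_park_trees <- round(n_trees * park_fraction)
    n_street_trees <- n_trees - n_park_trees

    # parks: axis-aligned rectangles, total area ~ park_fraction of the square
    park_side <- extent * sqrt(park_fraction / max(n_parks, 1L))
    park_ll <- cbind(lat0 + stats::runif(n_parks) * (extent - park_side),
                     lon0 + stats::runif(n_parks) * (extent - park_side))
    # street trees are planted by block: each street is cut into blocks by the
    # crossing streets, a block is planted with probability block_occupancy,
    # and planted blocks get heterogeneous intensities (real inventories are
    # strongly block-structured, with many unplanted stretches)
    rows <- street_grid[1]; cols <- street_grid[2]
    block_occupancy <- 0.5
    blocks <- rbind(
      expand.grid(street = seq_len(rows), blk = seq_len(cols), horiz = TRUE),
      expand.grid(street = seq_len(cols), blk = seq_len(rows), horiz = FALSE))
    w <- stats::rlnorm(nrow(blocks), 0, 1) *
      (stats::runif(nrow(blocks)) < block_occupancy)
    if (all(w == 0)) w[1L] <- 1
    blk_of <- sample.int(nrow(blocks), n_street_trees, replace = TRUE,
                         prob = w)
    blk_len_h <- extent / cols; blk_len_v <- extent / rows
    horiz <- blocks$horiz[blk_of]
    along <- (blocks$blk[blk_of] - stats::runif(n_street_trees)) *
      ifelse(horiz, blk_len_h, blk_len_v)
    jitter <- stats::runif(n_street_trees, -1, 1) * extent * 5e-4
    street_pos <- (blocks$street[blk_of] - 0.5) /
      ifelse(horiz, rows, cols) * extent
    s_lat <- ifelse(horiz, lat0 + street_pos + jitter, lat0 + along)
    s_lon <- ifelse(horiz, lon0 + along, lon0 + street_pos + jitter)
    park_of <- if (n_park_trees) sample.int(n_parks, n_park_trees, replace = TRUE)
      else integer(0)
    p_lat <- park_ll[park_of, 1] + stats::runif(n_park_trees) * park_side
    p_lon <- park_ll[park_of, 2] + stats::runif(n_park_trees) * park_side

    lat <- c(s_lat, p_lat); lon <- c(s_lon, p_lon)
    loc <- c(rep("built_environment", n_street_trees),
             rep("green_space", n_park_trees))
    # randomize the planting order so neighbour copying is order-agnostic
    ord <- sample.int(n_trees)
    lat <- lat[ord]; lon <- lon[ord]; loc <- loc[ord]

    # base species draws: nativity first, then geometric rank within the pool
    geom_weights <- function(k) abundance_shape^(seq_len(k) - 1L)
    is_native <- stats::runif(n_trees) < native_fraction
    draw_pool <- function(pool, n) {
      if (!n) return(character(0))
      pool[sample.int(length(pool), n, replace = TRUE,
                      prob = geom_weights(length(pool)))]
    }
    base_sp <- character(n_trees)
    base_sp[is_native] <- draw_pool(native_pool, sum(is_native))
    base_sp[!is_native] <- draw_pool(introduced_pool, sum(!is_native))

    species <- base_sp
    if (mixing_rho > 0 && n_trees > 1L) {
      copy <- stats::runif(n_trees) < mixing_rho
      copy[1L] <- FALSE
      nn <- seq_nearest_cpp(cbind(lat, lon))
      for (i in which(copy)) species[i] <- species[nn[i]]
    }
    native_set <- normalize_binomial(native_pool)
    status <- ifelse(normalize_binomial(species) %in% native_set,
                     "naturally_occurring", "introduced")

    df <- data.frame(
      city = city, state = state,
      tree_id = sprintf("%s_%06d", gsub("[^A-Za-z]", "", city), seq_len(n_trees)),
      scientific_name = species, common_name = NA_character_,
      latitude = lat, longitude = lon, location_type = loc,
      condition = sample(c("excellent", "good", "fair", "poor", "dead"),
                         n_trees, replace = TRUE,
                         prob = c(0.1, 0.45, 0.3, 0.1, 0.05)),
      native_status = status,
      dbh_cm = round(stats::rlnorm(n_trees, log(25), 0.6), 1),
      height_m = round(stats::rlnorm(n_trees, log(8), 0.5), 1),
      stringsAsFactors = FALSE)
    inv <- as_inventory(df, city = city, state = state)
    attr(inv, "truth") <- list(
      n_trees = n_trees, n_species = n_species,
      abundance_shape = abundance_shape, mixing_rho = mixing_rho,
      native_fraction = native_fraction, native_pool = native_pool,
      introduced_pool = introduced_pool, park_fraction = park_fraction,
      parks = cbind(park_ll, park_ll + park_side), seed = seed)
    inv
  })
}

#' Simulate a set of cities sharing an introduced species pool
#'
#' Emulates the premise behind biotic homogenization: every city draws its
#' introduced trees from one shared pool, while native pools are distinct
#' per city and track a latent climate gradient (cities with similar climate
#' share more native species). Also fabricates a 19-variable bioclimatic
#' table driven by the same gradient.
#'
#' @param n_cities number of cities.
#' @param n_trees trees per city (recycled).
#' @param shared_introduced_pool character vector, or an integer size for a
#'   generated pool.
#' @param native_pool_size native species per city.
#' @param native_overlap_span how many distinct native species exist along
#'   the whole gradient, as a multiple of `native_pool_size`: 1 makes all
#'   native pools identical, larger values make climatically distant cities'
#'   pools disjoint. Default 0 requests fully disjoint pools.
#' @param climate_slope strength of the latent gradient in the bioclim
#'   table (0 = climate unrelated to the gradient).
#' @param mixing_rho,native_fraction,abundance_shape passed to
#'   [simulate_city()].
#' @param seed RNG seed.
#' @param ... further arguments for [simulate_city()].
#' @return list of class `city_set`: `inventories` (named list), `climate`
#'   (data frame city + bio1..bio19), `truth`.
#' @export
simulate_city_set <- function(n_cities = 10L, n_trees = 5000L,
                              shared_introduced_pool = 20L,
                              native_pool_size = 20L,
                              native_overlap_span = 0,
                              climate_slope = 1,
                              mixing_rho = 0, native_fraction = 0.5,
                              abundance_shape = 0.85, seed = NULL, ...) {
  stopifnot(n_cities >= 2L)
  if (is.numeric(shared_introduced_pool) && length(shared_introduced_pool) == 1L)
    shared_introduced_pool <- sprintf("Introducta communis%02d",
                                      seq_len(shared_introduced_pool))
  n_trees <- rep_len(n_trees, n_cities)
  cities <- sprintf("City%02d", seq_len(n_cities))
  t_lat <- (seq_len(n_cities) - 1) / (n_cities - 1)  # latent climate gradient
  with_seed(seed, {
    # global native species list; each city's pool is a window positioned by
    # its gradient coordinate, so pool overlap decays with climate distance
    if (native_overlap_span > 0 && native_overlap_span <= n_cities) {
      g <- ceiling(native_pool_size * native_overlap_span)
      global_nat <- sprintf("Nativus continuus%03d", seq_len(g))
      starts <- round(t_lat * (g - native_pool_size))
      native_pools <- lapply(starts, function(s)
        global_nat[s + seq_len(native_pool_size)])
    } else {
      native_pools <- lapply(seq_len(n_cities), function(i)
        sprintf("Nativus loci%02d_%02d", i, seq_len(native_pool_size)))
    }
    seeds <- sample.int(.Machine$integer.max, n_cities)
    inventories <- stats::setNames(lapply(seq_len(n_cities), function(i)
      simulate_city(n_trees = n_trees[i],
                    n_species = native_pool_size + length(shared_introduced_pool),
                    abundance_shape = abundance_shape,
                    mixing_rho = mixing_rho,
                    native_fraction = native_fraction,
                    city = cities[i], state = sprintf("S%d", (i %% 50)),
                    center = c(30 + 15 * t_lat[i], -120 + 40 * t_lat[i]),
                    native_pool = native_pools[[i]],
                    introduced_pool = shared_introduced_pool,
                    seed = seeds[i], ...)), cities)
    base <- stats::runif(19, -5, 25); amp <- stats::runif(19, -10, 10)
    climate <- data.frame(city = cities)
    for (j in seq_len(19))
      climate[[sprintf("bio%d", j)]] <- base[j] +
        climate_slope * amp[j] * t_lat + stats::rnorm(n_cities, 0, 0.5)
    structure(list(inventories = inventories, climate = climate,
                   truth = list(latent = t_lat, native_pools = native_pools,
                                introduced_pool = shared_introduced_pool,
                                mixing_rho = mixing_rho,
                                native_fraction = native_fraction)),
              class = "city_set")
  })
}

#' @export
print.city_set <- function(x, ...) {
  cat(sprintf("<city_set> %d cities, %s trees\n", length(x$inventories),
              format(sum(vapply(x$inventories, nrow, integer(1))),
                     big.mark = ",")))
  invisible(x)
}
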