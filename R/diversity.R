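#' Effective species count (Shannon Hill number)
#'
#' The exponential of Shannon entropy, \eqn{\exp(-\sum_i p_i \ln p_i)}: the
#' number of equally common species that would produce the observed diversity.
#' Equals species richness exactly when frequencies are uniform, and 1 for a
#' monoculture.
#'
#' @param abund a `species_abundance`, a named count vector, or an
#'   [inventory].
#' @return a real number in `[1, richness]`.
#' @export
effective_species_count <- function(abund) {
  abund <- as_species_abundance(abund)
  if (is_empty_abundance(abund)) stop("empty species abundance")
  p <- abund$p
  exp(-sum(p * log(p)))
}

shannon_es <- function(counts) {
  # bare-metal version for hot loops: counts = positive integer vector
  p <- counts / sum(counts)
  exp(-sum(p * log(p)))
}

#' Santamour 10/20/30 abundance checks
#'
#' The planting guideline that the most common species should stay below 10%
#' of an urban forest, the most common genus below 20%, and the most common
#' family below 30%.
#'
#' @param abund species abundance (see [effective_species_count()] for
#'   accepted forms). Genus is the first token of the binomial.
#' @param family_lookup optional named vector genus -> family. Without it the
#'   family check is reported as unavailable (`NA`), not failed.
#' @return data frame with rows species/genus/family: `max_frequency`,
#'   `threshold`, `pass`.
#' @export
max_abundance_rule <- function(abund, family_lookup = NULL) {
  abund <- as_species_abundance(abund)
  if (is_empty_abundance(abund)) stop("empty species abundance")
  counts <- abund$counts
  genus <- vapply(strsplit(names(counts), "\\s+"), `[[`, character(1), 1L)
  gmax <- max(tapply(counts, genus, sum)) / abund$n
  smax <- max(abund$p)
  fmax <- NA_real_
  if (!is.null(family_lookup)) {
    fam <- unname(family_lookup[genus])
    if (!anyNA(fam)) fmax <- max(tapply(counts, fam, sum)) / abund$n
  }
  data.frame(
    rank = c("species", "genus", "family"),
    max_frequency = c(smax, gmax, fmax),
    threshold = c(0.10, 0.20, 0.30),
    pass = c(smax < 0.10, gmax < 0.20, if (is.na(fmax)) NA else fmax < 0.30),
    stringsAsFactors = FALSE
  )
}

# one subsample draw of `size` trees without replacement from a count vector;
# returns the per-species counts of the draw
subsample_counts <- function(counts, size, individuals = NULL) {
  n <- sum(counts)
  if (is.null(individuals)) individuals <- rep.int(seq_along(counts), counts)
  tabulate(individuals[sample.int(n, size)], nbins = length(counts))
}

#' Monte-Carlo standardization of diversity to a common population size
#'
#' Repeatedly subsamples `target_size` trees without replacement and computes
#' the effective species count of each subsample; the mean over replicates
#' estimates diversity at the standardized population size, with a percentile
#' interval over replicates. Standard sizes used for cross-city comparison are
#' 37,000 trees (all species) and 10,000 trees (naturally occurring only);
#' park-vs-urban comparisons use the smaller stratum size.
#'
#' When `target_size` exceeds the community size the community cannot be
#' rarefied; the estimate falls back to resampling with replacement and the
#' result is flagged `extrapolated = TRUE` (interpret with care).
#'
#' @param abund species abundance.
#' @param target_size standardized number of trees (>= 1).
#' @param reps Monte-Carlo replicates.
#' @param seed RNG seed (the whole computation is deterministic given it).
#' @return object of class `standardized_diversity`: `estimate`, `ci95`,
#'   `per_rep`, `target_size`, `reps`, `extrapolated`.
#' @export
standardized_diversity <- function(abund, target_size, reps = 500, seed = NULL) {
  abund <- as_species_abundance(abund)
  if (is_empty_abundance(abund)) stop("empty species abundance")
  target_size <- as.integer(target_size)
  if (target_size < 1L) stop("target_size must be >= 1")
  reps <- as.integer(reps)
  stopifnot(reps >= 1L)
  counts <- as.integer(abund$counts)
  n <- sum(counts)
  extrapolated <- target_size > n
  per_rep <- with_seed(seed, {
    if (!extrapolated) {
      individuals <- rep.int(seq_along(counts), counts)
      vapply(seq_len(reps), function(r) {
        cs <- tabulate(individuals[sample.int(n, target_size)],
                       nbins = length(counts))
        shannon_es(cs[cs > 0])
      }, numeric(1))
    } else {
      p <- counts / n
      vapply(seq_len(reps), function(r) {
        cs <- tabulate(sample.int(length(counts), target_size, replace = TRUE,
                                  prob = p), nbins = length(counts))
        shannon_es(cs[cs > 0])
      }, numeric(1))
    }
  })
  structure(list(estimate = mean(per_rep),
                 ci95 = unname(stats::quantile(per_rep, c(0.025, 0.975))),
                 per_rep = per_rep, target_size = target_size, reps = reps,
                 extrapolated = extrapolated),
            class = "standardized_diversity")
}

#' @export
print.standardized_diversity <- function(x, ...) {
  cat(sprintf(
    "<standardized_diversity> %.2f effective species at n = %d (%d reps)%s\n",
    x$estimate, x$target_size, x$reps,
    if (x$extrapolated) " [extrapolated beyond community size]" else ""))
  cat(sprintf("  95%% interval over replicates: [%.2f, %.2f]\n",
              x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' Park versus urban diversity comparison
#'
#' For each city with trees in both green space and the built environment,
#' computes the standardized effective species count of each stratum at the
#' smaller stratum's size, then a paired t-test of park minus urban across
#' cities.
#'
#' @param inventories list of [inventory] objects.
#' @param reps Monte-Carlo replicates per stratum.
#' @param seed RNG seed.
#' @return object of class `park_urban_test`: per-city table, excluded cities
#'   with reasons, and the paired test (`t`, `df`, `p`, `mean_diff`, `ci95`).
#' @export
park_urban_comparison <- function(inventories, reps = 500, seed = NULL) {
  stopifnot(is.list(inventories), length(inventories) >= 1L)
  rows <- list(); excluded <- list()
  with_seed(seed, {
    for (inv in inventories) {
      city <- attr(inv, "city") %||% inv$city[1L]
      park <- species_abundance(inv, function(d) d$location_type == "green_space")
      urban <- species_abundance(inv, function(d) d$location_type == "built_environment")
      if (is_empty_abundance(park) || is_empty_abundance(urban)) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          city = city, reason = "missing park or urban stratum",
          stringsAsFactors = FALSE)
        next
      }
      target <- min(park$n, urban$n)
      es_park <- standardized_diversity(park, target, reps = reps)$estimate
      es_urban <- standardized_diversity(urban, target, reps = reps)$estimate
      rows[[length(rows) + 1L]] <- data.frame(
        city = city, n_park = park$n, n_urban = urban$n, target_size = target,
        es_park = es_park, es_urban = es_urban, diff = es_park - es_urban,
        stringsAsFactors = FALSE)
    }
  })
  if (length(rows) < 2L)
    stop("paired comparison needs at least two cities with both strata")
  per_city <- do.call(rbind, rows)
  tt <- stats::t.test(per_city$es_park, per_city$es_urban, paired = TRUE)
  structure(list(per_city = per_city,
                 excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, mean_diff = unname(tt$estimate),
                 ci95 = as.numeric(tt$conf.int)),
            class = "park_urban_test")
}

#' @export
print.park_urban_test <- function(x, ...) {
  cat(sprintf(
    "<park_urban_test> %d cities: mean park - urban = %.2f effective species\n",
    nrow(x$per_city), x$mean_diff))
  cat(sprintf("  paired t = %.2f, df = %d, p = %.3g, 95%% CI [%.2f, %.2f]\n",
              x$t, x$df, x$p, x$ci95[1], x$ci95[2]))
  if (!is.null(x$excluded))
    cat(sprintf("  excluded: %s\n", paste(x$excluded$city, collapse = ", ")))
  invisible(x)
}
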