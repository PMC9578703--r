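#' Bootstrap clustering-by-species score of one spatial cluster
#'
#' Compares a spatial cluster's observed effective species count with its
#' expectation under random membership: `B` draws of the cluster's size from
#' the whole city's tree list (without replacement), effective species count
#' of each, and the ratio of observed to the median of those draws, as a
#' percentage. Values below 100% mean the cluster holds fewer effective
#' species than a random set of that size would — same-species aggregation.
#'
#' @param cluster_species character vector of the cluster members' species
#'   (or an [inventory] subset).
#' @param city_species the whole city's species vector (or [inventory]).
#' @param B bootstrap draws.
#' @param seed RNG seed.
#' @param orientation `"observed_over_expected"` (default; aggregation gives
#'   values < 100) or `"expected_over_observed"`.
#' @return one-row data frame: `size`, `observed_es`, `expected_es_mean`,
#'   `expected_es_median`, `expected_es_q25`, `expected_es_q75`, `ratio`
#'   (percent).
#' @export
cluster_homogenization_score <- function(cluster_species, city_species,
                                         B = 500L, seed = NULL,
                                         orientation = c("observed_over_expected",
                                                         "expected_over_observed")) {
  orientation <- match.arg(orientation)
  if (is.data.frame(cluster_species)) cluster_species <- cluster_species$scientific_name
  if (is.data.frame(city_species)) city_species <- city_species$scientific_name
  cluster_species <- cluster_species[cluster_species != "unknown"]
  city_species <- city_species[city_species != "unknown"]
  m <- length(cluster_species)
  if (m < 2L) stop("cluster must contain at least 2 trees")
  if (m > length(city_species))
    stop("cluster size exceeds the city's tree count")
  observed <- effective_species_count(species_abundance(cluster_species))
  sp_idx <- as.integer(factor(city_species))
  k <- max(sp_idx)
  n <- length(sp_idx)
  es_draws <- with_seed(seed, vapply(seq_len(B), function(b) {
    cs <- tabulate(sp_idx[sample.int(n, m)], nbins = k)
    shannon_es(cs[cs > 0])
  }, numeric(1)))
  expected <- stats::median(es_draws)
  ratio <- if (orientation == "observed_over_expected")
    100 * observed / expected else 100 * expected / observed
  data.frame(size = m, observed_es = observed,
             expected_es_mean = mean(es_draws),
             expected_es_median = expected,
             expected_es_q25 = unname(stats::quantile(es_draws, 0.25)),
             expected_es_q75 = unname(stats::quantile(es_draws, 0.75)),
             ratio = ratio)
}

#' City-level summary of clustering-by-species scores
#'
#' Median observed/expected ratio across a city's spatial clusters, with a
#' percentile bootstrap confidence interval of the median (resampling
#' clusters). A city is called significantly clustered by species when the
#' interval's upper bound is below 100%; cities with fewer than `min_clusters`
#' clusters are excluded as under-sampled.
#'
#' @param scores data frame of per-cluster scores (needs a `ratio` column) or
#'   a numeric ratio vector.
#' @param min_clusters minimum number of clusters for a usable summary.
#' @param boot_reps bootstrap resamples of the cluster set.
#' @param conf confidence level.
#' @param seed RNG seed.
#' @return object of class `city_clustering_summary`: `n_clusters`,
#'   `median_ratio`, `ci95`, `significant`, `excluded`, `exclusion_reason`.
#' @export
city_clustering_summary <- function(scores, min_clusters = 11L,
                                    boot_reps = 10000L, conf = 0.95,
                                    seed = NULL) {
  ratios <- if (is.data.frame(scores)) scores$ratio else as.numeric(scores)
  if (!length(ratios)) stop("no cluster scores supplied")
  nc <- length(ratios)
  med <- stats::median(ratios)
  alpha <- (1 - conf) / 2
  boot_med <- with_seed(seed, vapply(seq_len(boot_reps), function(b)
    stats::median(ratios[sample.int(nc, nc, replace = TRUE)]), numeric(1)))
  ci <- unname(stats::quantile(boot_med, c(alpha, 1 - alpha)))
  excluded <- nc < min_clusters
  structure(list(n_clusters = nc, median_ratio = med, ci95 = ci,
                 significant = !excluded && ci[2] < 100,
                 excluded = excluded,
                 exclusion_reason = if (excluded) "insufficient clusters" else NA_character_),
            class = "city_clustering_summary")
}

#' @export
print.city_clustering_summary <- function(x, ...) {
  cat(sprintf("<city_clustering_summary> %d clusters, median ratio %.1f%% [%.1f, %.1f]\n",
              x$n_clusters, x$median_ratio, x$ci95[1], x$ci95[2]))
  if (x$excluded) cat("  excluded:", x$exclusion_reason, "\n")
  else cat(sprintf("  significantly clustered by species: %s\n", x$significant))
  invisible(x)
}

#' Full clustering-by-species analysis of one city
#'
#' Projects, clusters ([cluster_trees()]), scores every non-noise cluster
#' ([cluster_homogenization_score()]) and summarizes
#' ([city_clustering_summary()]).
#'
#' @param inv an [inventory].
#' @param B bootstrap draws per cluster.
#' @param min_clusters,boot_reps summary settings.
#' @param seed RNG seed governing all resampling.
#' @param ... clustering parameters passed to [cluster_trees()].
#' @return list of class `city_clustering`: `assignment`, `scores` (one row
#'   per cluster), `summary`.
#' @export
city_clustering <- function(inv, B = 500L, min_clusters = 11L,
                            boot_reps = 10000L, seed = NULL, ...) {
  assignment <- cluster_trees(inv, ...)
  species <- inv$scientific_name
  out <- with_seed(seed, {
    scores <- lapply(seq_len(assignment$n_clusters), function(cl) {
      members <- which(!is.na(assignment$labels) & assignment$labels == cl)
      sc <- cluster_homogenization_score(species[members], species, B = B)
      cbind(cluster_id = cl, sc)
    })
    scores <- if (length(scores)) do.call(rbind, scores) else NULL
    summary <- if (!is.null(scores))
      city_clustering_summary(scores, min_clusters = min_clusters,
                              boot_reps = boot_reps)
    else NULL
    list(scores = scores, summary = summary)
  })
  structure(list(assignment = assignment, scores = out$scores,
                 summary = out$summary),
            class = "city_clustering")
}

#' @export
print.city_clustering <- function(x, ...) {
  print(x$assignment)
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}
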