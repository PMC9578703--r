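#' Default pipeline configuration
#'
#' Thresholds and replication settings for the full multi-city analysis:
#' standard population sizes 37,000 (all trees) and 10,000 (naturally
#' occurring), 500 bootstrap draws per cluster, 50 similarity subsamples,
#' cities excluded from sensitivity sets below 10,000 trees, below 50%
#' spatial coverage, or with fewer than 11 spatial clusters.
#'
#' @param ... overrides by name.
#' @return named list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    standard_size_all = 37000L,
    standard_size_native = 10000L,
    diversity_reps = 500L,
    cluster_boot = 500L,
    similarity_reps = 50L,
    min_trees = 10000L,
    min_coverage = 50,
    min_clusters = 11L,
    summary_boot = 10000L,
    cell_size = 0.005,
    min_cluster_size = 30L,
    min_samples = 10L,
    metric = "manhattan",
    cluster_selection_epsilon = 0.0004,
    run_clustering = TRUE,
    run_similarity = TRUE,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.null(names(over)) && is.list(over[[1L]]))
    over <- over[[1L]]
  cfg[names(over)] <- over
  cfg
}

read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("reading a config file requires the yaml package")
  pipeline_config(yaml::read_yaml(path))
}

#' Run the full multi-city analysis
#'
#' For each city: raw and standardized diversity, Santamour checks, nativity
#' summary, spatial coverage, and the clustering-by-species summary; across
#' cities: pairwise chi-square similarity under the all/native conditions,
#' the paired homogenization test, and (when a climate table is given) the
#' environmental-similarity correlation comparison. Failures in one city are
#' isolated and logged, not fatal. Deterministic under `config$seed`.
#'
#' @param inventories named list of [inventory] objects, or a directory of
#'   standardized city CSVs.
#' @param flora optional [nativity_table()] (or path) used to (re)label
#'   nativity; when absent, existing labels are used.
#' @param climate optional data frame (or CSV path) of per-city bioclim
#'   variables with a `city` column.
#' @param config list from [pipeline_config()] (or a YAML file path).
#' @param out_dir optional directory; when given, writes `city_summary.csv`,
#'   similarity matrices, and a JSON report.
#' @return object of class `canopy_run`: `city_summary` (data frame),
#'   `clustering`, `similarity` (matrices + tests), `failures`, `config`.
#' @export
run_pipeline <- function(inventories, flora = NULL, climate = NULL,
                         config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (is.character(inventories)) {
    paths <- list.files(inventories, pattern = "\\.csv$", full.names = TRUE)
    nm <- sub("\\.csv$", "", basename(paths))
    inventories <- stats::setNames(lapply(paths, function(p)
      tryCatch(read_inventory(p), error = function(e) e)), nm)
  }
  if (is.character(flora)) flora <- read_nativity_table(flora)
  if (is.character(climate)) climate <- utils::read.csv(climate)
  nm <- names(inventories) %||% paste0("city", seq_along(inventories))
  names(inventories) <- nm

  failures <- list(); rows <- list(); clustering <- list()
  seeds <- with_seed(config$seed,
                     sample.int(.Machine$integer.max, length(inventories)))
  for (i in seq_along(inventories)) {
    inv <- inventories[[i]]
    res <- tryCatch({
      if (inherits(inv, "error")) stop(conditionMessage(inv))
      abund <- species_abundance(inv)
      es_raw <- effective_species_count(abund)
      sd_all <- standardized_diversity(
        abund, min(config$standard_size_all, abund$n),
        reps = config$diversity_reps, seed = seeds[i])
      nat <- nativity_summary(inv, table = flora)
      nat_ab <- species_abundance(
        inv$scientific_name[nat$labels == "naturally_occurring"])
      sd_nat <- if (!is_empty_abundance(nat_ab)) standardized_diversity(
        nat_ab, min(config$standard_size_native, nat_ab$n),
        reps = config$diversity_reps, seed = seeds[i]) else NULL
      rule <- max_abundance_rule(abund)
      cov <- coverage_stats(grid_partition(inv, cell_size = config$cell_size))
      clus <- if (config$run_clustering) city_clustering(
        inv, B = config$cluster_boot, min_clusters = config$min_clusters,
        boot_reps = config$summary_boot, seed = seeds[i],
        min_cluster_size = config$min_cluster_size,
        min_samples = config$min_samples, metric = config$metric,
        cluster_selection_epsilon = config$cluster_selection_epsilon) else NULL
      list(row = data.frame(
        city = nm[i], state = attr(inv, "state"), n_trees = nrow(inv),
        n_species = length(abund$counts),
        effective_species = es_raw,
        effective_species_std = sd_all$estimate,
        std_size = sd_all$target_size,
        pct_native = nat$pct_native,
        effective_species_native_std =
          if (is.null(sd_nat)) NA_real_ else sd_nat$estimate,
        species_rule_pass = rule$pass[1], genus_rule_pass = rule$pass[2],
        pct_empty_cells = cov$pct_empty,
        coverage_skew = cov$skewness, coverage_kurtosis = cov$kurtosis,
        n_clusters = if (is.null(clus)) NA_integer_ else clus$summary$n_clusters %||% 0L,
        clustering_median_ratio =
          if (is.null(clus) || is.null(clus$summary)) NA_real_ else clus$summary$median_ratio,
        clustering_ci_low =
          if (is.null(clus) || is.null(clus$summary)) NA_real_ else clus$summary$ci95[1],
        clustering_ci_high =
          if (is.null(clus) || is.null(clus$summary)) NA_real_ else clus$summary$ci95[2],
        clustering_significant =
          if (is.null(clus) || is.null(clus$summary)) NA else clus$summary$significant,
        clustering_excluded =
          if (is.null(clus) || is.null(clus$summary)) NA else clus$summary$excluded,
        low_sample = nrow(inv) < config$min_trees,
        low_coverage = cov$pct_empty > config$min_coverage,
        stringsAsFactors = FALSE), clus = clus)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[nm[i]]] <- conditionMessage(res)
    } else {
      rows[[length(rows) + 1L]] <- res$row
      clustering[[nm[i]]] <- res$clus
    }
  }
  city_summary <- if (length(rows)) do.call(rbind, rows) else NULL

  similarity <- NULL
  ok_inv <- inventories[nm %in% (city_summary$city %||% character(0))]
  if (isTRUE(config$run_similarity) && length(ok_inv) >= 2L) {
    sim_seed <- with_seed(config$seed + 1L, sample.int(.Machine$integer.max, 2L))
    m_all <- similarity_matrix(ok_inv, "all",
                               reps = config$similarity_reps, seed = sim_seed[1])
    m_nat <- similarity_matrix(ok_inv, "naturally_occurring",
                               reps = config$similarity_reps, seed = sim_seed[2])
    pair_ok <- !is.na(lower_tri(m_all)) & !is.na(lower_tri(m_nat))
    homog <- if (sum(pair_ok) >= 2L)
      homogenization_test(lower_tri(m_all)[pair_ok], lower_tri(m_nat)[pair_ok])
    else NULL
    env <- NULL
    if (!is.null(climate)) {
      climate_ok <- climate[match(names(ok_inv), climate$city), , drop = FALSE]
      if (!anyNA(climate_ok$city)) {
        es <- env_similarity(env_pca(climate_ok))
        keep <- pair_ok
        cmp <- tryCatch(
          correlation_comparison(lower_tri(es)[keep], lower_tri(m_nat)[keep],
                                 lower_tri(m_all)[keep]),
          error = function(e) conditionMessage(e))
        env <- list(matrix = es,
                    comparison = if (inherits(cmp, "correlation_comparison"))
                      cmp else NULL,
                    note = if (is.character(cmp)) cmp else NULL)
      }
    }
    similarity <- list(all = m_all, naturally_occurring = m_nat,
                       homogenization = homog, environment = env)
  }

  run <- structure(list(city_summary = city_summary, clustering = clustering,
                        similarity = similarity, failures = failures,
                        config = config),
                   class = "canopy_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(run$city_summary))
    utils::write.csv(run$city_summary,
                     file.path(out_dir, "city_summary.csv"), row.names = FALSE)
  if (!is.null(run$similarity)) {
    utils::write.csv(run$similarity$all,
                     file.path(out_dir, "similarity_all.csv"))
    utils::write.csv(run$similarity$naturally_occurring,
                     file.path(out_dir, "similarity_native.csv"))
  }
  report <- list(
    config = run$config,
    failures = run$failures,
    homogenization = if (!is.null(run$similarity$homogenization))
      unclass(run$similarity$homogenization),
    environment = if (!is.null(run$similarity$environment))
      unclass(run$similarity$environment$comparison))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.canopy_run <- function(x, ...) {
  n_ok <- if (is.null(x$city_summary)) 0L else nrow(x$city_summary)
  cat(sprintf("<canopy_run> %d cities analysed, %d failed\n",
              n_ok, length(x$failures)))
  if (n_ok) {
    cat(sprintf("  median effective species (std): %.1f; median %% native: %.1f\n",
                stats::median(x$city_summary$effective_species_std),
                stats::median(x$city_summary$pct_native, na.rm = TRUE)))
    sig <- x$city_summary$clustering_significant
    if (!all(is.na(sig)))
      cat(sprintf("  clustering by species significant in %d of %d usable cities\n",
                  sum(sig & !x$city_summary$clustering_excluded, na.rm = TRUE),
                  sum(!x$city_summary$clustering_excluded, na.rm = TRUE)))
  }
  if (!is.null(x$similarity$homogenization)) print(x$similarity$homogenization)
  invisible(x)
}
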