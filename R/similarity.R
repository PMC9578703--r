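#' Chi-square similarity between two frequency vectors
#'
#' One minus the chi-square distance between species-frequency vectors over
#' the union of species: \eqn{1 - \frac{1}{2}\sum_i (x_i - y_i)^2/(x_i +
#' y_i)}. 1 means identical composition, 0 disjoint species pools. Species
#' absent from both vectors are dropped (0/0 guard); each vector must sum
#' to 1.
#'
#' @param x,y numeric frequency vectors. If both are named they are aligned
#'   on the union of names (absent species get 0); unnamed vectors must have
#'   equal length and shared indexing.
#' @return similarity in `[0, 1]`, symmetric in `x` and `y`.
#' @export
chisq_similarity <- function(x, y) {
  if (inherits(x, "species_abundance")) x <- x$p
  if (inherits(y, "species_abundance")) y <- y$p
  if (!is.null(names(x)) && !is.null(names(y))) {
    sp <- union(names(x), names(y))
    xx <- stats::setNames(numeric(length(sp)), sp); xx[names(x)] <- x
    yy <- stats::setNames(numeric(length(sp)), sp); yy[names(y)] <- y
    x <- xx; y <- yy
  }
  stopifnot(length(x) == length(y))
  if (abs(sum(x) - 1) > 1e-6 || abs(sum(y) - 1) > 1e-6)
    stop("frequency vectors must each sum to 1")
  keep <- (x + y) > 0
  x <- x[keep]; y <- y[keep]
  1 - 0.5 * sum((x - y)^2 / (x + y))
}

filter_condition <- function(inv, condition) {
  switch(condition,
         all = inv$scientific_name,
         naturally_occurring = inv$scientific_name[inv$native_status == "naturally_occurring"],
         introduced = inv$scientific_name[inv$native_status == "introduced"],
         stop("unknown condition: ", condition))
}

#' Subsampling-standardized similarity between two city communities
#'
#' Filters both inventories to a nativity condition, then compares species
#' frequencies with [chisq_similarity()]. Unequal population sizes are
#' standardized by subsampling the larger community without replacement down
#' to the smaller one's size, `reps` times, reporting the median similarity
#' over repetitions (equal sizes are compared exactly, once).
#'
#' @param inv_a,inv_b [inventory] objects (or character species vectors).
#' @param condition `"all"`, `"naturally_occurring"` or `"introduced"`.
#' @param reps subsampling repetitions.
#' @param seed RNG seed.
#' @return object of class `similarity_result`: `similarity` (the median),
#'   `per_rep`, `condition`, `n_a`, `n_b`, `reps`, `comparable`.
#' @export
paired_city_similarity <- function(inv_a, inv_b,
                                   condition = c("all", "naturally_occurring",
                                                 "introduced"),
                                   reps = 50L, seed = NULL) {
  condition <- match.arg(condition)
  sp_a <- if (is.character(inv_a)) inv_a else filter_condition(inv_a, condition)
  sp_b <- if (is.character(inv_b)) inv_b else filter_condition(inv_b, condition)
  sp_a <- sp_a[sp_a != "unknown"]; sp_b <- sp_b[sp_b != "unknown"]
  out <- list(condition = condition, n_a = length(sp_a), n_b = length(sp_b),
              reps = reps)
  if (!length(sp_a) || !length(sp_b)) {
    out$comparable <- FALSE; out$similarity <- NA_real_; out$per_rep <- numeric(0)
    return(structure(out, class = "similarity_result"))
  }
  out$comparable <- TRUE
  freq <- function(sp) { t <- table(sp); stats::setNames(as.numeric(t) / length(sp), names(t)) }
  if (length(sp_a) == length(sp_b)) {
    out$similarity <- chisq_similarity(freq(sp_a), freq(sp_b))
    out$per_rep <- out$similarity
    return(structure(out, class = "similarity_result"))
  }
  if (length(sp_a) < length(sp_b)) { small <- sp_a; large <- sp_b }
  else { small <- sp_b; large <- sp_a }
  f_small <- freq(small)
  m <- length(small)
  out$per_rep <- with_seed(seed, vapply(seq_len(reps), function(r)
    chisq_similarity(f_small, freq(large[sample.int(length(large), m)])),
    numeric(1)))
  out$similarity <- stats::median(out$per_rep)
  structure(out, class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  if (!x$comparable)
    cat(sprintf("<similarity_result> [%s] incomparable (empty community)\n",
                x$condition))
  else
    cat(sprintf("<similarity_result> [%s] similarity %.3f (n = %d vs %d, %d reps)\n",
                x$condition, x$similarity, x$n_a, x$n_b, length(x$per_rep)))
  invisible(x)
}

#' Paired test for biotic homogenization
#'
#' Tests whether all-species community similarity exceeds naturally-occurring
#' similarity across the same city pairs: a paired t-test of the difference
#' (all minus native), backed by a Wilcoxon signed-rank test.
#'
#' @param all_scores,native_scores equal-length numeric vectors of per-pair
#'   similarities under the two conditions.
#' @return object of class `homogenization_test`: `mean_diff`, `t`, `df`,
#'   `p`, `ci95`, `wilcoxon` (statistic + p), `n_pairs`.
#' @export
homogenization_test <- function(all_scores, native_scores) {
  stopifnot(is.numeric(all_scores), is.numeric(native_scores))
  if (length(all_scores) != length(native_scores))
    stop("paired score vectors differ in length")
  n <- length(all_scores)
  if (n < 2L) stop("paired test needs at least 2 pairs (df >= 1)")
  d <- all_scores - native_scores
  if (stats::sd(d) == 0) {
    # degenerate but well-defined: identical scores give t = 0
    return(structure(list(mean_diff = mean(d),
                          t = if (mean(d) == 0) 0 else sign(mean(d)) * Inf,
                          df = n - 1L, p = if (mean(d) == 0) 1 else 0,
                          ci95 = rep(mean(d), 2),
                          wilcoxon = list(V = NA_real_,
                                          p = if (mean(d) == 0) 1 else 0),
                          n_pairs = n),
                     class = "homogenization_test"))
  }
  tt <- stats::t.test(all_scores, native_scores, paired = TRUE)
  wt <- suppressWarnings(stats::wilcox.test(all_scores, native_scores,
                                            paired = TRUE, exact = n <= 25))
  structure(list(mean_diff = unname(tt$estimate), t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 ci95 = as.numeric(tt$conf.int),
                 wilcoxon = list(V = unname(wt$statistic), p = wt$p.value),
                 n_pairs = n),
            class = "homogenization_test")
}

#' @export
print.homogenization_test <- function(x, ...) {
  cat(sprintf("<homogenization_test> %d pairs: mean(all - native) = %.4f\n",
              x$n_pairs, x$mean_diff))
  cat(sprintf("  paired t = %.2f, df = %d, p = %.3g, 95%% CI [%.4f, %.4f]\n",
              x$t, x$df, x$p, x$ci95[1], x$ci95[2]))
  cat(sprintf("  Wilcoxon signed-rank V = %.0f, p = %.3g\n",
              x$wilcoxon$V, x$wilcoxon$p))
  invisible(x)
}

#' PCA of city bioclimatic profiles
#'
#' Principal components of the 19 bioclimatic variables across cities,
#' centered and scaled to unit variance. Component signs are fixed by
#' orienting each component so its largest-magnitude loading is positive.
#'
#' @param climate data frame: `city` column plus numeric bioclim columns.
#' @return object of class `env_pca`: `scores` (cities x PCs), `loadings`,
#'   `sdev`, `cities`.
#' @export
env_pca <- function(climate) {
  stopifnot(is.data.frame(climate), "city" %in% names(climate))
  vars <- climate[, setdiff(names(climate), "city"), drop = FALSE]
  stopifnot(all(vapply(vars, is.numeric, logical(1))))
  keep <- vapply(vars, function(v) stats::sd(v) > 0, logical(1))
  if (!any(keep)) {
    # no variation at all: every city sits at the origin of PC space
    scores <- matrix(0, nrow(climate), 2,
                     dimnames = list(climate$city, c("PC1", "PC2")))
    return(structure(list(scores = scores,
                          loadings = matrix(0, ncol(vars), 2),
                          sdev = c(0, 0), cities = climate$city),
                     class = "env_pca"))
  }
  pc <- stats::prcomp(vars[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  rownames(pc$x) <- climate$city
  structure(list(scores = pc$x, loadings = pc$rotation, sdev = pc$sdev,
                 cities = climate$city),
            class = "env_pca")
}

#' Environmental similarity between cities
#'
#' One minus the normalized Euclidean distance between cities in principal-
#' component space (the first two components by default): the most dissimilar
#' pair scores exactly 0 and identical climates score 1.
#'
#' @param x an [env_pca()] result or a climate data frame.
#' @param n_pc number of components used for the distance (default 2).
#' @return symmetric similarity matrix with unit diagonal.
#' @export
env_similarity <- function(x, n_pc = 2L) {
  if (!inherits(x, "env_pca")) x <- env_pca(x)
  n_pc <- min(n_pc, ncol(x$scores))
  d <- as.matrix(stats::dist(x$scores[, seq_len(n_pc), drop = FALSE]))
  mx <- max(d)
  if (mx == 0) {
    warning("all cities have identical climate profiles; similarities all 1")
    sim <- matrix(1, nrow(d), ncol(d), dimnames = dimnames(d))
    return(sim)
  }
  sim <- 1 - d / mx
  diag(sim) <- 1
  sim
}

#' Compare two overlapping dependent correlations (Pearson-Filon z)
#'
#' Tests whether environmental similarity correlates more strongly with
#' naturally-occurring community similarity than with all-species community
#' similarity, across the same city pairs. The two correlations share the
#' environmental vector, so the comparison uses Pearson and Filon's z for
#' overlapping correlations from dependent groups, which accounts for the
#' correlation between the two community-similarity vectors.
#'
#' @param env_sim,chisq_native,chisq_all equal-length numeric vectors over
#'   the same city pairs (pass e.g. the lower triangles of the matrices).
#' @return object of class `correlation_comparison`: `r_env_native`,
#'   `r_env_all`, `r_native_all`, `z`, `p`, `n`, `low_n`.
#' @export
correlation_comparison <- function(env_sim, chisq_native, chisq_all) {
  n <- length(env_sim)
  stopifnot(length(chisq_native) == n, length(chisq_all) == n)
  if (stats::sd(env_sim) == 0 || stats::sd(chisq_native) == 0 ||
      stats::sd(chisq_all) == 0)
    stop("correlation undefined for a constant vector")
  r12 <- stats::cor(env_sim, chisq_native)   # env ~ native
  r13 <- stats::cor(env_sim, chisq_all)      # env ~ all
  r23 <- stats::cor(chisq_native, chisq_all) # native ~ all (the overlap)
  out <- list(r_env_native = r12, r_env_all = r13, r_native_all = r23, n = n)
  if (n < 4L) {
    out$low_n <- TRUE; out$z <- NA_real_; out$p <- NA_real_
    return(structure(out, class = "correlation_comparison"))
  }
  out$low_n <- FALSE
  k <- r23 * (1 - r12^2 - r13^2) -
    0.5 * r12 * r13 * (1 - r12^2 - r13^2 - r23^2)
  den <- (1 - r12^2)^2 + (1 - r13^2)^2 - 2 * k
  if (den <= .Machine$double.eps) {
    # collapses when the two community vectors coincide: no difference to test
    out$z <- if (abs(r12 - r13) < 1e-12) 0 else NA_real_
  } else {
    out$z <- sqrt(n) * (r12 - r13) / sqrt(den)
  }
  out$p <- 2 * stats::pnorm(-abs(out$z))
  structure(out, class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> n = %d pairs\n", x$n))
  cat(sprintf("  r(env, native) = %.3f; r(env, all) = %.3f; r(native, all) = %.3f\n",
              x$r_env_native, x$r_env_all, x$r_native_all))
  if (isTRUE(x$low_n)) cat("  too few pairs for a z test (n < 4)\n")
  else cat(sprintf("  Pearson-Filon z = %.3f, two-sided p = %.3g\n", x$z, x$p))
  invisible(x)
}

#' Pairwise similarity matrices for a set of cities
#'
#' @param inventories named list of [inventory] objects.
#' @param condition nativity condition (see [paired_city_similarity()]).
#' @param reps,seed subsampling settings.
#' @return symmetric matrix of median chi-square similarities (diagonal 1;
#'   `NA` where a pair is incomparable under the condition).
#' @export
similarity_matrix <- function(inventories, condition = "all", reps = 50L,
                              seed = NULL) {
  nm <- names(inventories) %||% paste0("city", seq_along(inventories))
  k <- length(inventories)
  m <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(m) <- 1
  with_seed(seed, {
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      s <- paired_city_similarity(inventories[[i]], inventories[[j]],
                                  condition = condition, reps = reps)
      m[i, j] <- m[j, i] <- s$similarity
    }
  })
  m
}

lower_tri <- function(m) m[lower.tri(m)]
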