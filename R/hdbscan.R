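#' Hierarchical density-based clustering (HDBSCAN*)
#'
#' Density-based clustering with noise: core distances at `min_samples`
#' neighbours, single-linkage over the mutual-reachability graph, condensation
#' of the hierarchy at `min_cluster_size`, and excess-of-mass (`eom`) cluster
#' extraction with an optional `cluster_selection_epsilon` merge threshold.
#' Low-density points are labelled 0 (noise).
#'
#' @param x numeric matrix (or data frame) of point coordinates, n x 2.
#' @param min_cluster_size smallest cluster size considered a cluster.
#' @param min_samples neighbourhood size for core distances.
#' @param metric `"manhattan"` (city-block; appropriate for street grids) or
#'   `"euclidean"`.
#' @param cluster_selection_epsilon clusters born below this distance are
#'   merged into their parent (same units as `x`).
#' @param cluster_selection_method only `"eom"` (excess of mass) is
#'   implemented.
#' @return object of class `hdbscan_fit`: `labels` (0 = noise, 1..k),
#'   `n_clusters`, `core_distances`, `params`.
#' @export
hdbscan <- function(x, min_cluster_size = 30L, min_samples = 10L,
                    metric = c("manhattan", "euclidean"),
                    cluster_selection_epsilon = 0,
                    cluster_selection_method = "eom") {
  metric <- match.arg(metric)
  stopifnot(cluster_selection_method == "eom")
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 2L, !anyNA(x))
  n <- nrow(x)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  min_samples <- max(1L, as.integer(min_samples))
  params <- list(min_cluster_size = min_cluster_size,
                 min_samples = min_samples, metric = metric,
                 cluster_selection_epsilon = cluster_selection_epsilon,
                 cluster_selection_method = cluster_selection_method)
  if (n < min_cluster_size) {
    warning("fewer points than min_cluster_size; all points labelled noise")
    return(structure(list(labels = rep(0L, n), n_clusters = 0L,
                          core_distances = rep(NA_real_, n), params = params),
                     class = "hdbscan_fit"))
  }
  mst <- mrd_mst_cpp(x, min_samples, metric == "manhattan")
  sl <- single_linkage(mst$from, mst$to, mst$weight, n)
  ct <- condense_tree(sl, n, min_cluster_size)
  labels <- extract_eom(ct, n, cluster_selection_epsilon)
  structure(list(labels = labels, n_clusters = max(labels),
                 core_distances = mst$core, params = params),
            class = "hdbscan_fit")
}

#' @export
print.hdbscan_fit <- function(x, ...) {
  cat(sprintf("<hdbscan_fit> %d points: %d cluster(s), %d noise\n",
              length(x$labels), x$n_clusters, sum(x$labels == 0L)))
  if (x$n_clusters > 0) print(table(cluster = x$labels[x$labels > 0]))
  invisible(x)
}

# Single-linkage dendrogram from MST edges. Node ids: 1..n are points,
# n+1..2n-1 internal merges in order of increasing height; returns child
# pointers, merge heights and subtree sizes.
single_linkage <- function(from, to, weight, n) {
  ord <- order(weight)
  from <- from[ord]; to <- to[ord]; weight <- weight[ord]
  parent <- seq_len(2L * n - 1L)          # union-find over node ids
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  childL <- integer(n - 1L); childR <- integer(n - 1L)
  height <- numeric(n - 1L); size <- c(rep(1L, n), integer(n - 1L))
  for (k in seq_len(n - 1L)) {
    ra <- find(from[k]); rb <- find(to[k])
    node <- n + k
    childL[k] <- ra; childR[k] <- rb
    height[k] <- weight[k]
    size[node] <- size[ra] + size[rb]
    parent[ra] <- node; parent[rb] <- node
  }
  list(childL = childL, childR = childR, height = height, size = size)
}

leaves_under <- function(sl, node, n) {
  out <- integer(0); stack <- node
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v <= n) out[length(out) + 1L] <- v
    else {
      k <- v - n
      stack <- c(stack, sl$childL[k], sl$childR[k])
    }
  }
  out
}

# Condense the single-linkage hierarchy: walking down from the root, a split
# is real only if both sides have >= min_cluster_size points; otherwise the
# small side "falls out" of the running cluster at lambda = 1/height.
# Returns, per cluster: parent, birth lambda, size; and per point: the cluster
# it fell out of and the lambda at which it left.
condense_tree <- function(sl, n, mcs) {
  root <- 2L * n - 1L
  cl_parent <- 0L; cl_birth <- 0; cl_size <- n  # cluster 1 = root cluster
  pt_cluster <- integer(n); pt_lambda <- numeric(n)
  n_cl <- 1L
  stack_node <- root; stack_cl <- 1L
  lam_of <- function(h) 1 / max(h, 1e-12)
  while (length(stack_node)) {
    i <- length(stack_node)
    node <- stack_node[i]; cl <- stack_cl[i]
    stack_node <- stack_node[-i]; stack_cl <- stack_cl[-i]
    if (node <= n) { # isolated point reached without a fall-out: leaves at inf
      pt_cluster[node] <- cl; pt_lambda[node] <- lam_of(0)
      next
    }
    k <- node - n
    l <- sl$childL[k]; r <- sl$childR[k]
    lam <- lam_of(sl$height[k])
    sL <- sl$size[l]; sR <- sl$size[r]
    if (sL >= mcs && sR >= mcs) {
      for (ch in c(l, r)) {
        n_cl <- n_cl + 1L
        cl_parent[n_cl] <- cl; cl_birth[n_cl] <- lam
        cl_size[n_cl] <- sl$size[ch]
        stack_node <- c(stack_node, ch); stack_cl <- c(stack_cl, n_cl)
      }
    } else if (sL < mcs && sR < mcs) {
      pts <- c(leaves_under(sl, l, n), leaves_under(sl, r, n))
      pt_cluster[pts] <- cl; pt_lambda[pts] <- lam
    } else {
      small <- if (sL < mcs) l else r
      big <- if (sL < mcs) r else l
      pts <- leaves_under(sl, small, n)
      pt_cluster[pts] <- cl; pt_lambda[pts] <- lam
      stack_node <- c(stack_node, big); stack_cl <- c(stack_cl, cl)
    }
  }
  list(parent = cl_parent, birth = cl_birth, size = cl_size,
       pt_cluster = pt_cluster, pt_lambda = pt_lambda, n_clusters = n_cl)
}

# Excess-of-mass cluster selection over the condensed tree (the root cluster
# itself is never selected), then epsilon merging, then point labels.
extract_eom <- function(ct, n, epsilon = 0) {
  m <- ct$n_clusters
  if (m == 1L) return(rep(0L, n))
  # stability: points leaving + children splitting off, relative to birth
  stability <- numeric(m)
  for (p in seq_len(n))
    stability[ct$pt_cluster[p]] <- stability[ct$pt_cluster[p]] +
      (ct$pt_lambda[p] - ct$birth[ct$pt_cluster[p]])
  if (m > 1L) for (c in 2:m) {
    par <- ct$parent[c]
    stability[par] <- stability[par] + ct$size[c] * (ct$birth[c] - ct$birth[par])
  }
  children <- split(seq_len(m)[-1L], ct$parent[-1L])
  s_star <- numeric(m); selected <- logical(m)
  for (c in m:1) {
    ch <- children[[as.character(c)]]
    if (is.null(ch)) { s_star[c] <- stability[c]; selected[c] <- TRUE; next }
    cs <- sum(s_star[ch])
    if (c != 1L && stability[c] >= cs) {
      s_star[c] <- stability[c]; selected[c] <- TRUE
    } else s_star[c] <- cs
  }
  # keep only selection roots (no selected proper ancestor)
  has_sel_anc <- function(c) {
    c <- ct$parent[c]
    while (c != 0L) { if (selected[c]) return(TRUE); c <- ct$parent[c] }
    FALSE
  }
  for (c in seq_len(m)) if (selected[c] && has_sel_anc(c)) selected[c] <- FALSE
  # epsilon merging: a selected cluster born closer than epsilon is replaced
  # by its highest ancestor still born below epsilon (never the root cluster)
  if (epsilon > 0) {
    sel <- which(selected)
    for (c in sel) {
      eps_c <- 1 / ct$birth[c]
      if (eps_c >= epsilon) next
      cur <- c
      repeat {
        par <- ct$parent[cur]
        if (par == 0L || par == 1L) break
        cur <- par
        if (1 / ct$birth[cur] >= epsilon) break
      }
      selected[c] <- FALSE
      selected[cur] <- TRUE
    }
    for (c in seq_len(m)) if (selected[c] && has_sel_anc(c)) selected[c] <- FALSE
  }
  sel <- which(selected)
  if (!length(sel)) return(rep(0L, n))
  # map every cluster to its selected ancestor-or-self, if any
  assign_to <- integer(m)
  for (c in seq_len(m)) {
    cur <- c
    while (cur != 0L && !(cur %in% sel)) cur <- ct$parent[cur]
    assign_to[c] <- if (cur == 0L) 0L else match(cur, sel)
  }
  labels <- assign_to[ct$pt_cluster]
  as.integer(labels)
}

#' Cluster a city's trees in planar space
#'
#' Projects valid coordinates to UTM and runs [hdbscan()] with the street-tree
#' defaults (`min_cluster_size = 30`, `min_samples = 10`, Manhattan metric,
#' excess-of-mass selection). Noise trees are excluded from downstream
#' cluster scoring.
#'
#' @param inv an [inventory].
#' @param min_cluster_size,min_samples,metric,cluster_selection_epsilon,cluster_selection_method
#'   passed to [hdbscan()].
#' @return object of class `cluster_assignment`: `labels` (length n_trees; 0 =
#'   noise, NA = invalid coordinates), `n_clusters`, `fit`, `params`.
#' @export
cluster_trees <- function(inv, min_cluster_size = 30L, min_samples = 10L,
                          metric = "manhattan",
                          cluster_selection_epsilon = 0.0004,
                          cluster_selection_method = "eom") {
  pts <- inventory_planar(inv)
  fit <- hdbscan(cbind(pts$easting, pts$northing),
                 min_cluster_size = min_cluster_size,
                 min_samples = min_samples, metric = metric,
                 cluster_selection_epsilon = cluster_selection_epsilon,
                 cluster_selection_method = cluster_selection_method)
  labels <- rep(NA_integer_, nrow(inv))
  labels[pts$row] <- fit$labels
  structure(list(labels = labels, n_clusters = fit$n_clusters, fit = fit,
                 params = fit$params),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("<cluster_assignment> %d clusters; %d noise; %d unlocated\n",
              x$n_clusters, sum(x$labels == 0L, na.rm = TRUE),
              sum(is.na(x$labels))))
  invisible(x)
}
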