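#' Silhouette widths for a cluster assignment
#'
#' For item i with mean intra-cluster distance a(i) and minimum over other
#' clusters of the mean distance b(i), the silhouette is
#' \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))}. Items in singleton
#' clusters get s = 0 by convention. Euclidean distance on the profile rows.
#'
#' @param profiles Numeric matrix, one row per item.
#' @param assignment Integer cluster indices, one per row.
#' @return Numeric vector of silhouette widths in \[-1, 1\].
#' @export
silhouette_widths <- function(profiles, assignment) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (length(assignment) != n) abort("one cluster index per profile row required")
  if (length(unique(assignment)) < 2L) {
    abort("silhouette undefined for a single cluster")
  }
  D <- as.matrix(dist(profiles))
  if (all(D == 0)) abort("all profiles identical: silhouette degenerate")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(assignment == assignment[i]), i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a_i <- mean(D[i, own])
    b_i <- min(vapply(setdiff(unique(assignment), assignment[i]),
                      function(k) mean(D[i, assignment == k]), numeric(1)))
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  s
}

# One k-means run with random-point initialization (Lloyd, 300 iterations).
# Runs that converge to fewer than k non-empty clusters or fail on duplicate
# initial centers are re-initialized with the next derived seed.
kmeans_run <- function(profiles, k, seed) {
  n <- nrow(profiles)
  for (try in 0:99) {
    km <- withr::with_seed(derive_seed(seed, "kmeans-retry", try), {
      centers <- profiles[sample.int(n, k), , drop = FALSE]
      tryCatch(
        suppressWarnings(kmeans(profiles, centers = centers,
                                iter.max = 300L, algorithm = "Lloyd")),
        error = function(e) NULL)
    })
    if (!is.null(km) && length(unique(km$cluster)) == k) {
      if (try > 0) {
        inform(sprintf("k-means re-initialized %d time(s) (degenerate run)", try))
      }
      return(km$cluster)
    }
  }
  abort("k-means failed to produce k non-empty clusters after 100 restarts")
}

#' Consensus k-means stability of correlation profiles
#'
#' Runs k-means (`n_runs` random initializations, seeds derived from one
#' master seed), computes silhouette widths per run, and averages each
#' item's silhouette across runs. The consensus assignment is the run with
#' the highest overall mean silhouette. Clusters whose members' mean
#' (across-run) silhouette is at or above `threshold` are deemed stable, and
#' their members are retained.
#'
#' @param profiles Numeric matrix, one row per item (row names used as item
#'   labels).
#' @param k Number of clusters, `2 <= k < nrow(profiles)`.
#' @param n_runs Number of clustering runs (default 50).
#' @param threshold Stability threshold on the cluster mean silhouette
#'   (default 0.2).
#' @param seed Master seed; the same seed reproduces the result exactly.
#' @return A `stability_result` with per-item mean silhouettes, consensus
#'   assignment, per-cluster means, stable cluster ids and retained items.
#'   See [tidy.stability_result()] and [glance.stability_result()].
#' @export
consensus_stability <- function(profiles, k, n_runs = 50L, threshold = 0.2,
                                seed = 1L) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (is.null(rownames(profiles))) rownames(profiles) <- paste0("item", seq_len(n))
  if (k < 2L || k >= n) abort("k must satisfy 2 <= k < number of items")
  assignments <- matrix(NA_integer_, n, n_runs,
                        dimnames = list(rownames(profiles), NULL))
  sils <- matrix(NA_real_, n, n_runs)
  for (r in seq_len(n_runs)) {
    cl <- kmeans_run(profiles, k, derive_seed(seed, "stability-run", r))
    assignments[, r] <- cl
    sils[, r] <- silhouette_widths(profiles, cl)
  }
  mean_sil <- rowMeans(sils)
  best_run <- which.max(colMeans(sils))
  consensus <- assignments[, best_run]
  cluster_means <- tapply(mean_sil, consensus, mean)
  stable <- as.integer(names(cluster_means)[cluster_means >= threshold])
  retained <- rownames(profiles)[consensus %in% stable]
  structure(list(
    items = rownames(profiles),
    k = as.integer(k), n_runs = as.integer(n_runs),
    threshold = threshold, seed = seed,
    assignments = assignments,
    mean_silhouette = setNames(mean_sil, rownames(profiles)),
    consensus_assignment = setNames(consensus, rownames(profiles)),
    cluster_mean_silhouette = cluster_means,
    stable_clusters = stable,
    retained_items = retained,
    best_run = best_run,
    overall_mean_silhouette = mean(mean_sil)
  ), class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("<stability_result> %d items, k = %d, %d runs, threshold %.2f\n",
              length(x$items), x$k, x$n_runs, x$threshold))
  cat(sprintf("  stable clusters: %d of %d; retained items: %d of %d\n",
              length(x$stable_clusters), length(x$cluster_mean_silhouette),
              length(x$retained_items), length(x$items)))
  cat(sprintf("  overall mean silhouette: %.3f\n", x$overall_mean_silhouette))
  invisible(x)
}

#' Select the number of clusters by mean silhouette
#'
#' Runs [consensus_stability()] for each k in `k_range` and returns the k
#' maximizing the overall mean of the items' across-run mean silhouettes;
#' ties break toward the smaller k.
#'
#' @inheritParams consensus_stability
#' @param k_range Candidate k values within `[2, nrow(profiles) - 1]`
#'   (default `2:8`).
#' @return The selected k (integer), with the per-k scan attached as
#'   attribute `"scan"`.
#' @export
select_k <- function(profiles, k_range = 2:8, n_runs = 50L, threshold = 0.2,
                     seed = 1L) {
  profiles <- as.matrix(profiles)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0L) abort("empty k range")
  k_range <- k_range[k_range >= 2L & k_range < nrow(profiles)]
  if (length(k_range) == 0L) abort("k range outside [2, items - 1]")
  scan <- purrr::map_dfr(k_range, function(k) {
    res <- consensus_stability(profiles, k, n_runs = n_runs,
                               threshold = threshold,
                               seed = derive_seed(seed, "select-k", k))
    tibble(k = k, mean_silhouette = res$overall_mean_silhouette)
  })
  best <- scan$k[which.max(scan$mean_silhouette)]
  structure(as.integer(best), scan = scan)
}

#' Average-linkage dendrogram of correlation profiles
#'
#' Agglomerative hierarchical clustering (average linkage, Euclidean
#' distance) for display ordering of the items, e.g. heatmap margins.
#'
#' @param profiles Numeric matrix, one row per item.
#' @return List with `order` (item labels in leaf order) and `hclust` (the
#'   merge tree).
#' @export
dendrogram_order <- function(profiles) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) abort("at least 2 items required")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("item", seq_len(nrow(profiles)))
  }
  hc <- hclust(dist(profiles), method = "average")
  list(order = rownames(profiles)[hc$order], hclust = hc)
}

#' Export a dendrogram as Newick
#'
#' @param dend Result of [dendrogram_order()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dend, path) {
  phy <- ape::as.phylo(dend$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Export a stability result as CSV and JSON
#'
#' Writes the per-item table (`<stem>.csv`) and a JSON summary
#' (`<stem>.json`) with k, threshold, number of runs, seed, and the
#' per-cluster mean silhouettes of stable and unstable clusters.
#'
#' @param x A `stability_result`.
#' @param stem Output path without extension.
#' @return The paths written, invisibly.
#' @export
write_stability_result <- function(x, stem) {
  p1 <- paste0(stem, ".csv")
  p2 <- paste0(stem, ".json")
  write.csv(tidy(x), p1, row.names = FALSE)
  jsonlite::write_json(list(
    k = x$k, n_runs = x$n_runs, threshold = x$threshold, seed = x$seed,
    n_clusters = length(x$cluster_mean_silhouette),
    n_stable_clusters = length(x$stable_clusters),
    n_retained = length(x$retained_items),
    cluster_mean_silhouette = as.list(x$cluster_mean_silhouette)
  ), p2, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2))
}
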