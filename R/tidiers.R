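#' Tidy a stability result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return Tibble with one row per item: `item`, `mean_silhouette`,
#'   `consensus_cluster`, `cluster_mean_silhouette`, `retained`.
#' @method tidy stability_result
#' @export
tidy.stability_result <- function(x, ...) {
  cl <- x$consensus_assignment
  tibble(
    item = x$items,
    mean_silhouette = unname(x$mean_silhouette),
    consensus_cluster = unname(cl),
    cluster_mean_silhouette =
      as.numeric(x$cluster_mean_silhouette[as.character(cl)]),
    retained = x$items %in% x$retained_items
  )
}

#' One-row summary of a stability result
#'
#' @param x A `stability_result`.
#' @param ... Unused.
#' @return One-row tibble: k, runs, threshold, seed, cluster counts,
#'   retained count, overall mean silhouette.
#' @method glance stability_result
#' @export
glance.stability_result <- function(x, ...) {
  tibble(
    k = x$k, n_runs = x$n_runs, threshold = x$threshold, seed = x$seed,
    n_clusters = length(x$cluster_mean_silhouette),
    n_stable_clusters = length(x$stable_clusters),
    n_items = length(x$items),
    n_retained = length(x$retained_items),
    overall_mean_silhouette = x$overall_mean_silhouette
  )
}

#' Per-repetition metrics of a model evaluation
#'
#' @param x A `model_eval`.
#' @param ... Unused.
#' @return Tibble with one row per repetition: `repetition`,
#'   `balanced_accuracy`, `auc`, `seed`.
#' @method tidy model_eval
#' @export
tidy.model_eval <- function(x, ...) {
  x$per_rep
}

#' One-row summary of a model evaluation
#'
#' @param x A `model_eval`.
#' @param ... Unused.
#' @return One-row tibble with target, predictors, medians and quartiles of
#'   balanced accuracy and AUC over the repetitions.
#' @method glance model_eval
#' @export
glance.model_eval <- function(x, ...) {
  tibble(
    target = x$target,
    predictors = paste(x$predictors, collapse = "+"),
    n_reps = x$n_reps,
    median_bacc = x$median_bacc, q1_bacc = x$q1_bacc, q3_bacc = x$q3_bacc,
    median_auc = x$median_auc, q1_auc = x$q1_auc, q3_auc = x$q3_auc,
    minority_fraction = x$minority_fraction
  )
}
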