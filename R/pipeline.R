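#' Configuration for an end-to-end pipeline run
#'
#' Either a synthetic fixture name or a set of input paths (feature table,
#' expression matrix, cell fractions, registry) must be supplied, not both.
#'
#' @param fixture Synthetic fixture name (see [make_fixture()]), or `NULL`.
#' @param features,expression,cell_fractions,registry Input file paths
#'   (TSV/TSV/CSV/YAML), used when `fixture` is `NULL`.
#' @param stability_runs Clustering runs per k (default 50).
#' @param stability_threshold Silhouette stability threshold (default 0.2).
#' @param k_range Candidate cluster numbers (default 2:8).
#' @param n_reps Holdout repetitions per model (default 100).
#' @param test_fraction Test proportion (default 0.2).
#' @param kernel,cost SVM settings (default linear, C = 1).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param min_fraction Minority-class gate (default 0.10).
#' @param master_seed Seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fixture = "paper_scale",
                            features = NULL, expression = NULL,
                            cell_fractions = NULL, registry = NULL,
                            stability_runs = 50L, stability_threshold = 0.2,
                            k_range = 2:8,
                            n_reps = 100L, test_fraction = 0.2,
                            kernel = "linear", cost = 1, smote_k = 5L,
                            min_fraction = 0.10,
                            master_seed = 1L) {
  paths <- list(features = features, expression = expression,
                cell_fractions = cell_fractions, registry = registry)
  has_paths <- any(!vapply(paths, is.null, logical(1)))
  if (!is.null(fixture) && has_paths) {
    abort("supply either a fixture name or input paths, not both")
  }
  if (is.null(fixture) && !all(!vapply(paths, is.null, logical(1)))) {
    abort("without a fixture, all four input paths are required")
  }
  structure(list(fixture = fixture, paths = paths,
                 stability_runs = as.integer(stability_runs),
                 stability_threshold = stability_threshold,
                 k_range = as.integer(k_range),
                 n_reps = as.integer(n_reps),
                 test_fraction = test_fraction,
                 kernel = kernel, cost = cost, smote_k = as.integer(smote_k),
                 min_fraction = min_fraction,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(config) {
  if (!is.null(config$fixture)) {
    cohort <- make_fixture(config$fixture, seed = config$master_seed)
    return(list(features = cohort$features, expression = cohort$expression,
                cell_fractions = cohort$cell_fractions,
                registry = cohort$registry))
  }
  p <- config$paths
  for (f in unlist(p)) if (!file.exists(f)) abort(sprintf("input not found: %s", f))
  list(
    features = as_tibble(utils::read.delim(p$features, check.names = FALSE)),
    expression = as_tibble(utils::read.delim(p$expression, check.names = FALSE)),
    cell_fractions = as_tibble(utils::read.csv(p$cell_fractions,
                                               check.names = FALSE)),
    registry = read_signature_registry(p$registry)
  )
}

#' Run the full radiogenomic association pipeline
#'
#' Stages, in order: radiomic scoring, gene signature scoring, radiomic-gene
#' Spearman correlation, consensus-silhouette stability filtering of the
#' gene signatures (with k selected by mean silhouette over `k_range`),
#' dichotomization of the retained signatures, the minority-class gate,
#' single-signature and combined radiomic SVM models for every gated target,
#' and radiomic-cell-fraction correlation. Any stage failure aborts with the
#' stage name.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_run` containing every intermediate artifact plus a
#'   reproducibility manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)))
    })
  }
  inputs <- stage("load", load_pipeline_inputs(config))
  registry <- inputs$registry

  census <- stage("census", census_features(registry))
  r_scores <- stage("radiomic-scoring",
                    score_radiomic(inputs$features, registry))
  g_scores <- stage("gene-scoring", score_genes(inputs$expression, registry))

  rg_cor <- stage("correlation", cross_correlate(g_scores, r_scores))
  profiles <- stage("profiles", correlation_profiles(rg_cor))

  k <- stage("select-k", select_k(profiles, k_range = config$k_range,
                                  n_runs = config$stability_runs,
                                  threshold = config$stability_threshold,
                                  seed = derive_seed(config$master_seed,
                                                     "pipeline-k")))
  stability <- stage("stability", consensus_stability(
    profiles, k = as.integer(k), n_runs = config$stability_runs,
    threshold = config$stability_threshold,
    seed = derive_seed(config$master_seed, "pipeline-stability")))
  retained <- stability$retained_items

  dend <- stage("dendrogram", dendrogram_order(profiles))

  labels <- stage("dichotomize", dichotomize_scores(
    g_scores[c("patient_id", retained)], registry = registry))
  gate <- stage("gate", gate_targets(labels, config$min_fraction))
  targets <- gate$signature[gate$pass]

  models <- stage("models", {
    predictor_sets <- c(
      setNames(as.list(setdiff(names(r_scores), "patient_id")),
               setdiff(names(r_scores), "patient_id")),
      list(Comb = setdiff(names(r_scores), "patient_id")))
    purrr::map(setNames(targets, targets), function(tg) {
      y <- tibble(patient_id = labels$patient_id, label = labels[[tg]])
      purrr::imap(predictor_sets, function(preds, nm) {
        evaluate_model(r_scores, y, preds,
                       n_reps = config$n_reps,
                       test_fraction = config$test_fraction,
                       kernel = config$kernel, cost = config$cost,
                       smote_k = config$smote_k,
                       seed = derive_seed(config$master_seed,
                                          paste0("model-", tg, "-", nm)),
                       target = tg)
      })
    })
  })

  fraction_cor <- stage("fraction-correlation",
                        cross_correlate(r_scores, inputs$cell_fractions))

  manifest <- list(
    package_version = as.character(utils::packageVersion("radsig")),
    master_seed = config$master_seed,
    fixture = config$fixture,
    paths = config$paths,
    stability = list(k_selected = as.integer(k),
                     k_range = config$k_range,
                     n_runs = config$stability_runs,
                     threshold = config$stability_threshold),
    prediction = list(n_reps = config$n_reps,
                      test_fraction = config$test_fraction,
                      kernel = config$kernel, cost = config$cost,
                      smote_k = config$smote_k,
                      min_fraction = config$min_fraction)
  )

  structure(list(config = config, census = census,
                 radiomic_scores = r_scores, gene_scores = g_scores,
                 rg_cor = rg_cor, stability = stability,
                 k_selected = as.integer(k), dendrogram = dend,
                 retained = retained, labels = labels, gate = gate,
                 targets = targets, models = models,
                 fraction_cor = fraction_cor, manifest = manifest),
            class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>\n")
  cat(sprintf("  %d radiomic scores, %d gene scores, k = %d\n",
              ncol(x$radiomic_scores) - 1L, ncol(x$gene_scores) - 1L,
              x$k_selected))
  cat(sprintf("  retained gene signatures: %d; gated targets: %d\n",
              length(x$retained), length(x$targets)))
  cat(sprintf("  models fitted: %d\n",
              sum(lengths(x$models))))
  invisible(x)
}

#' Summary grid of model performance
#'
#' One row per metric and target, one column per model (each radiomic
#' signature alone plus the combination), cells formatted
#' `"median (q1 q3)"` at 2 decimals. Full precision stays in the
#' `pipeline_run`.
#'
#' @param run A `pipeline_run`.
#' @return Tibble.
#' @export
summary_grid <- function(run) {
  stopifnot(inherits(run, "pipeline_run"))
  if (length(run$models) == 0L) {
    inform("no gated targets: empty summary grid")
    return(tibble(target = character(), metric = character()))
  }
  purrr::imap_dfr(run$models, function(models, tg) {
    fmt <- function(m, q1, q3) sprintf("%.2f (%.2f %.2f)", m, q1, q3)
    bacc <- purrr::map_chr(models, ~ fmt(.x$median_bacc, .x$q1_bacc, .x$q3_bacc))
    auc <- purrr::map_chr(models, ~ fmt(.x$median_auc, .x$q1_auc, .x$q3_auc))
    dplyr::bind_rows(
      tibble(target = tg, metric = "balanced_accuracy", !!!bacc),
      tibble(target = tg, metric = "auc", !!!auc))
  })
}

#' Write pipeline artifacts to a directory
#'
#' Persists scores, correlation tables, the stability result, per-repetition
#' model metrics, the Table-style summary grid, the dendrogram (Newick) and
#' the JSON manifest. Refuses to overwrite an existing non-empty directory
#' unless `force = TRUE`; a rerun with the same configuration and seed then
#' reproduces identical files.
#'
#' @param run A `pipeline_run`.
#' @param dir Output directory.
#' @param force Overwrite an existing non-empty directory.
#' @return `dir`, invisibly.
#' @export
render_report <- function(run, dir, force = FALSE) {
  stopifnot(inherits(run, "pipeline_run"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force) {
    abort(sprintf("output directory %s is not empty; use force = TRUE", dir))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = ",", row.names = FALSE, quote = FALSE)
  wcsv(run$radiomic_scores, "radiomic_scores.csv")
  wcsv(run$gene_scores, "gene_scores.csv")
  write_cor_tbl(run$rg_cor, file.path(dir, "rg_correlation"))
  write_cor_tbl(run$fraction_cor, file.path(dir, "fraction_correlation"))
  write_stability_result(run$stability, file.path(dir, "stability"))
  write_dendrogram_newick(run$dendrogram, file.path(dir, "dendrogram.nwk"))
  wcsv(run$gate, "minority_gate.csv")
  wcsv(dplyr::mutate(run$labels,
                     dplyr::across(-"patient_id", as.character)),
       "labels.csv")
  per_rep <- purrr::imap_dfr(run$models, function(models, tg) {
    purrr::imap_dfr(models, function(m, nm) {
      dplyr::mutate(m$per_rep, target = tg, model = nm, .before = 1L)
    })
  })
  if (nrow(per_rep)) wcsv(per_rep, "model_metrics_per_repetition.csv")
  wcsv(summary_grid(run), "model_summary_grid.csv")
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
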