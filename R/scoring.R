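#' Z-score columns of a feature table
#'
#' Standardizes the selected columns to mean 0 and sample SD 1 over their
#' non-missing entries. Zero-variance columns are mapped to all zeros with a
#' warning rather than producing NaN.
#'
#' @param features Tibble with a `patient_id` column and numeric feature
#'   columns.
#' @param columns Character vector of columns to transform; default all
#'   feature columns.
#' @return The feature table with the selected columns standardized.
#' @export
zscore_columns <- function(features, columns = NULL) {
  m <- table_to_matrix(features, "features")
  columns <- columns %||% colnames(m)
  missing <- setdiff(columns, colnames(m))
  if (length(missing)) {
    abort(sprintf("columns not in table: %s", paste(missing, collapse = ", ")))
  }
  for (cl in columns) {
    v <- m[, cl]
    ok <- is.finite(v)
    if (sum(ok) < 2L) {
      abort(sprintf("column %s has fewer than 2 non-missing values", cl))
    }
    s <- sd(v[ok])
    if (s == 0) {
      warn(sprintf("column %s has zero variance; z-scores set to 0", cl))
      m[ok, cl] <- 0
    } else {
      m[, cl] <- (v - mean(v[ok])) / s
    }
  }
  matrix_to_table(m)
}

#' Compute radiomic signature scores
#'
#' Each signature score is the linear combination
#' \eqn{s(p) = b_0 + \sum_t \beta_t x_t(p)} of its constituent features with
#' the published coefficients. Features enter raw when the signature's
#' normalization policy is `none` and column-z-scored when it is `zscore`.
#' Patients with a missing value in any constituent feature get a missing
#' score (no imputation).
#'
#' @param features Feature table: `patient_id` plus one column per feature,
#'   named by [feature_key()] i.e. `"modality|filter|feature"`.
#' @param registry A `sig_registry`.
#' @param signatures Radiomic signature ids to score; default all complete
#'   radiomic signatures.
#' @return Tibble: `patient_id` plus one numeric score column per signature.
#' @export
score_radiomic <- function(features, registry, signatures = NULL) {
  stopifnot(inherits(registry, "sig_registry"))
  defs <- registry$radiomic
  signatures <- signatures %||% defs$id[!defs$incomplete]
  unknown <- setdiff(signatures, defs$id)
  if (length(unknown)) {
    abort(sprintf("unknown radiomic signature: %s", paste(unknown, collapse = ", ")))
  }
  m <- table_to_matrix(features, "features")
  out <- tibble(patient_id = rownames(m))
  for (id in signatures) {
    i <- match(id, defs$id)
    if (defs$incomplete[i]) {
      abort(sprintf("signature %s is marked incomplete and cannot be scored", id))
    }
    terms <- defs$terms[[i]]
    keys <- feature_key(terms$modality, terms$image_filter, terms$feature_name)
    absent <- setdiff(keys, colnames(m))
    if (length(absent)) {
      abort(sprintf("signature %s: features missing from the table: %s",
                    id, paste(absent, collapse = ", ")))
    }
    x <- m[, keys, drop = FALSE]
    if (defs$normalization[i] == "zscore") {
      x <- apply(x, 2L, function(v) {
        ok <- is.finite(v)
        s <- sd(v[ok])
        if (is.na(s) || s == 0) {
          warn(sprintf("signature %s: zero-variance feature z-scored to 0", id))
          v[ok] <- 0
          v
        } else {
          (v - mean(v[ok])) / s
        }
      })
    }
    out[[id]] <- as.numeric(defs$intercept[i] + x %*% terms$coefficient)
  }
  out
}

#' Compute gene expression signature scores
#'
#' A gene signature score is the weighted sum of per-gene expression values,
#' genes keyed by EntrezID. Genes of the signature absent from the
#' expression matrix either abort the computation (`missing_policy =
#' "error"`) or are dropped with a message reporting the fraction dropped
#' (`"drop_gene"`). A signature all of whose genes are absent is an error
#' under both policies.
#'
#' @param expression Expression table: `entrez_id` column plus one numeric
#'   column per patient (log-scale expression).
#' @param registry A `sig_registry`.
#' @param signatures Gene signature ids to score; default all complete gene
#'   signatures.
#' @param missing_policy `"error"` or `"drop_gene"`.
#' @return Tibble: `patient_id` plus one numeric score column per signature.
#' @export
score_genes <- function(expression, registry, signatures = NULL,
                        missing_policy = c("drop_gene", "error")) {
  stopifnot(inherits(registry, "sig_registry"))
  missing_policy <- match.arg(missing_policy)
  if (!is.data.frame(expression) || !"entrez_id" %in% names(expression)) {
    abort("expression must be a data frame with an `entrez_id` column")
  }
  if (anyDuplicated(expression$entrez_id)) abort("duplicate EntrezIDs in expression")
  em <- as.matrix(expression[setdiff(names(expression), "entrez_id")])
  rownames(em) <- as.character(expression$entrez_id)
  defs <- registry$gene
  signatures <- signatures %||% defs$id[!defs$incomplete]
  unknown <- setdiff(signatures, defs$id)
  if (length(unknown)) {
    abort(sprintf("unknown gene signature: %s", paste(unknown, collapse = ", ")))
  }
  out <- tibble(patient_id = colnames(em))
  for (id in signatures) {
    i <- match(id, defs$id)
    if (defs$incomplete[i]) {
      abort(sprintf("gene signature %s is marked incomplete and cannot be scored", id))
    }
    genes <- defs$genes[[i]]
    present <- as.character(genes$entrez_id) %in% rownames(em)
    if (!any(present)) {
      abort(sprintf("gene signature %s: none of its genes are in the expression matrix", id))
    }
    if (any(!present)) {
      if (missing_policy == "error") {
        abort(sprintf("gene signature %s: EntrezIDs absent from expression: %s",
                      id, paste(genes$entrez_id[!present], collapse = ", ")))
      }
      inform(sprintf("gene signature %s: dropped %d/%d genes absent from expression (%.0f%%)",
                     id, sum(!present), nrow(genes),
                     100 * mean(!present)))
    }
    g <- genes[present, ]
    out[[id]] <- as.numeric(g$weight %*% em[as.character(g$entrez_id), , drop = FALSE])
  }
  out
}

#' Dichotomize signature scores into high/low classes
#'
#' Median rule: a patient is `high` iff the score is strictly greater than
#' the per-signature median (ties at the median go to `low`). Fixed rule:
#' `high` iff the score exceeds the given threshold. Rules default to each
#' signature's registry entry when a registry is supplied, and to the median
#' rule otherwise.
#'
#' @param scores Tibble: `patient_id` plus numeric score columns.
#' @param registry Optional `sig_registry` supplying per-signature threshold
#'   rules.
#' @param rules Optional named list overriding rules per signature: either
#'   `"median"` or a number (fixed threshold).
#' @return Tibble of the same shape with factor columns (`low`/`high`),
#'   carrying a `"thresholds"` attribute with the cutoffs used.
#' @export
dichotomize_scores <- function(scores, registry = NULL, rules = NULL) {
  m <- table_to_matrix(scores, "scores")
  out <- tibble(patient_id = rownames(m))
  thr <- numeric(0)
  for (sig in colnames(m)) {
    v <- m[, sig]
    if (anyNA(v)) abort(sprintf("missing scores for %s; cannot dichotomize", sig))
    rule <- rules[[sig]] %||% registry_threshold_rule(registry, sig) %||% "median"
    if (identical(rule, "median")) {
      cut <- median(v)
      if (sd(v) == 0) {
        warn(sprintf("%s: constant scores; all patients labelled low", sig))
      }
    } else if (is.numeric(rule)) {
      cut <- rule
    } else {
      abort(sprintf("%s: threshold rule must be `median` or a number", sig))
    }
    out[[sig]] <- factor(ifelse(v > cut, "high", "low"), levels = c("low", "high"))
    thr[sig] <- cut
  }
  attr(out, "thresholds") <- thr
  out
}

registry_threshold_rule <- function(registry, sig) {
  if (is.null(registry)) return(NULL)
  i <- match(sig, registry$gene$id)
  if (is.na(i)) return(NULL)
  if (registry$gene$threshold_rule[i] == "fixed") {
    registry$gene$threshold_value[i]
  } else {
    "median"
  }
}

#' Minority-class fractions of dichotomized labels
#'
#' @param labels Tibble from [dichotomize_scores()]: `patient_id` plus factor
#'   label columns.
#' @return Tibble with one row per signature: `signature`,
#'   `minority_fraction`, `minority_class`.
#' @export
minority_fractions <- function(labels) {
  sigs <- setdiff(names(labels), "patient_id")
  purrr::map_dfr(sigs, function(sig) {
    y <- labels[[sig]]
    n_high <- sum(y == "high")
    n_low <- sum(y == "low")
    tibble(signature = sig,
           minority_fraction = min(n_high, n_low) / length(y),
           minority_class = if (n_high <= n_low) "high" else "low")
  })
}
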