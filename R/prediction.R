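#' Minority-class gate for a dichotomized target
#'
#' A target qualifies for modeling only if its minority class comprises
#' strictly more than `min_fraction` of the cohort. Evaluated once on the
#' full cohort, before any train/test splitting.
#'
#' @param y Factor or character vector of binary labels.
#' @param min_fraction Gate fraction (default 0.10).
#' @return List with `pass` (logical) and `minority_fraction`.
#' @export
minority_gate <- function(y, min_fraction = 0.10) {
  y <- as.factor(y)
  if (length(y) == 0L) abort("empty label vector")
  counts <- table(factor(y, levels = levels(y)))
  frac <- min(counts) / length(y)
  list(pass = frac > min_fraction, minority_fraction = as.numeric(frac))
}

#' Apply the minority gate to every dichotomized signature
#'
#' @param labels Tibble from [dichotomize_scores()].
#' @param min_fraction Gate fraction (default 0.10).
#' @return Tibble: `signature`, `minority_fraction`, `pass`.
#' @export
gate_targets <- function(labels, min_fraction = 0.10) {
  mf <- minority_fractions(labels)
  dplyr::mutate(mf, pass = .data$minority_fraction > min_fraction)
}

#' Stratified train/test split
#'
#' Per class, `round(class_size * test_fraction)` patients (at least 1) go
#' to the test fold; the split is deterministic given the seed.
#'
#' @param y Binary factor labels.
#' @param test_fraction Test proportion in (0, 1) (default 0.2).
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.2, seed = 1L) {
  y <- as.factor(y)
  if (test_fraction <= 0 || test_fraction >= 1) abort("test_fraction must be in (0, 1)")
  counts <- table(y)
  if (any(counts < 2L)) {
    abort("each class needs at least 2 members to appear in both folds")
  }
  test <- withr::with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      idx <- which(y == cl)
      n_test <- max(1L, round(length(idx) * test_fraction))
      if (n_test >= length(idx)) {
        abort(sprintf("class %s too small for the requested test fraction", cl))
      }
      sample(idx, n_test)
    }), use.names = FALSE)
  })
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' SMOTE oversampling of the minority class
#'
#' Balances a binary training set by synthetic minority oversampling: each
#' synthetic sample is \eqn{x_i + u (x_{nn} - x_i)} with u ~ Uniform(0, 1)
#' and \eqn{x_{nn}} one of the k nearest minority neighbours (Euclidean) of
#' the minority point \eqn{x_i}. Original samples are preserved unchanged;
#' an already balanced input is returned as is. `k` is clamped to
#' minority count - 1 when larger, with a message.
#'
#' @param x Numeric matrix or data frame of predictors (rows = samples).
#' @param y Binary factor labels, one per row.
#' @param k Number of minority neighbours (default 5).
#' @param seed Integer seed.
#' @return List with `x` (matrix) and `y` (factor), classes exactly
#'   balanced; synthetic rows appended after the originals.
#' @export
smote_oversample <- function(x, y, k = 5L, seed = 1L) {
  x <- as.matrix(x)
  y <- as.factor(y)
  stopifnot(nrow(x) == length(y), nlevels(y) == 2L)
  counts <- table(y)
  n_needed <- abs(diff(as.integer(counts)))
  if (n_needed == 0L) return(list(x = x, y = y))
  minority <- names(counts)[which.min(counts)]
  min_idx <- which(y == minority)
  if (length(min_idx) < 2L) abort("SMOTE needs at least 2 minority samples")
  if (k > length(min_idx) - 1L) {
    inform(sprintf("SMOTE k clamped from %d to %d (minority size)",
                   k, length(min_idx) - 1L))
    k <- length(min_idx) - 1L
  }
  xm <- x[min_idx, , drop = FALSE]
  D <- as.matrix(dist(xm))
  diag(D) <- Inf
  nn <- apply(D, 1L, function(d) order(d)[seq_len(k)], simplify = FALSE)
  synth <- withr::with_seed(seed, {
    base_pick <- sample(seq_along(min_idx), n_needed, replace = TRUE)
    vals <- vapply(base_pick, function(i) {
      j <- nn[[i]][sample.int(k, 1L)]
      u <- runif(1)
      xm[i, ] + u * (xm[j, ] - xm[i, ])
    }, numeric(ncol(x)))
    if (is.matrix(vals)) t(vals) else matrix(vals, ncol = ncol(x))
  })
  colnames(synth) <- colnames(x)
  list(x = rbind(x, synth),
       y = factor(c(as.character(y), rep(minority, n_needed)),
                  levels = levels(y)))
}

#' Balanced accuracy
#'
#' Mean of sensitivity and specificity; the positive class is the second
#' factor level of `truth`.
#'
#' @param truth,pred Binary factors on the same levels.
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.factor(truth)
  pred <- factor(pred, levels = levels(truth))
  if (nlevels(truth) != 2L || any(table(truth) == 0L)) {
    abort("both classes must be present in truth")
  }
  pos <- levels(truth)[2L]
  sens <- mean(pred[truth == pos] == pos)
  spec <- mean(pred[truth != pos] != pos)
  (sens + spec) / 2
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Probability that a random positive outranks a random negative, ties
#' counted one half: computed over all positive-negative pairs from the
#' continuous scores. The positive class is the second factor level.
#'
#' @param scores Numeric decision scores (larger = more positive).
#' @param truth Binary factor labels.
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, truth) {
  truth <- as.factor(truth)
  if (nlevels(truth) != 2L || any(table(truth) == 0L)) {
    abort("both classes must be present in truth")
  }
  pos <- truth == levels(truth)[2L]
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(pos); n_neg <- sum(!pos)
  (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate a radiomic classifier of a dichotomized gene signature
#'
#' Repeated stratified holdout: for each repetition (seed derived from the
#' master seed), the cohort is split 80/20 preserving class proportions;
#' predictors are standardized with training-fold statistics; the training
#' fold (only) is rebalanced by SMOTE; a support vector machine is fitted
#' and applied to the untouched test fold; balanced accuracy is computed
#' from predicted labels and AUC from the decision values. Medians and
#' quartiles are aggregated over repetitions. No test-fold information
#' enters training.
#'
#' @param scores Radiomic score table: `patient_id` plus score columns.
#' @param labels Either a tibble with `patient_id` and `label` columns or a
#'   factor named by patient id.
#' @param predictors Character vector of score columns to use (length 1 for
#'   a single-signature model; all columns for the combined model).
#' @param n_reps Number of repetitions (default 100).
#' @param test_fraction Test proportion (default 0.2).
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost SVM cost parameter C (default 1).
#' @param smote_k SMOTE neighbour count (default 5).
#' @param seed Master seed.
#' @param target Optional label for the target signature (metadata only).
#' @return A `model_eval` object; see [tidy.model_eval()] and
#'   [glance.model_eval()].
#' @export
evaluate_model <- function(scores, labels, predictors, n_reps = 100L,
                           test_fraction = 0.2, kernel = c("linear", "radial"),
                           cost = 1, smote_k = 5L, seed = 1L, target = NULL) {
  kernel <- match.arg(kernel)
  m <- table_to_matrix(scores, "scores")
  missing_pred <- setdiff(predictors, colnames(m))
  if (length(missing_pred)) {
    abort(sprintf("predictors not in scores: %s",
                  paste(missing_pred, collapse = ", ")))
  }
  if (is.data.frame(labels)) {
    if (!all(c("patient_id", "label") %in% names(labels))) {
      abort("labels data frame needs `patient_id` and `label` columns")
    }
    y_all <- setNames(labels$label, labels$patient_id)
  } else {
    y_all <- labels
  }
  shared <- intersect(rownames(m), names(y_all))
  if (length(shared) < 10L) abort("fewer than 10 patients shared between scores and labels")
  x <- m[shared, predictors, drop = FALSE]
  y <- factor(as.character(y_all[shared]), levels = c("low", "high"))
  if (anyNA(x)) abort("missing predictor values among labelled patients")
  gate <- minority_gate(y)
  per_rep <- purrr::map_dfr(seq_len(n_reps), function(r) {
    rep_seed <- derive_seed(seed, "eval-rep", r)
    split <- tryCatch(
      stratified_split(y, test_fraction, seed = rep_seed),
      error = function(e) abort(sprintf("repetition %d: %s", r, conditionMessage(e))))
    x_tr <- x[split$train, , drop = FALSE]
    y_tr <- y[split$train]
    x_te <- x[split$test, , drop = FALSE]
    y_te <- y[split$test]
    # leakage-safe standardization: training-fold statistics only
    mu <- colMeans(x_tr)
    sdev <- apply(x_tr, 2L, sd)
    sdev[sdev == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2L, mu), 2L, sdev, "/")
    x_te <- sweep(sweep(x_te, 2L, mu), 2L, sdev, "/")
    bal <- smote_oversample(x_tr, y_tr, k = smote_k,
                            seed = derive_seed(seed, "eval-smote", r))
    fit <- e1071::svm(bal$x, bal$y, kernel = kernel, cost = cost,
                      scale = FALSE)
    pred <- predict(fit, x_te, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # orient decision values toward the `high` class
    dv_name <- colnames(dv)[1L]
    d <- if (identical(dv_name, "high/low")) dv[, 1L] else -dv[, 1L]
    tibble(repetition = r,
           balanced_accuracy = balanced_accuracy(y_te, pred),
           auc = auc_mw(d, y_te),
           seed = rep_seed)
  })
  q_bacc <- quantile(per_rep$balanced_accuracy, c(0.25, 0.5, 0.75))
  q_auc <- quantile(per_rep$auc, c(0.25, 0.5, 0.75))
  structure(list(
    target = target %||% NA_character_,
    predictors = predictors,
    kernel = kernel, cost = cost, smote_k = smote_k,
    n_reps = as.integer(n_reps), test_fraction = test_fraction, seed = seed,
    minority_fraction = gate$minority_fraction,
    per_rep = per_rep,
    median_bacc = unname(q_bacc[2L]), q1_bacc = unname(q_bacc[1L]),
    q3_bacc = unname(q_bacc[3L]),
    median_auc = unname(q_auc[2L]), q1_auc = unname(q_auc[1L]),
    q3_auc = unname(q_auc[3L])
  ), class = "model_eval")
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("<model_eval> target %s ~ %s (%s SVM, C = %g)\n",
              x$target, paste(x$predictors, collapse = " + "), x$kernel, x$cost))
  cat(sprintf("  %d repetitions, test fraction %.2f\n", x$n_reps, x$test_fraction))
  cat(sprintf("  balanced accuracy: %.2f (%.2f %.2f)\n",
              x$median_bacc, x$q1_bacc, x$q3_bacc))
  cat(sprintf("  AUC:               %.2f (%.2f %.2f)\n",
              x$median_auc, x$q1_auc, x$q3_auc))
  invisible(x)
}
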