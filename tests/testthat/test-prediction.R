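test_that("minority gate applies the strict 10% rule on the full cohort", {
  y <- factor(c(rep("high", 8), rep("low", 74)), levels = c("low", "high"))
  g <- minority_gate(y)
  expect_false(g$pass)  # 8/82 ~ 0.098 <= 0.10
  expect_equal(g$minority_fraction, 8 / 82)
  g2 <- minority_gate(factor(rep(c("high", "low"), each = 41)))
  expect_true(g2$pass)
  expect_error(minority_gate(factor(character(0))), "empty")

  labs <- tibble::tibble(patient_id = paste0("P", 1:82),
                         A = y, B = factor(rep(c("low", "high"), 41)))
  gt <- gate_targets(labs)
  expect_equal(gt$pass, c(FALSE, TRUE))
})

test_that("stratified splits have per-class rounded test counts and are reproducible", {
  y <- factor(c(rep("high", 40), rep("low", 42)))
  sp <- stratified_split(y, 0.2, seed = 3)
  expect_equal(sum(y[sp$test] == "high"), 8L)   # round(40 * .2)
  expect_equal(sum(y[sp$test] == "low"), 8L)    # round(42 * .2) = round(8.4)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, stratified_split(y, 0.2, seed = 3))

  yb <- factor(rep(c("a", "b"), each = 10))
  sp2 <- stratified_split(yb, 0.5, seed = 1)
  expect_equal(as.vector(table(yb[sp2$test])), c(5L, 5L))

  expect_error(stratified_split(factor(c("a", "a", "a", "b")), 0.2, seed = 1),
               "at least 2")
})

test_that("SMOTE balances classes along minority segments and preserves originals", {
  x <- withr::with_seed(1, matrix(rnorm(28), 14, 2))
  y <- factor(c(rep("low", 10), rep("high", 4)), levels = c("low", "high"))
  out <- smote_oversample(x, y, k = 3, seed = 5)
  expect_equal(as.vector(table(out$y)), c(10L, 10L))
  expect_equal(out$x[1:14, ], x)  # originals untouched
  # synthetic points lie within the minority bounding box (convex hull edge)
  synth <- out$x[15:20, , drop = FALSE]
  xm <- x[11:14, ]
  expect_true(all(synth[, 1] >= min(xm[, 1]) & synth[, 1] <= max(xm[, 1])))
  expect_true(all(synth[, 2] >= min(xm[, 2]) & synth[, 2] <= max(xm[, 2])))

  # balanced input returned unchanged
  yb <- factor(rep(c("low", "high"), 7))
  same <- smote_oversample(x, yb, seed = 1)
  expect_equal(same$x, x)
  expect_equal(same$y, yb)
})

test_that("with two minority points synthetics sit on their closed segment", {
  x <- rbind(matrix(0, 6, 2), c(1, 1), c(3, 5))
  y <- factor(c(rep("low", 6), "high", "high"), levels = c("low", "high"))
  expect_message(out <- smote_oversample(x, y, k = 5, seed = 2), "clamped")
  synth <- out$x[9:12, , drop = FALSE]
  p <- c(1, 1); q <- c(3, 5)
  for (i in seq_len(nrow(synth))) {
    s <- synth[i, ]
    expect_lt(abs(sqrt(sum((s - p)^2)) + sqrt(sum((s - q)^2)) -
                  sqrt(sum((p - q)^2))), 1e-9)
  }
  expect_error(smote_oversample(x[1:7, ], y[1:7], seed = 1), "at least 2")
})

test_that("balanced accuracy evaluates the sensitivity/specificity mean", {
  y <- factor(c(rep("high", 4), rep("low", 4)), levels = c("low", "high"))
  expect_equal(balanced_accuracy(y, y), 1)
  expect_equal(balanced_accuracy(y, factor(rep("low", 8), levels = levels(y))),
               0.5)
  # TP = 3, FN = 1, TN = 2, FP = 2
  pred <- factor(c("high", "high", "high", "low", "high", "high", "low", "low"),
                 levels = c("low", "high"))
  expect_equal(balanced_accuracy(y, pred), (0.75 + 0.5) / 2)
  expect_error(balanced_accuracy(factor(rep("low", 4), levels = levels(y)), y),
               "both classes")
})

test_that("AUC equals the Mann-Whitney pair probability, ties half-counted", {
  y <- factor(c("low", "low", "high", "high"), levels = c("low", "high"))
  expect_equal(auc_mw(c(1, 2, 3, 4), y), 1)
  expect_equal(auc_mw(c(4, 3, 2, 1), y), 0)
  expect_equal(auc_mw(c(1, 2, 2, 3), y), oracle_auc(c(1, 2, 2, 3), y))
  expect_equal(oracle_auc(c(1, 2, 2, 3), y), 0.875)
  for (s in 1:10) {
    v <- withr::with_seed(s, list(sc = sample(1:6, 12, TRUE),
                                  y = factor(sample(c("low", "high"), 12, TRUE),
                                             levels = c("low", "high"))))
    if (length(unique(v$y)) < 2) next
    expect_equal(auc_mw(v$sc, v$y), oracle_auc(v$sc, v$y))
    expect_equal(auc_mw(v$sc, v$y),
                 as.numeric(suppressMessages(pROC::auc(v$y, v$sc,
                                                       direction = "<"))))
  }
})

sep_fixture <- make_fixture("separable", seed = 4)
sep_scores <- sep_fixture$planted$radiomic_scores
sep_labels <- tibble::tibble(patient_id = sep_fixture$planted$labels$patient_id,
                             label = sep_fixture$planted$labels$G1)

test_that("evaluate_model is deterministic and self-consistent", {
  e1 <- evaluate_model(sep_scores, sep_labels, "R1", n_reps = 20, seed = 31,
                       target = "G1")
  e2 <- evaluate_model(sep_scores, sep_labels, "R1", n_reps = 20, seed = 31,
                       target = "G1")
  expect_identical(e1, e2)
  expect_equal(nrow(e1$per_rep), 20)
  expect_true(all(e1$per_rep$balanced_accuracy >= 0 &
                  e1$per_rep$balanced_accuracy <= 1))
  expect_true(all(e1$per_rep$auc >= 0 & e1$per_rep$auc <= 1))
  # medians/quartiles recomputable from the per-repetition records
  expect_equal(e1$median_auc, median(e1$per_rep$auc))
  expect_equal(e1$q1_bacc,
               unname(quantile(e1$per_rep$balanced_accuracy, 0.25)))
  expect_equal(glance(e1)$median_bacc, median(e1$per_rep$balanced_accuracy))
})

test_that("a separable target is learned and label permutation destroys it", {
  e <- evaluate_model(sep_scores, sep_labels, "R1", n_reps = 40, seed = 7)
  expect_gte(e$median_bacc, 0.95)
  expect_gte(e$median_auc, 0.98)
  # combined model with noise predictors stays within tolerance of the
  # single informative model
  ec <- evaluate_model(sep_scores, sep_labels, paste0("R", 1:7),
                       n_reps = 40, seed = 7)
  expect_gte(ec$median_auc, e$median_auc - 0.05)
  for (s in 1:3) {
    perm <- sep_labels
    perm$label <- withr::with_seed(s, sample(perm$label))
    en <- evaluate_model(sep_scores, perm, "R1", n_reps = 40, seed = s)
    expect_gte(en$median_auc, 0.3)
    expect_lte(en$median_auc, 0.7)
  }
})

test_that("evaluate_model validates its inputs", {
  expect_error(evaluate_model(sep_scores, sep_labels, "R99", n_reps = 2),
               "predictors")
  bad <- sep_labels[1:5, ]
  expect_error(evaluate_model(sep_scores, bad, "R1", n_reps = 2),
               "fewer than 10")
})
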