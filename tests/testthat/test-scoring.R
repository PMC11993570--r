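mk_features <- function(...) {
  vals <- list(...)
  tibble::tibble(patient_id = paste0("P", seq_along(vals[[1]])), !!!vals)
}

simple_registry <- function(terms_list, normalization = "none",
                            intercept = 0) {
  rad <- purrr::imap_dfr(terms_list, function(tt, id) {
    tibble::tibble(id = id, source = "t", normalization = normalization,
                   intercept = intercept, incomplete = FALSE,
                   terms = list(tt))
  })
  radsig:::new_registry(rad, radsig:::parse_gene_defs(NULL))
}

term <- function(name, coef, modality = "T2w", filter = "original") {
  tibble::tibble(modality = modality, image_filter = filter,
                 feature_class = "t", feature_name = name,
                 coefficient = coef)
}

test_that("z-scoring standardizes, zero variance maps to zero, shifts cancel", {
  ft <- mk_features(`T2w|original|a` = c(1, 2, 3), `T2w|original|b` = c(4, 4, 4))
  expect_warning(z <- zscore_columns(ft), "zero variance")
  expect_equal(mean(z$`T2w|original|a`), 0)
  expect_equal(sd(z$`T2w|original|a`), 1)
  expect_equal(z$`T2w|original|b`, c(0, 0, 0))

  shifted <- ft
  shifted$`T2w|original|a` <- shifted$`T2w|original|a` + 100
  expect_warning(z2 <- zscore_columns(shifted))
  expect_equal(z2$`T2w|original|a`, z$`T2w|original|a`)
})

test_that("radiomic scores are the published linear combination", {
  ft <- mk_features(`T2w|original|a` = c(3, 1, -2), `T2w|original|b` = c(1, 0, 5))
  # single term, coefficient 2, value 3 -> 6
  reg <- simple_registry(list(S = term("a", 2)))
  expect_equal(score_radiomic(ft, reg)$S, c(6, 2, -4))
  # all-zero coefficients -> intercept everywhere
  reg0 <- simple_registry(list(S = dplyr::bind_rows(term("a", 0), term("b", 0))),
                          intercept = 1.5)
  expect_equal(score_radiomic(ft, reg0)$S, rep(1.5, 3))
  # unresolvable term names every missing column
  regm <- simple_registry(list(S = term("zz", 1)))
  expect_error(score_radiomic(ft, regm), "zz")
  # incomplete signatures refuse to score
  regi <- simple_registry(list(S = term("a", 2)))
  regi$radiomic$incomplete <- TRUE
  expect_error(score_radiomic(ft, regi, "S"), "incomplete")
})

test_that("missing feature values propagate to missing scores", {
  ft <- mk_features(`T2w|original|a` = c(1, NA, 3))
  reg <- simple_registry(list(S = term("a", 1)))
  s <- score_radiomic(ft, reg)$S
  expect_true(is.na(s[2]))
  expect_equal(s[c(1, 3)], c(1, 3))
})

test_that("z-score normalization makes scores affine-invariant per column", {
  withr::with_seed(7, {
    ft <- mk_features(`T2w|original|a` = rnorm(10), `T2w|original|b` = rnorm(10))
  })
  reg <- simple_registry(list(S = dplyr::bind_rows(term("a", 1.3),
                                                   term("b", -0.4))),
                         normalization = "zscore")
  base <- score_radiomic(ft, reg)$S
  ft2 <- ft
  ft2$`T2w|original|a` <- 3 * ft2$`T2w|original|a` + 10
  ft2$`T2w|original|b` <- 0.5 * ft2$`T2w|original|b` - 2
  expect_equal(score_radiomic(ft2, reg)$S, base)
})

test_that("row permutation permutes scores identically", {
  withr::with_seed(8, ft <- mk_features(`T2w|original|a` = rnorm(6)))
  reg <- simple_registry(list(S = term("a", 2)))
  s1 <- score_radiomic(ft, reg)
  perm <- c(4, 2, 6, 1, 3, 5)
  s2 <- score_radiomic(ft[perm, ], reg)
  expect_equal(s2$S, s1$S[perm])
  expect_equal(s2$patient_id, s1$patient_id[perm])
})

gene_registry <- function(ids, weights, threshold = "median") {
  gen <- tibble::tibble(
    id = "G", source = "t", aggregation = "weighted_sum",
    threshold_rule = if (is.numeric(threshold)) "fixed" else threshold,
    threshold_value = if (is.numeric(threshold)) threshold else NA_real_,
    n_genes = length(ids), incomplete = FALSE,
    genes = list(tibble::tibble(entrez_id = ids, symbol = paste0("S", ids),
                                weight = weights)))
  radsig:::new_registry(radsig:::parse_radiomic_defs(NULL), gen)
}

test_that("gene signature scores are EntrezID-weighted sums", {
  expr <- tibble::tibble(entrez_id = c(10L, 20L), P1 = c(5, 2), P2 = c(1, 1))
  reg <- gene_registry(c(10L, 20L), c(1, -1))
  expect_equal(score_genes(expr, reg)$G, c(3, 0))
  reg0 <- gene_registry(c(10L, 20L), c(0, 0))
  expect_equal(score_genes(expr, reg0)$G, c(0, 0))
})

test_that("absent genes follow the missing policy", {
  expr <- tibble::tibble(entrez_id = c(10L, 20L), P1 = c(5, 2), P2 = c(1, 1))
  reg <- gene_registry(c(10L, 99L), c(1, 1))
  expect_error(score_genes(expr, reg, missing_policy = "error"), "99")
  expect_message(s <- score_genes(expr, reg, missing_policy = "drop_gene"),
                 "dropped 1/2")
  expect_equal(s$G, c(5, 1))
  reg_none <- gene_registry(c(98L, 99L), c(1, 1))
  expect_error(score_genes(expr, reg_none), "none of its genes")
})

test_that("dichotomization follows the median-tie and fixed-threshold rules", {
  sc <- tibble::tibble(patient_id = paste0("P", 1:5), S = c(1, 2, 3, 4, 5))
  lab <- dichotomize_scores(sc)
  expect_equal(sum(lab$S == "high"), 2L)  # ties at the median go low
  expect_equal(as.character(lab$S[4:5]), c("high", "high"))

  lab2 <- dichotomize_scores(sc, rules = list(S = 0))
  expect_true(all(lab2$S == "high"))

  const <- tibble::tibble(patient_id = paste0("P", 1:4), S = rep(2, 4))
  expect_warning(lab3 <- dichotomize_scores(const), "constant")
  expect_true(all(lab3$S == "low"))
})

test_that("median dichotomization is invariant to monotone transforms and balanced for even n", {
  for (s in 1:10) {
    x <- withr::with_seed(s, rnorm(20))
    sc <- tibble::tibble(patient_id = paste0("P", 1:20), S = x)
    lab <- dichotomize_scores(sc)$S
    expect_equal(sum(lab == "high"), sum(lab == "low"))
    sc2 <- sc
    sc2$S <- exp(3 * sc2$S)  # strictly increasing
    expect_equal(dichotomize_scores(sc2)$S, lab)
  }
})
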