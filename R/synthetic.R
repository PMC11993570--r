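# Synthetic cohort generator.
#
# Latent-factor model: each patient carries one prognostic factor f0, one
# factor per planted immune cluster (f1..fC), and two nuisance imaging
# factors. Radiomic scores load on f0 with the configured sign pattern
# (yielding the "one signature anti-correlated with the rest" archetype),
# on the cluster factors with fixed magnitudes, and on the nuisance
# factors. Planted gene signatures load on exactly one cluster factor;
# unclustered ("noise") signatures are placed on a fixed maximally-spread
# frame of latent directions so that, by design, they carry no mutual
# cluster structure. The feature table is built by inverse construction:
# one carrier feature per radiomic signature is solved so that the
# registry's linear combination reproduces the planted score exactly.

# Fixed design constants for the default archetype (7 radiomic signatures,
# 4 planted clusters). Chosen once by maximin spread of the planted center
# and noise-signature directions in correlation-profile space; see the
# methods vignette.
.center_signs <- matrix(c(
  +1, +1, +1, -1,
  -1,  0, +1, +1,
  -1,  0, -1, +1,
  -1, +1, +1, +1,
  -1, -1, +1, +1,
  -1, -1, +1, +1,
   0, +1, +1, +1), nrow = 7, byrow = TRUE)

.center_magnitudes <- matrix(c(
  0.30, 0.85, 0.592, 0.85, 0.85, 0.30, 0,
  0.325, 0, 0, 0.85, 0.448, 0.85, 0.30,
  0.777, 0.402, 0.85, 0.85, 0.30, 0.85, 0.30,
  0.85, 0.503, 0.30, 0.585, 0.30, 0.375, 0.85), nrow = 7)

.noise_frame <- matrix(c(
  -0.1012, 0.4756, 0.533, -0.3712, 0.5695, 0.0646, 0.1149,
  -0.1809, -0.236, -0.1471, -0.1542, -0.0201, 0.0429, -0.9295,
  0.1187, 0.1894, 0.422, 0.5387, -0.5729, 0.1238, 0.3717,
  -0.1906, 0.2012, -0.4232, -0.2238, 0.5667, -0.3164, 0.5223,
  -0.4374, 0.1013, -0.4792, 0.429, 0.3858, 0.1971, 0.4439,
  -0.0331, 0.4108, -0.0555, 0.2694, 0.3515, 0.3402, -0.7177,
  0.0215, 0.2304, 0.3942, 0.3351, 0.2458, 0.5236, 0.5867,
  -0.1053, -0.2378, 0.4047, -0.2133, -0.0166, 0.3836, 0.7587,
  -0.3005, -0.2677, 0.0761, 0.0467, -0.0792, 0.3257, -0.8472,
  -0.233, 0.3999, -0.1234, -0.0093, 0.6344, -0.5491, -0.2579,
  0.0533, -0.5677, 0.1894, -0.7411, 0.2326, 0.1597, -0.1013,
  -0.0899, -0.2789, 0.3557, -0.0252, 0.1793, 0.8342, 0.2427,
  -0.0274, -0.0852, -0.1626, -0.0653, 0.0049, 0.7324, -0.6518,
  0.1964, -0.1051, -0.1507, 0.0946, -0.5581, 0.779, -0.0173), nrow = 7)

.lm22_populations <- c(
  "B cells naive", "B cells memory", "Plasma cells", "T cells CD8",
  "T cells CD4 naive", "T cells CD4 memory resting",
  "T cells CD4 memory activated", "T cells follicular helper",
  "T cells regulatory (Tregs)", "T cells gamma delta", "NK cells resting",
  "NK cells activated", "Monocytes", "Macrophages M0", "Macrophages M1",
  "Macrophages M2", "Dendritic cells resting", "Dendritic cells activated",
  "Mast cells resting", "Mast cells activated", "Eosinophils", "Neutrophils")

#' Configuration for a synthetic radiogenomic cohort
#'
#' Defaults reproduce the study conditions the package is designed around:
#' 82 patients, 7 radiomic signatures with one anti-correlated to the rest,
#' 29 gene signatures of which 15 belong to 4 planted correlation-profile
#' clusters (sizes 5, 4, 3, 3) and 14 are unclustered, and 22 immune cell
#' populations on the simplex.
#'
#' @param n_patients Cohort size (default 82).
#' @param n_radiomic Number of radiomic signatures (default 7).
#' @param radiomic_sign_pattern Vector of +-1, one per radiomic signature
#'   (default: first negative, rest positive).
#' @param n_gene_signatures Number of gene signatures (default 29).
#' @param planted_sizes Sizes of the planted clusters (default
#'   `c(5, 4, 3, 3)`).
#' @param genes_per_signature Range of member-gene counts (default 3 to 31).
#' @param cross_corr_strength Loading of a planted gene signature score on
#'   its cluster factor (default 0.9).
#' @param score_noise_sd SD of the idiosyncratic noise on gene signature
#'   scores (default 0.22).
#' @param expr_noise_sd SD of the per-gene expression noise around the
#'   signature score (default 0.5).
#' @param radiomic_noise_sd SD of the idiosyncratic noise on radiomic scores
#'   (default 0.3).
#' @param prognostic_strength Loading of radiomic scores on the shared
#'   prognostic factor (default 0.8).
#' @param nuisance_strength Loading of radiomic scores on the two nuisance
#'   imaging factors (default 0.5).
#' @param noise_profile_radius Radius of the unclustered signatures'
#'   profiles relative to the planted center norm (default 1.0).
#' @param minority_fraction_range Range the per-signature minority class
#'   fraction is drawn from (default `c(0.15, 0.5)`).
#' @param n_extra_genes Unassigned noise genes in the expression matrix
#'   (default 50).
#' @param null_structure If `TRUE`, all systematic loadings are zeroed: no
#'   planted structure anywhere.
#' @param seed Master seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 82L, n_radiomic = 7L,
                          radiomic_sign_pattern = NULL,
                          n_gene_signatures = 29L,
                          planted_sizes = c(5L, 4L, 3L, 3L),
                          genes_per_signature = c(3L, 31L),
                          cross_corr_strength = 0.9,
                          score_noise_sd = 0.22,
                          expr_noise_sd = 0.5,
                          radiomic_noise_sd = 0.3,
                          prognostic_strength = 0.8,
                          nuisance_strength = 0.5,
                          noise_profile_radius = 1.0,
                          minority_fraction_range = c(0.15, 0.5),
                          n_extra_genes = 50L,
                          null_structure = FALSE,
                          seed = 1L) {
  radiomic_sign_pattern <- radiomic_sign_pattern %||%
    c(-1, rep(1, n_radiomic - 1L))
  stopifnot(length(radiomic_sign_pattern) == n_radiomic,
            all(radiomic_sign_pattern %in% c(-1, 1)),
            sum(planted_sizes) <= n_gene_signatures,
            cross_corr_strength >= 0, cross_corr_strength <= 1,
            minority_fraction_range[1] > 0,
            minority_fraction_range[2] <= 0.5)
  structure(list(
    n_patients = as.integer(n_patients),
    n_radiomic = as.integer(n_radiomic),
    radiomic_sign_pattern = radiomic_sign_pattern,
    n_gene_signatures = as.integer(n_gene_signatures),
    planted_sizes = as.integer(planted_sizes),
    genes_per_signature = as.integer(genes_per_signature),
    cross_corr_strength = cross_corr_strength,
    score_noise_sd = score_noise_sd,
    expr_noise_sd = expr_noise_sd,
    radiomic_noise_sd = radiomic_noise_sd,
    prognostic_strength = prognostic_strength,
    nuisance_strength = nuisance_strength,
    noise_profile_radius = noise_profile_radius,
    minority_fraction_range = minority_fraction_range,
    n_extra_genes = as.integer(n_extra_genes),
    null_structure = isTRUE(null_structure),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Latent loading matrix of the radiomic scores: columns (f0, f1..fC, v1, v2).
radiomic_loadings <- function(config) {
  k <- length(config$planted_sizes)
  p <- config$n_radiomic
  if (p == 7L && k == 4L) {
    A <- .center_signs * .center_magnitudes
  } else {
    A <- withr::with_seed(derive_seed(config$seed, "structure-A"), {
      signs <- matrix(sample(c(-1, 1), p * k, replace = TRUE), p, k)
      mags <- matrix(runif(p * k, 0.3, 0.85), p, k)
      signs * mags
    })
  }
  s <- config$radiomic_sign_pattern
  B <- cbind(A, s)
  V <- withr::with_seed(derive_seed(config$seed, "structure-V"), {
    out <- NULL
    for (i in 1:2) {
      r <- qr.resid(qr(cbind(B, out)), rnorm(p))
      nr <- sqrt(sum(r^2))
      out <- cbind(out, if (nr > 1e-8) r / nr else rnorm(p) * 0)
    }
    out
  })
  L <- cbind(config$prognostic_strength * s, A, config$nuisance_strength * V)
  if (config$null_structure) L[] <- 0
  L
}

# Latent directions of the unclustered gene signatures.
noise_directions <- function(config, n_factors) {
  n_noise <- config$n_gene_signatures - sum(config$planted_sizes)
  if (n_noise == 0L) return(matrix(0, n_factors, 0L))
  if (config$n_radiomic == 7L && length(config$planted_sizes) == 4L &&
      n_factors == 7L && n_noise <= 14L) {
    return(.noise_frame[, seq_len(n_noise), drop = FALSE])
  }
  withr::with_seed(derive_seed(config$seed, "structure-noise"), {
    u <- matrix(rnorm(n_factors * n_noise), n_factors)
    u %*% diag(1 / sqrt(colSums(u^2)), n_noise)
  })
}

#' Generate a synthetic radiogenomic cohort
#'
#' Produces a cohort with known ground truth: a radiomic feature table whose
#' registry signatures reproduce the planted radiomic scores exactly (by
#' inverse construction), an expression matrix whose member genes track the
#' planted gene signature scores, simplex-valued immune cell fractions
#' coupled to the latent factors, and a complete signature registry. All
#' planted quantities are returned for recovery testing.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` list: `features`, `expression`,
#'   `cell_fractions`, `registry`, `planted` (radiomic and gene scores,
#'   cluster memberships, labels, latent factors) and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  p <- config$n_radiomic
  k <- length(config$planted_sizes)
  n_gene <- config$n_gene_signatures
  n_noise <- n_gene - sum(config$planted_sizes)
  patients <- sprintf("P%03d", seq_len(n))
  r_ids <- paste0("R", seq_len(p))
  g_ids <- paste0("G", seq_len(n_gene))

  L <- radiomic_loadings(config)            # p x (1 + k + 2)
  n_fac <- ncol(L)
  sd_R <- sqrt(rowSums(L^2) + config$radiomic_noise_sd^2)

  seed_of <- function(stage) derive_seed(config$seed, stage)

  Fall <- withr::with_seed(seed_of("factors"),
                           matrix(rnorm(n * n_fac), n, n_fac))
  R <- Fall %*% t(L) +
    withr::with_seed(seed_of("radiomic-noise"),
                     matrix(rnorm(n * p, sd = config$radiomic_noise_sd), n, p))
  colnames(R) <- r_ids
  rownames(R) <- patients

  # planted gene signature scores
  cluster_of <- integer(n_gene)
  idx <- 1L
  for (c in seq_len(k)) {
    cluster_of[idx:(idx + config$planted_sizes[c] - 1L)] <- c
    idx <- idx + config$planted_sizes[c]
  }
  gamma <- config$cross_corr_strength
  G <- matrix(NA_real_, n, n_gene, dimnames = list(patients, g_ids))
  gnoise <- withr::with_seed(seed_of("gene-noise"),
                             matrix(rnorm(n * n_gene, sd = config$score_noise_sd),
                                    n, n_gene))
  # gene scores are kept at unit model variance: the scale of a signature
  # score is arbitrary, and unit variance keeps the expression-level
  # signal-to-noise uniform across signatures
  sd_planted <- sqrt(gamma^2 + config$score_noise_sd^2)
  for (j in seq_len(n_gene)) {
    if (cluster_of[j] > 0L) {
      G[, j] <- (gamma * Fall[, 1L + cluster_of[j]] + gnoise[, j]) / sd_planted
    }
  }
  if (n_noise > 0L) {
    U <- noise_directions(config, n_fac)
    rho_g <- gamma / sqrt(gamma^2 + config$score_noise_sd^2)
    gains <- vapply(seq_len(k), function(c) {
      u <- numeric(n_fac); u[1L + c] <- 1
      sqrt(sum(((L %*% u) / sd_R)^2))
    }, numeric(1))
    center_norm <- rho_g * mean(gains)
    radius <- withr::with_seed(seed_of("noise-radius"),
      (config$noise_profile_radius + rnorm(n_noise, sd = 0.04)) * center_norm)
    for (jj in seq_len(n_noise)) {
      j <- sum(config$planted_sizes) + jj
      d <- U[, jj]
      if (config$null_structure || sum(abs(d)) == 0 || all(L == 0)) {
        G[, j] <- gnoise[, j] / config$score_noise_sd  # unit-variance noise
        next
      }
      # scale the loading so the expected profile norm matches the target
      fobj <- function(t) {
        uu <- t * d
        pv <- (L %*% uu) / (sd_R * sqrt(sum(uu^2) + config$score_noise_sd^2))
        sqrt(sum(pv^2)) - radius[jj]
      }
      t_scale <- if (fobj(50) < 0) 50 else uniroot(fobj, c(1e-6, 50))$root
      G[, j] <- (Fall %*% (t_scale * d) + gnoise[, j]) /
        sqrt(t_scale^2 + config$score_noise_sd^2)
    }
  }

  registry <- build_synthetic_registry(config, G, seed_of("registry"))
  features <- features_from_scores(registry, R, seed_of("features"))
  expression <- expression_from_scores(registry, G, config,
                                       seed_of("expression"))
  registry <- finalize_thresholds(registry, expression, G)
  fractions <- cell_fractions_from_factors(Fall, patients, config,
                                           seed_of("fractions"))

  computed_g <- score_genes(expression, registry)
  labels <- dichotomize_scores(computed_g, registry = registry)

  structure(list(
    features = features,
    expression = expression,
    cell_fractions = fractions,
    registry = registry,
    planted = list(
      radiomic_scores = matrix_to_table(R),
      gene_scores = matrix_to_table(G),
      cluster_of = setNames(cluster_of, g_ids),
      labels = labels,
      factors = Fall,
      loadings = L
    ),
    config = config
  ), class = "synthetic_cohort")
}

# Complete registry for the synthetic cohort. The default archetype mirrors
# the seven-signature structure (feature counts 10/6/3/4/2/5/5, modalities,
# one feature shared between R6 and R7); other dimensions use 3 features per
# signature. Gene signatures carry fixed stratification thresholds placed at
# a quantile of the computed score so the minority fraction lands in the
# configured range.
build_synthetic_registry <- function(config, G, seed) {
  p <- config$n_radiomic
  default7 <- p == 7L
  n_feat <- if (default7) c(10L, 6L, 3L, 4L, 2L, 5L, 5L) else rep(3L, p)
  modality <- if (default7) {
    list("T1wCont", "T1wCont", c("T1w", "T1wCont", "T2w"), "T1wCont",
         "T2w", "T2w", "T2w")
  } else {
    as.list(rep("T2w", p))
  }
  withr::with_seed(seed, {
    rad <- purrr::map_dfr(seq_len(p), function(j) {
      mods <- rep(modality[[j]], length.out = n_feat[j])
      feats <- sprintf("synth_R%d_f%02d", j, seq_len(n_feat[j]))
      # R7 reuses one of R6's features (as a non-carrier term, so the
      # inverse construction solves each signature's own carrier)
      if (default7 && j == 7L) feats[2L] <- "synth_R6_f01"
      coefs <- runif(n_feat[j], 0.2, 1.2) * sample(c(-1, 1), n_feat[j], TRUE)
      coefs[1L] <- sample(c(-1, 1), 1L) * runif(1, 0.6, 1.4)  # carrier
      tibble(id = paste0("R", j), source = "synthetic",
             normalization = "none", intercept = 0,
             incomplete = FALSE,
             terms = list(tibble(modality = mods,
                                 image_filter = "original",
                                 feature_class = "synthetic",
                                 feature_name = feats,
                                 coefficient = coefs)))
    })
    lo <- config$genes_per_signature[1]; hi <- config$genes_per_signature[2]
    next_entrez <- 9000001L
    gen <- purrr::map_dfr(seq_len(config$n_gene_signatures), function(j) {
      ng <- sample(seq(lo, hi), 1L)
      ids <- next_entrez + seq_len(ng) - 1L
      next_entrez <<- next_entrez + ng
      q <- runif(1, config$minority_fraction_range[1],
                 config$minority_fraction_range[2])
      side_high <- sample(c(TRUE, FALSE), 1L)
      # threshold on the *computed* (summed) score scale: the computed score
      # equals ng * planted + noise, plus per-gene baselines
      thr_planted <- quantile(G[, j], if (side_high) 1 - q else q)
      tibble(id = paste0("G", j), source = "synthetic",
             aggregation = "weighted_sum",
             threshold_rule = "fixed",
             threshold_value = NA_real_,  # filled after expression is built
             n_genes = ng, incomplete = FALSE,
             genes = list(tibble(entrez_id = ids,
                                 symbol = sprintf("SYN%07d", ids),
                                 weight = 1)),
             .thr_planted = unname(thr_planted))
    })
    reg <- new_registry(radiomic = rad, gene = gen,
                        provenance = list(path = "<synthetic>", checksum = NA))
    reg
  })
}

# Inverse construction: non-carrier feature values are random baselines; the
# carrier (first term) is solved so the linear combination equals the
# planted score exactly.
features_from_scores <- function(registry, R, seed) {
  patients <- rownames(R)
  n <- nrow(R)
  cols <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(registry$radiomic))) {
      id <- registry$radiomic$id[i]
      terms <- registry$radiomic$terms[[i]]
      keys <- feature_key(terms$modality, terms$image_filter,
                          terms$feature_name)
      if (abs(terms$coefficient[1L]) < 1e-8) {
        abort(sprintf("signature %s: carrier coefficient is zero", id))
      }
      for (t in seq_len(nrow(terms))[-1L]) {
        if (!keys[t] %in% names(cols)) cols[[keys[t]]] <- rnorm(n)
      }
      other <- if (nrow(terms) > 1L) {
        vals <- vapply(seq(2L, nrow(terms)),
                       function(t) cols[[keys[t]]] * terms$coefficient[t],
                       numeric(n))
        rowSums(matrix(vals, nrow = n))
      } else {
        numeric(n)
      }
      cols[[keys[1L]]] <-
        (R[, id] - registry$radiomic$intercept[i] - other) / terms$coefficient[1L]
    }
  })
  out <- tibble::as_tibble(cols)
  tibble::add_column(out, patient_id = patients, .before = 1L)
}

# Member genes track their signature's planted score with unit weight plus
# gene-level noise; extra genes are pure noise. Fixed thresholds are
# re-expressed on the computed-score scale.
expression_from_scores <- function(registry, G, config, seed) {
  patients <- rownames(G)
  n <- nrow(G)
  rows <- list()
  withr::with_seed(seed, {
    for (i in seq_len(nrow(registry$gene))) {
      id <- registry$gene$id[i]
      genes <- registry$gene$genes[[i]]
      for (g in seq_len(nrow(genes))) {
        base <- rnorm(1, sd = 2)
        rows[[as.character(genes$entrez_id[g])]] <-
          base + G[, id] + rnorm(n, sd = config$expr_noise_sd)
      }
    }
    if (config$n_extra_genes > 0L) {
      for (e in seq_len(config$n_extra_genes)) {
        rows[[as.character(9500000L + e)]] <- rnorm(1, sd = 2) + rnorm(n)
      }
    }
  })
  em <- do.call(rbind, rows)
  colnames(em) <- patients
  tibble::add_column(as_tibble(em),
                     entrez_id = as.integer(names(rows)), .before = 1L)
}

# Translate the planted-score stratification quantiles to the computed-score
# scale (the weighted gene sum has a different location and spread than the
# planted latent score).
finalize_thresholds <- function(registry, expression, G) {
  computed <- score_genes(expression, registry)
  for (i in seq_len(nrow(registry$gene))) {
    id <- registry$gene$id[i]
    q_level <- mean(G[, id] <= registry$gene$.thr_planted[i])
    registry$gene$threshold_value[i] <-
      unname(quantile(computed[[id]], q_level))
  }
  registry$gene$.thr_planted <- NULL
  registry
}

# Logistic-normal cell fractions: softmax of baseline log-concentrations
# shifted by the latent factors through a fixed sparse coupling.
cell_fractions_from_factors <- function(Fall, patients, config, seed) {
  pops <- .lm22_populations
  n <- length(patients)
  base <- log(c(4, 2, 1.5, 5, 2, 4, 1.5, 1.5, 2, 1, 2, 1.5, 2, 3, 3, 4,
                2, 1, 2, 0.8, 0.8, 1.5))
  lambda <- matrix(0, 22L, ncol(Fall))
  if (!config$null_structure && ncol(Fall) >= 3L) {
    # immune axis 1: M1 macrophages, CD8 T cells, resting dendritic cells up;
    # B cells, naive CD4, neutrophils, Tregs down
    lambda[15L, 2L] <- 0.8; lambda[4L, 2L] <- 0.5; lambda[17L, 2L] <- 0.7
    lambda[10L, 2L] <- 0.4; lambda[21L, 2L] <- 0.4; lambda[19L, 2L] <- 0.4
    lambda[1L, 2L] <- -0.6; lambda[5L, 2L] <- -0.5; lambda[22L, 2L] <- -0.5
    lambda[9L, 2L] <- -0.4
    # immune axis 2: activated NK and B cells up, eosinophils down
    lambda[12L, 3L] <- 0.5; lambda[2L, 3L] <- 0.4; lambda[21L, 3L] <- -0.3
  }
  z <- matrix(base, n, 22L, byrow = TRUE) + Fall %*% t(lambda) +
    withr::with_seed(seed, matrix(rnorm(n * 22L, sd = 0.3), n, 22L))
  frac <- exp(z) / rowSums(exp(z))
  colnames(frac) <- pops
  rownames(frac) <- patients
  matrix_to_table(frac)
}

#' Canned synthetic fixtures
#'
#' * `tiny` - 12 patients, 3 radiomic and 6 gene signatures; fast unit
#'   tests.
#' * `paper_scale` - the default archetype: 82 patients, 7 radiomic
#'   signatures, 29 gene signatures (15 planted in 4 clusters).
#' * `separable` - one strongly separable target: the first gene
#'   signature's classes sit 6 SD apart on the first radiomic score (Bayes
#'   AUC about 0.999); the other radiomic scores are noise.
#' * `null` - no planted structure anywhere.
#'
#' @param name Fixture name.
#' @param seed Master seed.
#' @return A `synthetic_cohort`.
#' @export
make_fixture <- function(name = c("tiny", "paper_scale", "separable", "null"),
                         seed = 1L) {
  name <- match.arg(name)
  switch(name,
    tiny = generate_cohort(cohort_config(
      n_patients = 12L, n_radiomic = 3L, n_gene_signatures = 6L,
      planted_sizes = c(2L, 2L), genes_per_signature = c(3L, 5L),
      n_extra_genes = 5L, seed = seed)),
    paper_scale = generate_cohort(cohort_config(seed = seed)),
    null = generate_cohort(cohort_config(null_structure = TRUE, seed = seed)),
    separable = separable_cohort(seed)
  )
}

# Bespoke strongly separable fixture: G1's classes are 6 SD apart on R1.
separable_cohort <- function(seed) {
  config <- cohort_config(seed = seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  g_ids <- paste0("G", seq_len(config$n_gene_signatures))
  r_ids <- paste0("R", seq_len(config$n_radiomic))
  out <- withr::with_seed(derive_seed(seed, "separable"), {
    y0 <- sample(rep(c(1, -1), length.out = n))
    g1 <- y0 + rnorm(n, sd = 0.25)
    lab <- g1 > 0
    G <- matrix(rnorm(n * config$n_gene_signatures), n,
                dimnames = list(patients, g_ids))
    G[, 1L] <- g1
    R <- matrix(rnorm(n * config$n_radiomic), n,
                dimnames = list(patients, r_ids))
    R[, 1L] <- ifelse(lab, 3, -3) + rnorm(n)
    list(G = G, R = R)
  })
  registry <- build_synthetic_registry(config, out$G,
                                       derive_seed(seed, "separable-registry"))
  features <- features_from_scores(registry, out$R,
                                   derive_seed(seed, "separable-features"))
  expression <- expression_from_scores(registry, out$G, config,
                                       derive_seed(seed, "separable-expr"))
  # G1 splits at zero on the planted scale; the others keep their drawn
  # stratification quantiles
  registry$gene$.thr_planted[1L] <- 0
  registry <- finalize_thresholds(registry, expression, out$G)
  fractions <- cell_fractions_from_factors(
    withr::with_seed(derive_seed(seed, "separable-factors"),
                     matrix(rnorm(n * 7L), n)),
    patients, config, derive_seed(seed, "separable-fractions"))
  # ground-truth labels on the planted scale: G1 splits at zero, the rest at
  # their medians (the registry's fixed thresholds reproduce these up to
  # expression noise when scoring from the expression matrix)
  labels <- dichotomize_scores(matrix_to_table(out$G), rules = list(G1 = 0))
  structure(list(
    features = features, expression = expression,
    cell_fractions = fractions, registry = registry,
    planted = list(
      radiomic_scores = matrix_to_table(out$R),
      gene_scores = matrix_to_table(out$G),
      cluster_of = setNames(rep(0L, config$n_gene_signatures), g_ids),
      labels = labels, factors = NULL, loadings = NULL
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patients, %d radiomic, %d gene signatures\n",
              x$config$n_patients, x$config$n_radiomic,
              x$config$n_gene_signatures))
  n_planted <- sum(x$planted$cluster_of > 0)
  cat(sprintf("  planted: %d signatures in %d clusters; %d unclustered\n",
              n_planted, length(unique(x$planted$cluster_of[x$planted$cluster_of > 0])),
              sum(x$planted$cluster_of == 0)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes the feature table (TSV), expression matrix (TSV), cell fractions
#' (CSV), planted truth tables (CSV), the registry (YAML) and the echoed
#' configuration (JSON).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f, sep = ",") {
    utils::write.table(x, file.path(dir, f), sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  w(cohort$features, "features.tsv", "\t")
  w(cohort$expression, "expression.tsv", "\t")
  w(cohort$cell_fractions, "cell_fractions.csv")
  w(cohort$planted$radiomic_scores, "planted_radiomic_scores.csv")
  w(cohort$planted$gene_scores, "planted_gene_scores.csv")
  w(tibble(signature = names(cohort$planted$cluster_of),
           cluster = unname(cohort$planted$cluster_of)),
    "planted_clusters.csv")
  write_signature_registry(cohort$registry, file.path(dir, "registry.yaml"))
  cfg <- cohort$config
  class(cfg) <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
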