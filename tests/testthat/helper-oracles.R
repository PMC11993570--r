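# Independent brute-force oracles used across the suite.

# Exhaustive silhouette: direct transcription of the definition, one pair at
# a time, no shared code with silhouette_widths().
oracle_silhouette <- function(X, cl) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(cl == cl[i]), i)
    if (length(own) == 0L) return(0)
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (k in setdiff(unique(cl), cl[i])) {
      mem <- which(cl == k)
      b <- min(b, mean(vapply(mem, function(j) d(i, j), numeric(1))))
    }
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
}

# Naive O(n^3) average-linkage agglomeration returning sorted merge heights.
oracle_average_linkage_heights <- function(X) {
  groups <- as.list(seq_len(nrow(X)))
  D <- as.matrix(dist(X))
  heights <- numeric(0)
  while (length(groups) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(groups)) for (j in seq_along(groups)) {
      if (i >= j) next
      dd <- mean(D[groups[[i]], groups[[j]]])
      if (dd < best_d) { best_d <- dd; best <- c(i, j) }
    }
    heights <- c(heights, best_d)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  sort(heights)
}

# Mid-rank Spearman from first principles (explicit average ranks and the
# Pearson product-moment formula).
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# AUC by exhaustive pair enumeration.
oracle_auc <- function(scores, truth) {
  pos <- which(truth == levels(as.factor(truth))[2])
  neg <- which(truth == levels(as.factor(truth))[1])
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(pos) * length(neg))
}

# Distinct-feature census by brute-force set union over enumerated triples.
oracle_census_total <- function(registry) {
  keys <- character(0)
  for (terms in registry$radiomic$terms) {
    keys <- union(keys, paste(terms$modality, terms$image_filter,
                              terms$feature_name, sep = "\r"))
  }
  length(keys)
}

# Small helper: random registry with controllable term overlap.
random_registry <- function(n_sig, n_pool, seed) {
  withr::with_seed(seed, {
    pool <- tibble::tibble(
      modality = sample(c("T1w", "T1wCont", "T2w"), n_pool, TRUE),
      image_filter = sample(c("original", "wavelet-LLH"), n_pool, TRUE),
      feature_name = paste0("f", seq_len(n_pool)))
    rad <- purrr::map_dfr(seq_len(n_sig), function(j) {
      k <- sample(2:5, 1)
      pick <- pool[sample(n_pool, k), ]
      tibble::tibble(id = paste0("R", j), source = "sim",
                     normalization = "none", intercept = 0,
                     incomplete = FALSE,
                     terms = list(dplyr::mutate(
                       pick, feature_class = "sim",
                       coefficient = stats::rnorm(k),
                       .before = 4)))
    })
    radsig:::new_registry(rad, radsig:::parse_gene_defs(NULL))
  })
}
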