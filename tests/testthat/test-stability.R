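test_that("silhouette widths match hand-computed values on a fixed instance", {
  # four points on a line, assignment {1,1},{2,2}
  X <- matrix(c(0, 1, 4, 6), ncol = 1)
  cl <- c(1L, 1L, 2L, 2L)
  # by direct evaluation of the formula:
  # a = (1, 1, 2, 2); b = ((4+6)/2, (3+5)/2, (4+3)/2, (6+5)/2)
  expect_equal(silhouette_widths(X, cl),
               c((5 - 1) / 5, (4 - 1) / 4, (3.5 - 2) / 3.5, (5.5 - 2) / 5.5))
  expect_equal(silhouette_widths(X, cl), oracle_silhouette(X, cl))
})

test_that("a point equidistant between its own and the nearest other cluster scores zero", {
  # mean distance to co-member (2) equals mean distance to the other
  # cluster ((|2-4| + |2-0|) / 2 = 2)
  X <- matrix(c(0, 2, 4, 0), ncol = 1)
  cl <- c(1L, 1L, 2L, 2L)
  s <- silhouette_widths(X, cl)
  expect_equal(s[2], 0)
})

test_that("tight well-separated blobs give near-unit silhouettes and singletons zero", {
  X <- withr::with_seed(3, rbind(matrix(rnorm(20, 0, 0.05), 10),
                                 matrix(rnorm(20, 10, 0.05), 10)))
  cl <- rep(1:2, each = 10)
  expect_true(all(silhouette_widths(X, cl) > 0.9))
  # singleton convention
  s <- silhouette_widths(rbind(X, c(50, 50)), c(cl, 3L))
  expect_equal(s[21], 0)
})

test_that("degenerate silhouette inputs error", {
  X <- matrix(rnorm(10), 5)
  expect_error(silhouette_widths(X, rep(1L, 5)), "single cluster")
  expect_error(silhouette_widths(matrix(1, 4, 2), c(1L, 1L, 2L, 2L)),
               "identical")
})

test_that("consensus stability is reproducible and threshold-monotone", {
  X <- withr::with_seed(5, rbind(matrix(rnorm(24, 0, 0.3), 8),
                                 matrix(rnorm(24, 4, 0.3), 8),
                                 matrix(rnorm(9, 2, 2), 3)))
  rownames(X) <- paste0("i", 1:19)
  r1 <- consensus_stability(X, k = 3, n_runs = 20, seed = 42)
  r2 <- consensus_stability(X, k = 3, n_runs = 20, seed = 42)
  expect_identical(r1, r2)
  expect_true(all(r1$mean_silhouette >= -1 & r1$mean_silhouette <= 1))
  expect_true(all(r1$retained_items %in% r1$items))
  # retained set shrinks (weakly) as the threshold rises
  thresholds <- c(-1, 0, 0.2, 0.5, 0.9)
  sets <- lapply(thresholds, function(th)
    consensus_stability(X, 3, n_runs = 20, threshold = th, seed = 42)$retained_items)
  expect_setequal(sets[[1]], rownames(X))  # threshold below the floor keeps all
  for (i in seq_along(sets)[-1]) {
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  }
})

test_that("planted clusters are retained and scattered singles dropped at small scale", {
  # module-scale recovery: 3 tight planted clusters of 4 plus 3 remote
  # scattered items; k scanned over 3..6
  ok_planted <- 0; ok_noise <- 0; n_seed <- 8
  for (s in seq_len(n_seed)) {
    X <- withr::with_seed(s, {
      centers <- rbind(c(10, 0, 0), c(0, 10, 0), c(0, 0, 10))
      planted <- do.call(rbind, lapply(1:3, function(c)
        matrix(rnorm(12, sd = 0.3), 4, 3, byrow = TRUE) +
          matrix(centers[c, ], 4, 3, byrow = TRUE)))
      noise <- matrix(rnorm(9, sd = 25), 3, 3)
      rbind(planted, noise)
    })
    rownames(X) <- c(paste0("p", 1:12), paste0("n", 1:3))
    k <- select_k(X, k_range = 3:6, n_runs = 20, seed = s)
    res <- consensus_stability(X, as.integer(k), n_runs = 20, seed = s)
    if (all(paste0("p", 1:12) %in% res$retained_items)) ok_planted <- ok_planted + 1
    if (sum(paste0("n", 1:3) %in% res$retained_items) <= 1) ok_noise <- ok_noise + 1
  }
  expect_gte(ok_planted / n_seed, 0.9)
  expect_gte(ok_noise / n_seed, 0.9)
})

test_that("select_k finds two well-separated blobs and honours a singleton range", {
  X <- withr::with_seed(11, rbind(matrix(rnorm(30, 0, 0.2), 10),
                                  matrix(rnorm(30, 8, 0.2), 10)))
  expect_equal(as.integer(select_k(X, k_range = 2:5, n_runs = 15, seed = 1)), 2L)
  expect_equal(as.integer(select_k(X, k_range = 3, n_runs = 5, seed = 1)), 3L)
  expect_error(select_k(X, k_range = integer(0)), "empty")
  expect_error(select_k(X, k_range = 25:30), "outside")
})

test_that("dendrogram ordering matches a naive average-linkage oracle", {
  X2 <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  rownames(X2) <- c("a", "b")
  d2 <- dendrogram_order(X2)
  expect_equal(d2$hclust$height, 5)  # single merge at the pair distance

  # two distant blocks: within-block merges precede the cross-block merge
  Xb <- withr::with_seed(4, rbind(matrix(rnorm(8, 0, 0.1), 4, 2),
                                  matrix(rnorm(8, 20, 0.1), 4, 2)))
  hb <- dendrogram_order(Xb)$hclust
  expect_true(max(hb$height[1:6]) < hb$height[7])

  for (s in 1:5) {
    X5 <- withr::with_seed(s, matrix(rnorm(15), 5))
    rownames(X5) <- paste0("x", 1:5)
    d5 <- dendrogram_order(X5)
    expect_equal(sort(d5$hclust$height), oracle_average_linkage_heights(X5),
                 tolerance = 1e-10)
  }
})

test_that("silhouette widths agree with the cluster package on random data", {
  library(cluster)
  for (s in 1:10) {
    X <- withr::with_seed(s, matrix(rnorm(36), 12))
    cl <- withr::with_seed(s + 100, sample(1:3, 12, replace = TRUE))
    if (length(unique(cl)) < 2) next
    ref <- cluster::silhouette(cl, dist(X))
    # cluster::silhouette uses the same convention except singletons; align
    ours <- silhouette_widths(X, cl)
    multi <- cl %in% as.integer(names(which(table(cl) > 1)))
    expect_equal(ours[multi], unname(ref[multi, "sil_width"]),
                 tolerance = 1e-12)
  }
})

test_that("stability results export round-trippable tables and Newick trees", {
  X <- withr::with_seed(6, rbind(matrix(rnorm(20, 0, 0.3), 5, 4),
                                 matrix(rnorm(20, 5, 0.3), 5, 4)))
  rownames(X) <- paste0("g", 1:10)
  res <- consensus_stability(X, 2, n_runs = 10, seed = 9)
  td <- tidy(res)
  expect_equal(nrow(td), 10)
  expect_equal(td$retained, td$item %in% res$retained_items)
  gl <- glance(res)
  expect_equal(gl$n_retained, length(res$retained_items))
  dir <- withr::local_tempdir()
  write_stability_result(res, file.path(dir, "stab"))
  expect_true(file.exists(file.path(dir, "stab.csv")))
  js <- jsonlite::read_json(file.path(dir, "stab.json"))
  expect_equal(js$k, 2L)
  dend <- dendrogram_order(X)
  write_dendrogram_newick(dend, file.path(dir, "t.nwk"))
  tree <- ape::read.tree(file.path(dir, "t.nwk"))
  expect_equal(sort(tree$tip.label), sort(rownames(X)))
})
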