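test_that("silhouette profile matches hand values and the definition", {
  # clusters {A,B} {C,D}, within 0.1, across 1.0 -> every s(i) = 0.9
  dm <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  dm[1, 2] <- dm[2, 1] <- dm[3, 4] <- dm[4, 3] <- 0.1
  diag(dm) <- 0
  prof <- silhouette_profile(as.dist(dm), c(1, 1, 2, 2))
  expect_equal(prof$samples$s, rep(0.9, 4))
  expect_equal(unname(prof$cluster_means), c(0.9, 0.9))
  expect_equal(prof$mean, 0.9)

  # a point equidistant between two clusters scores 0
  dm2 <- as.matrix(block_dist(3, 3, within = 0.2, between = 0.8))
  dm2 <- cbind(rbind(dm2, x = 0.5), x = c(rep(0.5, 6), 0))
  labs <- c(rep(1, 3), rep(2, 3), 1)
  s <- silhouette_profile(as.dist(dm2), labs)$samples$s
  expect_equal(s[7], 0)

  # a sample planted in the wrong block scores negative
  labs_bad <- c(rep(1, 3), rep(2, 3))
  labs_bad[1] <- 2
  s_bad <- silhouette_profile(block_dist(3, 3), labs_bad)$samples$s
  expect_lt(s_bad[1], 0)

  expect_error(silhouette_profile(block_dist(3, 3), rep(1, 6)), "single-cluster")
})

test_that("silhouette agrees with a brute-force double loop on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:30, 1)
    dm <- as.matrix(block_dist(ceiling(n / 2), floor(n / 2), jitter = 0.3, seed = seed))
    labs <- sample(1:3, n, replace = TRUE)
    if (length(unique(labs)) < 2) next
    prof <- silhouette_profile(as.dist(dm), labs)
    expect_equal(prof$samples$s, oracle_silhouette(dm, labs), tolerance = 1e-12)
    expect_equal(prof$mean, mean(prof$samples$s))
    expect_true(all(prof$samples$s >= -1 & prof$samples$s <= 1))
  }
})

test_that("silhouette widths agree with the cluster package's implementation", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 20
    d <- block_dist(12, 8, jitter = 0.3, seed = seed)
    labs <- sample(1:3, n, replace = TRUE)
    if (min(table(labs)) < 2) next   # exclude singleton-convention differences
    ref <- cluster::silhouette(labs, d)
    prof <- silhouette_profile(d, labs)
    expect_equal(prof$samples$s, unname(ref[, "sil_width"]), tolerance = 1e-12)
  }
})

test_that("singleton clusters take silhouette zero", {
  dm <- as.matrix(block_dist(4, 1, within = 0.1, between = 0.9))
  prof <- silhouette_profile(as.dist(dm), c(1, 1, 1, 1, 2))
  expect_equal(prof$samples$s[5], 0)
})

test_that("complete linkage recovers planted blocks and matches a naive replay", {
  d <- block_dist(5, 4, jitter = 0.05, seed = 3)
  labs <- hierarchical_complete(d, 2)
  expect_equal(length(unique(labs)), 2)
  expect_equal(length(unique(labs[1:5])), 1)
  expect_equal(length(unique(labs[6:9])), 1)
  # agreement with the naive O(n^3) merge replay at several cut levels
  for (k in 2:5) {
    naive <- oracle_complete_linkage(as.matrix(d), k)
    expect_equal(adjusted_rand_index(hierarchical_complete(d, k), naive), 1)
  }
  # boundaries
  expect_equal(unname(hierarchical_complete(d, 1)), rep(1, 9))
  expect_equal(length(unique(hierarchical_complete(d, 9))), 9)
  expect_error(hierarchical_complete(d, 10), "k must")
  # merge heights are non-decreasing
  hc <- hclust(d, method = "complete")
  expect_true(all(diff(hc$height) >= -1e-12))
})

test_that("fuzzy clustering on the dissimilarity matrix recovers blocks", {
  d <- block_dist(6, 6, jitter = 0.05, seed = 8)
  fz <- fuzzy_medoids(d, 2, seed = 1)
  expect_equal(adjusted_rand_index(fz$labels, hierarchical_complete(d, 2)), 1)
  expect_equal(unname(rowSums(fz$membership)), rep(1, 12), tolerance = 1e-9)
  fz2 <- fuzzy_medoids(d, 2, seed = 1)
  expect_identical(fz$labels, fz2$labels)
  zero <- as.dist(matrix(0, 4, 4))
  expect_error(fuzzy_medoids(zero, 2), "degenerate")
})

test_that("k-medoids minimises the brute-force objective on small instances", {
  d <- block_dist(6, 6, jitter = 0.05, seed = 12)
  labs <- kmedoids(d, 2, restarts = 5, seed = 1)
  expect_equal(length(unique(labs[1:6])), 1)
  expect_equal(length(unique(labs[7:12])), 1)
  expect_identical(unname(labs), unname(kmedoids(d, 2, restarts = 5, seed = 1)))

  # exhaustive medoid-pair enumeration on n <= 12
  dm <- as.matrix(d)
  brute <- Inf
  for (i in 1:11) for (j in (i + 1):12)
    brute <- min(brute, sum(pmin(dm[, i], dm[, j])))
  expect_equal(attr(labs, "objective") * 12, brute, tolerance = 1e-9)

  # three equidistant points, k = 2: objective equals the enumerated optimum
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  l3 <- kmedoids(d3, 2, restarts = 3, seed = 2)
  expect_equal(attr(l3, "objective") * 3, 1, tolerance = 1e-9)
  expect_error(kmedoids(d3, 3), "k must")
})

test_that("select_k picks the silhouette argmax and flags near-ties", {
  d <- block_dist(8, 7, jitter = 0.05, seed = 21)
  sel <- select_k(d, k_range = 2:6)
  expect_equal(sel$k, 2)
  expect_false(sel$ambiguous)
  # internal consistency: chosen k is the scan argmax
  expect_equal(sel$k, sel$k_scan$k[which.max(sel$k_scan$silhouette)])
  # all pairwise distances equal: every k ties, ambiguity fires
  n <- 8
  deq <- as.dist(matrix(1, n, n) - diag(n))
  sel_eq <- select_k(deq, k_range = 2:5)
  expect_true(sel_eq$ambiguous)
  expect_equal(sel_eq$ambiguous_k, 2:5)
  # single-candidate range
  expect_equal(select_k(d, k_range = 2)$k, 2)
  expect_error(select_k(d, k_range = integer(0)), "k_range")
})

test_that("select_k recovers three planted well-separated classes", {
  hits <- 0
  for (seed in 1:10) {
    sim <- simulate_habitat(separated_spec(90), seed = seed)
    p <- to_proportions(sim$counts)
    sel <- select_k(bray_curtis(p), k_range = 2:6)
    if (sel$k == 3 && !sel$ambiguous) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("refinement removes sub-two-sample clusters and logs it", {
  # two clean blocks plus one far-away singleton
  dm <- as.matrix(block_dist(5, 5, jitter = 0.03, seed = 4))
  n <- 11
  dm <- cbind(rbind(dm, x = 2), x = c(rep(2, 10), 0))
  dm[n, 1:10] <- dm[1:10, n] <- 2 + runif(10, 0, 0.01)
  dm <- (dm + t(dm)) / 2; diag(dm) <- 0
  rownames(dm) <- colnames(dm) <- c(paste0("s", 1:10), "lone")
  d <- as.dist(dm)
  p <- random_proportions(11, 4, seed = 1)
  rownames(p) <- rownames(dm)
  sel <- select_k(d, k_range = 2:4)
  fit <- refine_classes(d, sel, p)
  expect_true("lone" %in% fit$removed_samples)
  expect_false("lone" %in% names(fit$labels))
  expect_equal(fit$k, 2)
  expect_match(paste(fit$refinement_log, collapse = " "), "< 2 samples")
})

test_that("a well-shaped solution is a refinement fixed point", {
  d <- block_dist(6, 5, jitter = 0.03, seed = 6)
  p <- random_proportions(11, 4, seed = 2)
  rownames(p) <- attr(d, "Labels")
  sel <- select_k(d, k_range = 2:4)
  fit <- refine_classes(d, sel, p)
  expect_length(fit$refinement_log, 0)
  expect_equal(adjusted_rand_index(fit$labels, sel$labels), 1)
})

test_that("the split rule rescues a heterogeneous cluster beside a tight one", {
  # one tight cluster, plus a heterogeneous cluster made of two far-apart
  # tight subgroups: its mean silhouette falls below the split threshold
  # while the big cluster is high, and splitting carves out the subgroups
  set.seed(41)
  n_a <- 30
  ids <- c(paste0("a", 1:n_a), paste0("b", 1:4), paste0("c", 1:4))
  n <- length(ids)
  dm <- matrix(0.7, n, n, dimnames = list(ids, ids))
  dm[1:n_a, 1:n_a] <- 0.05
  dm[n_a + 1:4, n_a + 1:4] <- 0.05
  dm[n_a + 5:8, n_a + 5:8] <- 0.05
  dm[n_a + 1:4, n_a + 5:8] <- 1.0
  dm[n_a + 5:8, n_a + 1:4] <- 1.0
  jit <- matrix(runif(n * n, 0, 0.01), n, n)
  dm <- dm + (jit + t(jit)) / 2
  diag(dm) <- 0
  d <- as.dist(dm)
  lump <- setNames(c(rep(1, n_a), rep(2, 8)), ids)
  sel <- structure(list(labels = lump, method = "hclust",
                        k_scan = data.frame(k = 2, silhouette = NA)),
                   class = "cluster_selection")
  p <- random_proportions(n, 4, seed = 1)
  rownames(p) <- ids
  fit <- refine_classes(d, sel, p)
  expect_equal(fit$k, 3)
  truth <- setNames(c(rep(1, n_a), rep(2, 4), rep(3, 4)), ids)
  expect_equal(adjusted_rand_index(fit$labels, truth), 1)
  expect_match(paste(fit$refinement_log, collapse = " "), "split cluster")
})

test_that("one large plus two small tight planted classes are fully recovered", {
  hits <- 0
  for (seed in 1:10) {
    spec <- community_sim_spec(n_subjects = 80, n_classes = 3,
                               mixing = c(0.7, 0.16, 0.14), dominance = 300,
                               base_concentration = 0.05)
    sim <- simulate_habitat(spec, seed = seed)
    p <- to_proportions(sim$counts)
    d <- bray_curtis(p)
    fit <- refine_classes(d, select_k(d, 2:9), p)
    if (adjusted_rand_index(fit$labels, sim$classes[names(fit$labels)]) >= 0.9)
      hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("subsampling stability tabulates optimal-k frequencies", {
  sim <- simulate_habitat(separated_spec(80), seed = 5)
  res <- subsample_stability(sim$counts, sizes = c(30, 60), replicates = 10,
                             k_range = 2:4, seed = 7)
  expect_equal(unname(rowSums(res$frequencies)), c(1, 1))
  expect_gte(res$frequencies["60", "3"], res$frequencies["30", "3"] - 0.1)
  # single replicate gives a one-hot row
  res1 <- subsample_stability(sim$counts, sizes = 40, replicates = 1,
                              k_range = 2:4, seed = 1)
  expect_equal(sort(unname(res1$frequencies[1, ])), c(0, 0, 1))
  expect_error(subsample_stability(sim$counts, sizes = 1000, replicates = 1),
               "exceeds")
})
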