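test_that("ARI matches hand values and the pair-counting oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(3, 3, 4, 4)), 1)
  # {1,2|3,4} vs {1,3|2,4} -> -0.5 by explicit pair counting
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # random partitions of n <= 8, degenerate ones included
  set.seed(13)
  for (i in 1:200) {
    n <- sample(3:8, 1)
    a <- sample(1:sample(1:4, 1), n, replace = TRUE)
    b <- sample(1:sample(1:4, 1), n, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b), tolerance = 1e-12)
  }
})

test_that("ARI is symmetric, relabeling-invariant and centred at zero", {
  set.seed(17)
  a <- sample(1:3, 50, replace = TRUE)
  b <- sample(1:3, 50, replace = TRUE)
  expect_equal(adjusted_rand_index(a, b), adjusted_rand_index(b, a))
  expect_equal(adjusted_rand_index(a, b),
               adjusted_rand_index(c("x", "y", "z")[a], b))
  vals <- replicate(1000, adjusted_rand_index(sample(1:3, 50, replace = TRUE),
                                              sample(1:3, 50, replace = TRUE)))
  expect_lt(abs(mean(vals)), 0.02)
  # named vectors align on shared ids
  x <- c(A = 1, B = 1, C = 2, D = 2)
  y <- c(D = 5, C = 5, B = 7, A = 7, Z = 1)  # same split after alignment
  expect_equal(adjusted_rand_index(x, y), 1)
  y2 <- c(A = 1, B = 2, C = 1, D = 2, Z = 9)
  expect_equal(adjusted_rand_index(x, y2), -0.5)
  expect_error(adjusted_rand_index(c(A = 1), c(B = 2)), "shared")
})

test_that("ARI agrees with the independent mclust implementation", {
  set.seed(19)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})

test_that("cross-habitat agreement reflects planted coupling", {
  spec <- separated_spec(70)
  sim <- simulate_habitat(spec, seed = 23)
  # same table presented as two habitats: perfect agreement
  tabs <- list(h1 = sim$counts, h2 = sim$counts)
  ari <- cross_habitat_ari(tabs, k_range = 2:4)
  expect_equal(ari["h1", "h2"], 1)
  expect_equal(diag(ari), c(h1 = 1, h2 = 1))

  # habitats with identical planted memberships agree strongly; independent
  # ones do not
  coupled <- independent <- numeric(5)
  for (seed in 1:5) {
    s1 <- simulate_habitat(spec, seed = 100 + seed)
    set.seed(200 + seed)
    regen <- .draw_counts_for_test(spec, s1$classes)
    coupled[seed] <- cross_habitat_ari(list(a = s1$counts, b = regen),
                                       k_range = 2:4)["a", "b"]
    s2 <- simulate_habitat(spec, seed = 300 + seed)
    rownames(s2$counts) <- rownames(s1$counts)
    independent[seed] <- cross_habitat_ari(list(a = s1$counts, b = s2$counts),
                                           k_range = 2:4)["a", "b"]
  }
  expect_gte(mean(coupled), 0.8)
  expect_lte(abs(mean(independent)), 0.1)

  # too little overlap is flagged missing
  t1 <- sim$counts[1:10, ]
  t2 <- sim$counts[30:40, ]
  expect_message(ari2 <- cross_habitat_ari(list(a = t1, b = t2), k_range = 2:3),
                 "fewer than 2 subjects")
  expect_true(is.na(ari2["a", "b"]))
})

test_that("stability summarises class switching between visits", {
  spec <- separated_spec(60, switch_matrix = diag(3))
  sim <- simulate_longitudinal(spec, seed = 31)
  # identity switching: visit 2 re-drawn from the same class
  ts <- stability(sim$visit1, sim$visit2, k_range = 2:4, refine = FALSE)
  expect_gte(ts$maintained_fraction, 0.95)
  expect_gte(ts$ari, 0.9)
  # literally identical visits: no switching at all
  ts0 <- stability(sim$visit1, sim$visit1, k_range = 2:4, refine = FALSE)
  expect_equal(ts0$maintained_fraction, 1)
  expect_equal(ts0$ari, 1)
  # transition row sums equal visit-1 class sizes among paired subjects
  expect_equal(unname(rowSums(ts$transitions)),
               unname(as.integer(table(factor(ts$labels_visit1,
                                              levels = rownames(ts$transitions))))))
  # internal consistency with adjusted_rand_index
  expect_equal(ts$ari, adjusted_rand_index(unname(ts$labels_visit1),
                                           unname(ts$labels_visit2)))
  expect_error(stability(sim$visit1[1:3, ],
                         `rownames<-`(sim$visit2[4:6, ], c("x", "y", "z"))),
               "fewer than 2 subjects")
})
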