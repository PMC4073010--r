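test_that("Shannon diversity matches closed forms after rarefaction", {
  # one-taxon sample has zero entropy; uniform sample attains ln S
  x <- rbind(mono = c(1000L, 0L, 0L, 0L),
             even = c(250L, 250L, 250L, 250L))
  colnames(x) <- paste0("g", 1:4)
  div <- shannon_diversity(x, depth = 1000, seed = 1)
  expect_equal(unname(div$h["mono"]), 0)
  expect_equal(unname(div$h["even"]), log(4))
  # hand-evaluated -sum p ln p for proportions (0.5, 0.25, 0.25)
  y <- rbind(s = c(500L, 250L, 250L))
  colnames(y) <- paste0("g", 1:3)
  expect_equal(unname(shannon_diversity(y, depth = 1000)$h), 1.0397, tolerance = 1e-4)
  expect_equal(unname(shannon_diversity(y, depth = 1000)$h),
               oracle_shannon(c(0.5, 0.25, 0.25)), tolerance = 1e-12)
  # permutation invariance in taxa (exactly-at-depth samples, so the
  # rarefaction draw is a no-op) and determinism under a fixed seed
  set.seed(2)
  z <- t(rmultinom(4, 500, rep(1 / 10, 10)))
  dimnames(z) <- list(paste0("s", 1:4), paste0("g", 1:10))
  expect_equal(shannon_diversity(z, depth = 500)$h,
               shannon_diversity(z[, sample(10)], depth = 500)$h)
  expect_equal(shannon_diversity(z, depth = 400, seed = 5)$h,
               shannon_diversity(z, depth = 400, seed = 5)$h)
  low <- rbind(s = c(5L, 5L))
  colnames(low) <- c("g1", "g2")
  expect_error(shannon_diversity(low, depth = 1000), "below")
})

test_that("silhouette-diversity correlation behaves on exact lines", {
  expect_equal(correlate_silhouette_diversity(c(0.9, 0.5, 0.1), c(1, 2, 3)), -1)
  expect_equal(correlate_silhouette_diversity(c(0.1, 0.5, 0.9), c(1, 2, 3)), 1)
  expect_error(correlate_silhouette_diversity(c(0.5, 0.5, 0.5), c(1, 2, 3)),
               "zero variance")
  expect_error(correlate_silhouette_diversity(c(0.5, 0.6), c(1, 2)), "3 habitats")
})

test_that("habitat typing applies both thresholds with strict Shannon bound", {
  expect_equal(classify_habitat_type(0.8, 0.86), "I")   # posterior-fornix-like
  expect_equal(classify_habitat_type(3.0, 0.14), "II")  # saliva-like
  expect_equal(classify_habitat_type(1.5, 0.9), "II")   # boundary: strict <
  expect_equal(classify_habitat_type(1.0, 0.4), "II")   # low sil despite low H
  expect_equal(classify_habitat_type(c(0.8, 3), c(0.86, 0.14)), c("I", "II"))
  expect_error(classify_habitat_type(1, 1.5), "silhouette")
})

test_that("demographic association tests find planted effects only", {
  # perfectly separated 2x2 table: exact test p = 2 / choose(20, 10)
  labs <- setNames(rep(1:2, each = 10), paste0("s", 1:20))
  md <- data.frame(gender = rep(c("m", "f"), each = 10),
                   row.names = paste0("s", 1:20))
  res <- associate(labs, md)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  expect_lt(res$p, 1e-4)
  expect_true(res$significant)
  # identical composition across levels: p = 1
  md2 <- data.frame(gender = rep(c("m", "f"), 10), row.names = paste0("s", 1:20))
  expect_equal(associate(labs, md2)$p, 1)
  # single-level factors are skipped
  md3 <- data.frame(gender = rep("m", 20), age = rnorm(20, 30),
                    row.names = paste0("s", 1:20))
  expect_message(res3 <- associate(labs, md3), "single level")
  expect_equal(res3$factor, "age")
  # numeric bmi is categorised, continuous age goes through ANOVA
  set.seed(3)
  md4 <- data.frame(age = rnorm(20, 30, 5), bmi = runif(20, 18, 35),
                    row.names = paste0("s", 1:20))
  res4 <- associate(labs, md4)
  expect_equal(res4$test[res4$factor == "age"], "anova")
  expect_equal(res4$test[res4$factor == "bmi"], "fisher")
  # Bonferroni never shrinks p and significance is monotone
  expect_true(all(res4$p_adj >= res4$p))
})

test_that("planted gender and age effects are detected with power", {
  hits_gender <- hits_age <- 0
  for (seed in 1:10) {
    sim <- simulate_habitat(separated_spec(200), seed = seed)
    md <- simulate_metadata(sim$classes, metadata_model(3), seed = seed)
    res <- associate(sim$classes, md, factors = c("gender", "age"), seed = seed)
    if (res$significant[res$factor == "gender"]) hits_gender <- hits_gender + 1
    if (res$significant[res$factor == "age"]) hits_age <- hits_age + 1
  }
  expect_gte(hits_gender, 8)
  expect_gte(hits_age, 8)
})

test_that("taxon-level rank-sum test is calibrated and powered", {
  p <- random_proportions(20, 5, seed = 7)
  # strictly separated groups attain the minimal two-sided p for n = 10 vs 10
  p[, 1] <- c(seq(0.5, 0.6, length.out = 10), seq(0.1, 0.2, length.out = 10)) / 10
  grp <- rep(c("A", "B"), each = 10)
  res <- taxon_vs_group(p, colnames(p)[1], grp)
  expect_equal(res$p, 2 / choose(20, 10), tolerance = 1e-12)
  # null calibration over label shuffles
  set.seed(9)
  pv <- replicate(200, taxon_vs_group(p, colnames(p)[2], sample(grp))$p)
  expect_lte(mean(pv < 0.05), 0.075)
  # constant abundances warn and return p = 1
  p[, 3] <- 0.01
  expect_warning(res3 <- taxon_vs_group(p, colnames(p)[3], grp), "constant")
  expect_equal(res3$p, 1)
  # one sample per group cannot be significant
  expect_false(taxon_vs_group(p[1:2, ], colnames(p)[1], c("A", "B"))$significant)
})
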