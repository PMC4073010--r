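# Independent reference implementations used to validate the package's
# computations: deliberately naive (double loops, enumeration, pair
# counting), sharing no code with the implementations they check.

# Bray-Curtis by the summation formula, one pair at a time.
oracle_bray <- function(p) {
  n <- nrow(p)
  d <- matrix(0, n, n, dimnames = list(rownames(p), rownames(p)))
  for (i in seq_len(n)) for (j in seq_len(n))
    d[i, j] <- sum(abs(p[i, ] - p[j, ])) / sum(p[i, ] + p[j, ])
  d
}

# Silhouette widths by the definition, one sample at a time.
oracle_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    mates <- setdiff(which(labels == own), i)
    if (!length(mates)) { s[i] <- 0; next }
    a <- mean(dm[i, mates])
    b <- min(vapply(setdiff(unique(labels), own),
                    function(cl) mean(dm[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# Complete-linkage agglomeration replayed naively: merge the pair of
# clusters whose most-dissimilar members are closest, down to k clusters.
oracle_complete_linkage <- function(dm, k) {
  clusters <- as.list(seq_len(nrow(dm)))
  while (length(clusters) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dij <- max(dm[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(nrow(dm))
  for (c in seq_along(clusters)) labels[clusters[[c]]] <- c
  labels
}

# ARI from explicit pair counting over all subject pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (!sa && !sb) n00 <- n00 + 1
      else if (sa) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  denom <- (n00 + n01) * (n01 + n11) + (n00 + n10) * (n10 + n11)
  if (denom == 0) return(1)
  2 * (n00 * n11 - n01 * n10) / denom
}

# Shannon index from first principles.
oracle_shannon <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Two well-separated blocks of sizes n1, n2: within-block dissimilarity
# `within` (jittered to break ties), between-block `between`.
block_dist <- function(n1, n2, within = 0.1, between = 0.9, jitter = 0, seed = 1) {
  set.seed(seed)
  n <- n1 + n2
  dm <- matrix(between, n, n)
  dm[seq_len(n1), seq_len(n1)] <- within
  dm[(n1 + 1):n, (n1 + 1):n] <- within
  if (jitter > 0) {
    noise <- matrix(stats::runif(n * n, 0, jitter), n, n)
    noise <- (noise + t(noise)) / 2
    dm <- dm + noise
  }
  diag(dm) <- 0
  dimnames(dm) <- list(paste0("s", seq_len(n)), paste0("s", seq_len(n)))
  stats::as.dist(dm)
}

# Random proportion table.
random_proportions <- function(n, g, seed = 1) {
  set.seed(seed)
  x <- matrix(stats::rexp(n * g), n, g,
              dimnames = list(paste0("s", seq_len(n)), paste0("g", seq_len(g))))
  x / rowSums(x)
}

# Small deterministic count table fixture.
toy_counts <- function() {
  m <- matrix(c(10L, 5L, 0L, 3L,
                2L, 8L, 4L, 6L,
                7L, 0L, 9L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("g1", "g2", "g3", "g4")))
  m
}

# Fresh Dirichlet-multinomial abundance draw for a fixed class assignment
# (couples a second habitat to planted memberships).
.draw_counts_for_test <- function(spec, classes) {
  counts <- matrix(0L, length(classes), length(spec$taxa),
                   dimnames = list(names(classes), spec$taxa))
  for (i in seq_along(classes)) {
    a <- spec$concentrations[classes[i], ]
    g <- stats::rgamma(length(a), a)
    counts[i, ] <- stats::rmultinom(1, 5000, g / sum(g))[, 1]
  }
  counts
}

# Well-separated three-class study condition used across recovery tests:
# high single-genus dominance, unequal class sizes.
separated_spec <- function(n_subjects = 150, switch_matrix = NULL) {
  community_sim_spec(n_subjects = n_subjects, n_classes = 3,
                     mixing = c(0.5, 0.3, 0.2), dominance = 300,
                     base_concentration = 0.05,
                     signature_taxa = c("Bacteroides", "Prevotella", "Ruminococcus"),
                     switch_matrix = switch_matrix)
}
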