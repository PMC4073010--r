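# Partitioning samples into community classes: complete-linkage hierarchical
# clustering (the main path), dissimilarity-native fuzzy clustering and
# k-medoids (confirmation paths), silhouette-based selection of the number of
# classes, and subsampling robustness of that selection.

.check_dist <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
      stop("d must be a 'dist' object or a square symmetric matrix")
    d <- stats::as.dist(m)
  }
  d
}

#' Complete-linkage hierarchical partition
#'
#' Agglomerative clustering in which the distance between two clusters is the
#' dissimilarity of their most dissimilar members, cut to exactly `k`
#' clusters. Complete linkage is used because it favours compact clusters.
#'
#' @param d A `dist` object.
#' @param k Number of clusters, between 1 and the number of samples.
#' @return Named integer vector of cluster labels (1..k).
#' @export
hierarchical_complete <- function(d, k) {
  d <- .check_dist(d)
  n <- attr(d, "Size")
  if (length(k) != 1 || k < 1 || k > n) stop("k must lie in [1, n]")
  stats::cutree(stats::hclust(d, method = "complete"), k = k)
}

#' Fuzzy clustering on a dissimilarity matrix
#'
#' Dissimilarity-native fuzzy clustering (`cluster::fanny`): every sample
#' receives a membership weight in each cluster, and hard labels are taken as
#' the cluster of maximal membership.
#'
#' @param d A `dist` object.
#' @param k Number of clusters, 2 <= k < n.
#' @param membership_exponent Fuzziness exponent (> 1); larger values give
#'   softer memberships.
#' @param seed Optional seed, accepted for interface uniformity (the
#'   algorithm itself is deterministic).
#' @return List with `labels` (named, by maximal membership), `membership`
#'   (n x k matrix, rows summing to 1) and `k`.
#' @export
fuzzy_medoids <- function(d, k, membership_exponent = 2, seed = NULL) {
  d <- .check_dist(d)
  n <- attr(d, "Size")
  if (k < 2 || k >= n) stop("k must lie in [2, n - 1]")
  if (membership_exponent <= 1) stop("membership_exponent must exceed 1")
  if (all(d < .Machine$double.eps)) stop("degenerate dissimilarity matrix (all zero)")
  if (!is.null(seed)) set.seed(seed)
  fit <- cluster::fanny(d, k = k, diss = TRUE, memb.exp = membership_exponent)
  membership <- fit$membership
  labels <- apply(membership, 1, which.max)
  names(labels) <- attr(d, "Labels")
  rownames(membership) <- attr(d, "Labels")
  list(labels = labels, membership = membership, k = k)
}

#' k-medoids partition of a dissimilarity matrix
#'
#' Partitioning around medoids: a greedy build phase followed by swap
#' optimisation, plus seeded random-initialisation restarts, keeping the
#' solution with the lowest total dissimilarity to its medoids.
#'
#' @param d A `dist` object.
#' @param k Number of clusters, 2 <= k < n.
#' @param restarts Number of starts (the first is the deterministic greedy
#'   build; the rest use random initial medoids).
#' @param seed Optional seed for the random restarts.
#' @return Named integer vector of cluster labels with attributes `medoids`
#'   (sample ids) and `objective` (mean dissimilarity to assigned medoid).
#' @export
kmedoids <- function(d, k, restarts = 10, seed = NULL) {
  d <- .check_dist(d)
  n <- attr(d, "Size")
  if (k < 2 || k >= n) stop("k must lie in [2, n - 1]")
  if (restarts < 1) stop("restarts must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  best <- cluster::pam(d, k = k, diss = TRUE)
  best_obj <- unname(best$objective["swap"])
  if (restarts > 1) {
    for (r in seq_len(restarts - 1)) {
      fit <- cluster::pam(d, k = k, diss = TRUE, medoids = sample.int(n, k))
      obj <- unname(fit$objective["swap"])
      if (obj < best_obj - 1e-12) { best <- fit; best_obj <- obj }
    }
  }
  labels <- best$clustering
  names(labels) <- attr(d, "Labels")
  attr(labels, "medoids") <- attr(d, "Labels")[best$id.med]
  attr(labels, "objective") <- best_obj
  labels
}

.cluster_labels <- function(d, k, method, seed = NULL, ...) {
  switch(method,
         hclust = hierarchical_complete(d, k),
         fuzzy = fuzzy_medoids(d, k, seed = seed, ...)$labels,
         kmedoids = kmedoids(d, k, seed = seed, ...),
         stop("unknown clustering method '", method, "'"))
}

#' Choose the number of community classes by average silhouette width
#'
#' Runs the chosen clusterer for every k in `k_range`, scores each partition
#' by its overall mean silhouette width, and picks the k with the highest
#' value. Competing k whose mean silhouettes fall within
#' `ambiguity_threshold` (default 0.02) of the best are flagged for manual
#' inspection, mirroring how near-ties are resolved by expert review.
#'
#' @param d A `dist` object.
#' @param k_range Candidate numbers of clusters (within [2, n - 1]).
#' @param method One of `"hclust"`, `"kmedoids"`, `"fuzzy"`.
#' @param ambiguity_threshold Silhouette difference below which two k are
#'   considered tied.
#' @param seed Optional seed passed to stochastic clusterers.
#' @param ... Further arguments for the clusterer.
#' @return An object of class `cluster_selection`: `k_scan` (data frame of k
#'   and mean silhouette), `k` (chosen), `labels` for the chosen k,
#'   `silhouette` (its profile), `ambiguous` flag and `ambiguous_k`.
#' @export
select_k <- function(d, k_range = 2:9, method = c("hclust", "kmedoids", "fuzzy"),
                     ambiguity_threshold = 0.02, seed = NULL, ...) {
  d <- .check_dist(d)
  method <- match.arg(method)
  n <- attr(d, "Size")
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (!length(k_range)) stop("k_range is empty after restriction to [2, n - 1]")
  labels_by_k <- lapply(k_range, function(k) .cluster_labels(d, k, method, seed = seed, ...))
  profiles <- lapply(labels_by_k, function(lab) silhouette_profile(d, lab))
  sil <- vapply(profiles, `[[`, numeric(1), "mean")
  best <- which.max(sil)
  ambiguous_k <- k_range[sil > sil[best] - ambiguity_threshold]
  structure(list(k_scan = data.frame(k = k_range, silhouette = sil),
                 k = k_range[best],
                 labels = labels_by_k[[best]],
                 silhouette = profiles[[best]],
                 ambiguous = length(ambiguous_k) > 1,
                 ambiguous_k = ambiguous_k,
                 method = method,
                 ambiguity_threshold = ambiguity_threshold),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Silhouette scan (", x$method, "):\n", sep = "")
  print(transform(x$k_scan, silhouette = round(silhouette, 4)), row.names = FALSE)
  cat("chosen k =", x$k, "(mean silhouette",
      format(max(x$k_scan$silhouette), digits = 3), ")\n")
  if (x$ambiguous)
    cat("ambiguous: k in {", paste(x$ambiguous_k, collapse = ", "),
        "} within ", x$ambiguity_threshold, " of the best\n", sep = "")
  invisible(x)
}

#' Robustness of the chosen number of classes under subsampling
#'
#' Repeatedly draws subsets of samples without replacement, reruns the
#' standard pipeline (proportions, Bray-Curtis, silhouette scan) on each
#' subset, and tabulates how often each candidate k is chosen at each subset
#' size.
#'
#' @param counts Count matrix (samples x taxa); copy-number scaling, if
#'   wanted, should be applied upstream via `copy_numbers`.
#' @param sizes Subsample sizes (each <= number of samples).
#' @param replicates Replicate draws per size.
#' @param k_range Candidate numbers of clusters scored per replicate.
#' @param copy_numbers Optional genus -> copy-number map applied before the
#'   proportion transform.
#' @param seed Seed for the subsampling draws.
#' @return Object of class `subsampling_result`: `frequencies` (sizes x k
#'   matrix of chosen-k fractions, rows summing to 1), plus the settings.
#' @export
subsample_stability <- function(counts, sizes = c(50, 100, 150, 180),
                                replicates = 100, k_range = 2:5,
                                copy_numbers = NULL, seed = NULL) {
  validate_count_table(counts, integer_counts = FALSE)
  n <- nrow(counts)
  if (any(sizes > n)) stop("subsample size exceeds the number of samples")
  if (replicates < 1) stop("replicates must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  scaled <- if (is.null(copy_numbers)) counts else
    suppressMessages(scale_by_copy_number(counts, copy_numbers))
  k_range <- sort(unique(as.integer(k_range)))
  freq <- matrix(0, length(sizes), length(k_range),
                 dimnames = list(as.character(sizes), as.character(k_range)))
  for (si in seq_along(sizes)) {
    for (r in seq_len(replicates)) {
      idx <- sample.int(n, sizes[si])
      p <- to_proportions(scaled[idx, , drop = FALSE])
      sel <- select_k(bray_curtis(p), k_range = k_range, method = "hclust")
      freq[si, as.character(sel$k)] <- freq[si, as.character(sel$k)] + 1
    }
  }
  structure(list(frequencies = freq / replicates, sizes = sizes,
                 replicates = replicates, k_range = k_range, seed = seed),
            class = "subsampling_result")
}

#' @export
print.subsampling_result <- function(x, ...) {
  cat("Optimal-k frequencies over", x$replicates, "subsamples per size:\n")
  print(round(x$frequencies, 3))
  invisible(x)
}
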