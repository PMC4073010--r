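# Silhouette widths over a dissimilarity matrix. The silhouette is the
# quantity the whole class-selection recipe optimises, so it is computed here
# with explicit conventions rather than delegated: singleton clusters get
# s(i) = 0, and per-cluster means are reported for the refinement rules.

#' Silhouette profile of a partition
#'
#' For each sample i, a(i) is the mean dissimilarity to the other members of
#' its cluster, b(i) the lowest mean dissimilarity to any other cluster, and
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)). Samples near 1 are well clustered,
#' near 0 lie between two clusters, and negative values suggest
#' misassignment. Members of singleton clusters are assigned s(i) = 0.
#'
#' @param d A `dist` object over the samples.
#' @param labels Cluster labels, one per sample, in `d`'s sample order (or
#'   named by sample id).
#' @return An object of class `silhouette_profile`: a list with `samples`
#'   (data frame of sample, cluster, neighbor, a, b, s), `cluster_means`,
#'   `mean` (the overall average silhouette width) and `k`.
#' @export
silhouette_profile <- function(d, labels) {
  m <- as.matrix(d)
  n <- nrow(m)
  labels <- .align_labels(labels, rownames(m), n)
  cl <- unique(labels)
  if (length(cl) < 2) stop("silhouette is undefined for a single-cluster partition")
  sizes <- table(factor(labels, levels = cl))
  # column sums of d within each cluster, for every sample at once
  sums <- rowsum(m, group = labels)        # clusters x samples
  a <- b <- s <- numeric(n)
  neighbor <- character(n)
  for (i in seq_len(n)) {
    own <- labels[i]
    if (sizes[[own]] == 1) {
      a[i] <- 0; b[i] <- 0; s[i] <- 0
      others <- setdiff(cl, own)
      mean_to <- sums[others, i] / as.numeric(sizes[others])
      neighbor[i] <- others[which.min(mean_to)]
      next
    }
    a[i] <- sums[own, i] / (sizes[[own]] - 1)
    others <- setdiff(cl, own)
    mean_to <- sums[others, i] / as.numeric(sizes[others])
    j <- which.min(mean_to)
    b[i] <- mean_to[j]
    neighbor[i] <- others[j]
    s[i] <- if (max(a[i], b[i]) > 0) (b[i] - a[i]) / max(a[i], b[i]) else 0
  }
  samples <- data.frame(sample = rownames(m), cluster = labels,
                        neighbor = neighbor, a = a, b = b, s = s,
                        stringsAsFactors = FALSE)
  cm <- tapply(s, factor(labels, levels = cl), mean)
  structure(list(samples = samples,
                 cluster_means = stats::setNames(as.numeric(cm), names(cm)),
                 mean = mean(s),
                 k = length(cl)),
            class = "silhouette_profile")
}

#' @export
print.silhouette_profile <- function(x, ...) {
  cat("Silhouette profile: ", nrow(x$samples), " samples in ", x$k,
      " clusters\n", sep = "")
  cat("  overall mean width:", format(x$mean, digits = 3), "\n")
  cat("  per-cluster means:\n")
  print(round(x$cluster_means, 3))
  invisible(x)
}

.align_labels <- function(labels, ids, n) {
  if (length(labels) != n) stop("labels must cover every sample in d")
  if (!is.null(names(labels)) && !is.null(ids)) {
    if (!all(ids %in% names(labels))) stop("label names do not match sample ids")
    labels <- labels[ids]
  }
  as.character(labels)
}
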