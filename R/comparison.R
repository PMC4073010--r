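# Agreement between partitions: the adjusted Rand index (ARI) for pairs of
# habitats sharing subjects, and community-class switching between two
# visits under a joint (pooled) clustering.

#' Adjusted Rand index of two partitions
#'
#' Chance-corrected pair-counting agreement computed from the label
#' contingency table under the permutation model: 1 for identical
#' partitions, expectation 0 for independent ones. If both label vectors are
#' named they are first aligned on their shared ids.
#'
#' @param labels_a,labels_b Cluster labels of the same subjects in two
#'   contexts.
#' @return The ARI, a single number <= 1.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    shared <- intersect(names(labels_a), names(labels_b))
    if (length(shared) < 2) stop("fewer than 2 shared subjects")
    labels_a <- labels_a[shared]
    labels_b <- labels_b[shared]
  }
  if (length(labels_a) != length(labels_b)) stop("label vectors differ in length")
  n <- length(labels_a)
  if (n < 2) stop("fewer than 2 subjects")
  tab <- table(labels_a, labels_b)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (abs(max_index - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Cross-habitat agreement of community classes
#'
#' For every pair of habitats, restricts to the subjects sampled in both,
#' re-runs the standard typing pipeline on each habitat's shared subset, and
#' reports the ARI of the two resulting partitions. A pair with fewer than
#' two shared subjects is left `NA` and messaged.
#'
#' @param tables Named list of count matrices (one per habitat), rownames
#'   being subject ids.
#' @param k_range Scan range used when re-selecting k on each shared subset;
#'   alternatively fix the number of classes per habitat with `fixed_k`.
#' @param fixed_k Optional named (or single) number of clusters per habitat,
#'   bypassing re-selection.
#' @param metric,method Passed to [community_classes()].
#' @param ... Further arguments for [community_classes()].
#' @return Symmetric habitat-by-habitat ARI matrix with unit diagonal.
#' @export
cross_habitat_ari <- function(tables, k_range = 2:9, fixed_k = NULL,
                              metric = "bray-curtis", method = "hclust", ...) {
  if (length(tables) < 2 || is.null(names(tables)))
    stop("tables must be a named list of at least two habitats")
  habs <- names(tables)
  out <- matrix(NA_real_, length(habs), length(habs), dimnames = list(habs, habs))
  diag(out) <- 1
  for (i in seq_along(habs)[-length(habs)]) {
    for (j in (i + 1):length(habs)) {
      shared <- intersect(rownames(tables[[i]]), rownames(tables[[j]]))
      if (length(shared) < 2) {
        message("habitats '", habs[i], "' and '", habs[j],
                "' share fewer than 2 subjects; ARI left missing")
        next
      }
      part <- lapply(c(i, j), function(h) {
        k_h <- if (is.null(fixed_k)) NULL else
          if (!is.null(names(fixed_k))) fixed_k[[habs[h]]] else fixed_k
        fit <- community_classes(tables[[h]][shared, , drop = FALSE],
                                 metric = metric, method = method,
                                 k = k_h, k_range = k_range, refine = FALSE, ...)
        fit$labels
      })
      out[i, j] <- out[j, i] <- adjusted_rand_index(part[[1]], part[[2]])
    }
  }
  out
}

#' Community-class stability between two visits
#'
#' Pools the samples from both visits and clusters them jointly (so labels
#' are directly comparable), then pairs each subject's two samples to build
#' the class-by-class transition matrix, the fraction of subjects that kept
#' their class, and the ARI of the paired labels.
#'
#' @param visit1,visit2 Count matrices with subject ids as rownames; only
#'   subjects present in both visits enter the transition summary.
#' @param ... Arguments for [community_classes()] (metric, method, k_range,
#'   refine, ...).
#' @return Object of class `transition_summary`: `transitions` (visit-1 by
#'   visit-2 class count matrix), `maintained` (per-class diagonal counts),
#'   `maintained_fraction`, `ari`, `n_subjects`, and the joint `fit`.
#' @export
stability <- function(visit1, visit2, ...) {
  shared <- intersect(rownames(visit1), rownames(visit2))
  if (length(shared) < 2) stop("fewer than 2 subjects present at both visits")
  taxa <- union(colnames(visit1), colnames(visit2))
  pad <- function(x) {
    m <- matrix(0, nrow(x), length(taxa), dimnames = list(rownames(x), taxa))
    m[, colnames(x)] <- x
    m
  }
  pooled <- rbind(pad(visit1), pad(visit2))
  rownames(pooled) <- c(paste0(rownames(visit1), "_v1"), paste0(rownames(visit2), "_v2"))
  fit <- community_classes(pooled, ...)
  l1 <- fit$labels[paste0(shared, "_v1")]
  l2 <- fit$labels[paste0(shared, "_v2")]
  ok <- !is.na(l1) & !is.na(l2)
  l1 <- l1[ok]; l2 <- l2[ok]
  if (length(l1) < 2) stop("fewer than 2 paired subjects survive clustering")
  lev <- sort(unique(c(l1, l2)))
  transitions <- table(factor(l1, levels = lev), factor(l2, levels = lev),
                       dnn = c("visit1", "visit2"))
  structure(list(transitions = transitions,
                 maintained = diag(as.matrix(transitions)),
                 maintained_fraction = sum(diag(as.matrix(transitions))) / length(l1),
                 ari = adjusted_rand_index(unname(l1), unname(l2)),
                 n_subjects = length(l1),
                 labels_visit1 = l1, labels_visit2 = l2,
                 fit = fit),
            class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("Community-class transitions over", x$n_subjects, "paired subjects\n")
  print(x$transitions)
  cat(sprintf("maintained: %.1f%%   ARI: %.3f\n",
              100 * x$maintained_fraction, x$ari))
  invisible(x)
}
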