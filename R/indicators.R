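# Dufrene-Legendre indicator values: which genera characterise which
# community class. For genus i and cluster c, f is the fraction of cluster-c
# samples where the genus is present, a is cluster c's share of the
# per-cluster mean abundances, and the indicator value d = f * a; a genus
# with d = 1 is found in every sample of one cluster and nowhere else.
# Significance comes from permuting sample labels and comparing each genus's
# maximum-over-clusters d against its permutation distribution.

#' Indicator values of genera for a partition
#'
#' @param abund Proportion (or abundance) matrix, samples x genera.
#' @param labels Cluster labels per sample (named by sample id or in row
#'   order).
#' @param n_perm Number of label permutations for the p-value; the add-one
#'   correction `p = (1 + exceedances) / (1 + n_perm)` keeps p > 0.
#' @param seed Optional seed for the permutations.
#' @return Object of class `indval_scores`: `scores` (data frame with one
#'   row per genus at its best cluster: genus, cluster, f, a, d, p) and the
#'   full `f`, `a`, `d` cluster-by-genus matrices. Genera absent from every
#'   sample are excluded and messaged.
#' @export
indval <- function(abund, labels, n_perm = 999, seed = NULL) {
  if (!is.matrix(abund)) abund <- as.matrix(abund)
  labels <- .align_labels(labels, rownames(abund), nrow(abund))
  if (n_perm < 1) stop("n_perm must be >= 1")
  empty <- colSums(abund > 0) == 0
  if (any(empty)) {
    message("excluding ", sum(empty), " genera absent from all samples: ",
            paste(colnames(abund)[empty], collapse = ", "))
    abund <- abund[, !empty, drop = FALSE]
  }
  if (!ncol(abund)) stop("no genus is present in any sample")
  if (!is.null(seed)) set.seed(seed)
  obs <- .indval_matrices(abund, labels)
  obs_max <- apply(obs$d, 2, max)
  exceed <- integer(ncol(abund))
  for (b in seq_len(n_perm)) {
    perm <- .indval_matrices(abund, sample(labels))
    exceed <- exceed + (apply(perm$d, 2, max) >= obs_max - 1e-12)
  }
  pval <- (1 + exceed) / (1 + n_perm)
  best <- apply(obs$d, 2, which.max)
  cl <- rownames(obs$d)
  scores <- data.frame(genus = colnames(abund),
                       cluster = cl[best],
                       f = obs$f[cbind(best, seq_along(best))],
                       a = obs$a[cbind(best, seq_along(best))],
                       d = obs$d[cbind(best, seq_along(best))],
                       p = pval,
                       stringsAsFactors = FALSE, row.names = NULL)
  structure(list(scores = scores, f = obs$f, a = obs$a, d = obs$d,
                 n_perm = n_perm),
            class = "indval_scores")
}

.indval_matrices <- function(abund, labels) {
  g <- factor(labels)
  sizes <- as.numeric(table(g))
  f <- rowsum((abund > 0) + 0, g) / sizes          # clusters x genera
  meanab <- rowsum(abund, g) / sizes
  tot <- colSums(meanab)
  a <- sweep(meanab, 2, pmax(tot, .Machine$double.xmin), "/")
  list(f = f, a = a, d = f * a)
}

#' @export
print.indval_scores <- function(x, ...) {
  cat("Indicator values for", nrow(x$scores), "genera across",
      nrow(x$d), "clusters (", x$n_perm, "permutations)\n")
  top <- x$scores[order(-x$scores$d), ][seq_len(min(10, nrow(x$scores))), ]
  print(transform(top, f = round(f, 3), a = round(a, 3), d = round(d, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Select indicator genera by the significance and prevalence rules
#'
#' Keeps genera with a permutation p-value below `p_max` that are present in
#' at least `min_presence` of the samples of at least one cluster (defaults:
#' p < 0.01 and 50% presence).
#'
#' @param scores An [indval()] result.
#' @param p_max Upper p-value bound (exclusive).
#' @param min_presence Minimum within-cluster presence fraction (inclusive)
#'   required in at least one cluster.
#' @return The `scores` data frame with a logical `selected` column, ordered
#'   by decreasing indicator value.
#' @export
select_indicators <- function(scores, p_max = 0.01, min_presence = 0.5) {
  if (!inherits(scores, "indval_scores")) stop("scores must come from indval()")
  if (p_max <= 0 || p_max > 1) stop("p_max must lie in (0, 1]")
  if (min_presence < 0 || min_presence > 1) stop("min_presence must lie in [0, 1]")
  out <- scores$scores
  max_presence <- apply(scores$f, 2, max)
  out$selected <- out$p < p_max & max_presence[out$genus] >= min_presence
  out[order(-out$d), ]
}
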