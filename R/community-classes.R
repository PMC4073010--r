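# The central fit: from a genus count table to a community-class solution.
# community_classes() chains copy-number scaling, the proportion transform,
# a dissimilarity matrix, silhouette-scanned clustering and rule-based
# refinement, and returns a classed object with print/summary/plot methods.

#' Fit community classes to a genus count table
#'
#' Implements the community-class (enterotype-style) typing recipe: scale
#' read counts by 16S copy number, transform to proportions, build a
#' dissimilarity matrix (Bray-Curtis by default, root Jensen-Shannon as the
#' k-medoids replication path), scan candidate numbers of clusters by average
#' silhouette width, and refine the winning partition with two rules that
#' codify manual inspection: heterogeneous clusters are split when the split
#' raises their silhouettes, and clusters of fewer than two samples are
#' removed with the analysis redone on the remainder. Samples with negative
#' silhouette are flagged as outliers; each class is named by its dominant
#' taxon (highest median relative abundance).
#'
#' @param counts Integer count matrix, samples in rows, genus-level taxa in
#'   columns. A matrix whose rows already sum to 1 is accepted as
#'   ready-made proportions.
#' @param copy_numbers Optional named genus -> 16S copy-number map; missing
#'   genera fall back to `default_copy_number`.
#' @param default_copy_number Copy number used for unmapped genera.
#' @param metric `"bray-curtis"` (main pipeline) or `"jensen-shannon"`.
#' @param method Clusterer: `"hclust"` (complete linkage, main pipeline),
#'   `"kmedoids"`, or `"fuzzy"`.
#' @param k Fixed number of clusters; if `NULL` (default) the number is
#'   chosen by the silhouette scan over `k_range`.
#' @param k_range Candidate numbers of clusters for the scan.
#' @param refine Apply the split/removal refinement rules.
#' @param ambiguity_threshold Silhouette near-tie margin for flagging the
#'   scan as ambiguous.
#' @param high_threshold Per-cluster mean silhouette regarded as "high" by
#'   the refinement split rule.
#' @param split_threshold Per-cluster mean silhouette below which a cluster
#'   is a split candidate (when some other cluster is high).
#' @param max_iterations Refinement iteration cap.
#' @param seed Optional seed forwarded to stochastic clusterers.
#' @param ... Further arguments for the clusterer (e.g. `restarts`,
#'   `membership_exponent`).
#' @return An object of class `community_classes`; see Details.
#' @details The returned object contains `labels` (class per sample, classes
#'   numbered by decreasing size), `k`, `silhouette` (a
#'   [silhouette_profile()]), `selection` (the k scan), `dominant_taxa`,
#'   `outliers` (sample ids with negative silhouette), `removed_samples`
#'   (dropped by the <2-sample rule), `refinement_log`, `proportions`,
#'   `dist`, `metric` and `method`.
#' @export
community_classes <- function(counts, copy_numbers = NULL, default_copy_number = 1,
                              metric = c("bray-curtis", "jensen-shannon"),
                              method = c("hclust", "kmedoids", "fuzzy"),
                              k = NULL, k_range = 2:9, refine = TRUE,
                              ambiguity_threshold = 0.02,
                              high_threshold = 0.4, split_threshold = 0.2,
                              max_iterations = 10, seed = NULL, ...) {
  metric <- match.arg(metric)
  method <- match.arg(method)
  p <- .as_proportions(counts, copy_numbers, default_copy_number)
  d <- if (metric == "bray-curtis") bray_curtis(p) else jensen_shannon(p)
  if (is.null(k)) {
    sel <- select_k(d, k_range = k_range, method = method,
                    ambiguity_threshold = ambiguity_threshold, seed = seed, ...)
  } else {
    labels <- .cluster_labels(d, k, method, seed = seed, ...)
    sel <- structure(list(k_scan = data.frame(k = k, silhouette = silhouette_profile(d, labels)$mean),
                          k = k, labels = labels,
                          silhouette = silhouette_profile(d, labels),
                          ambiguous = FALSE, ambiguous_k = k, method = method,
                          ambiguity_threshold = ambiguity_threshold),
                     class = "cluster_selection")
  }
  if (refine) {
    fit <- refine_classes(d, sel, p, high_threshold = high_threshold,
                          split_threshold = split_threshold,
                          max_iterations = max_iterations,
                          k_range = k_range, seed = seed, ...)
  } else {
    fit <- .assemble_solution(d, sel$labels, p, sel, removed = character(0),
                              log = character(0))
  }
  fit$metric <- metric
  fit$method <- method
  fit$call <- match.call()
  fit
}

.as_proportions <- function(counts, copy_numbers, default_copy_number) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (all(abs(rowSums(counts) - 1) < 1e-6)) return(counts)
  validate_count_table(counts, integer_counts = FALSE)
  scaled <- if (is.null(copy_numbers)) counts else
    scale_by_copy_number(counts, copy_numbers, default = default_copy_number)
  to_proportions(scaled)
}

#' Refine a cluster selection into a community-class solution
#'
#' Applies the two manual-inspection rules iteratively: (i) a cluster whose
#' mean silhouette is below `split_threshold`, while some other cluster is
#' above `high_threshold`, is re-clustered at higher k and the split is kept
#' if its best resulting sub-cluster mean improves on the old mean; (ii)
#' clusters with fewer than two samples are removed and the silhouette scan
#' is redone on the remaining samples. Iteration stops at a fixed point.
#'
#' @param d A `dist` object over the samples.
#' @param selection A [select_k()] result on `d` (or any object with
#'   `labels` and `method`).
#' @param proportions Proportion matrix used to name classes by their
#'   dominant taxon.
#' @param high_threshold,split_threshold,max_iterations Refinement controls;
#'   see [community_classes()].
#' @param k_range Scan range used when re-clustering after removals.
#' @param seed Optional seed for stochastic clusterers.
#' @param ... Further clusterer arguments.
#' @return A `community_classes` object.
#' @export
refine_classes <- function(d, selection, proportions,
                           high_threshold = 0.4, split_threshold = 0.2,
                           max_iterations = 10, k_range = 2:9, seed = NULL, ...) {
  d <- .check_dist(d)
  method <- if (!is.null(selection$method)) selection$method else "hclust"
  ids <- attr(d, "Labels")
  labels <- .align_labels(selection$labels, ids, attr(d, "Size"))
  names(labels) <- ids
  active <- ids
  removed <- character(0)
  log <- character(0)
  no_split <- character(0)   # member-set keys of rejected splits
  converged <- FALSE
  for (iter in seq_len(max_iterations)) {
    dm <- as.matrix(d)[active, active]
    prof <- silhouette_profile(stats::as.dist(dm), labels[active])
    sizes <- table(labels[active])
    small <- names(sizes)[sizes < 2]
    if (length(small)) {
      drop_ids <- active[labels[active] %in% small]
      removed <- c(removed, drop_ids)
      active <- setdiff(active, drop_ids)
      log <- c(log, sprintf("iteration %d: removed %d cluster(s) with < 2 samples (%s); redoing scan on %d samples",
                            iter, length(small), paste(drop_ids, collapse = ", "), length(active)))
      sub_d <- stats::as.dist(as.matrix(d)[active, active])
      sel2 <- select_k(sub_d, k_range = k_range, method = method, seed = seed, ...)
      labels[active] <- sel2$labels
      next
    }
    means <- prof$cluster_means
    member_key <- function(cl) paste(sort(active[labels[active] == cl]), collapse = "|")
    candidates <- names(means)[means < split_threshold & as.numeric(sizes[names(means)]) >= 4]
    candidates <- candidates[!vapply(candidates, member_key, "") %in% no_split]
    if (length(candidates) && max(means) >= high_threshold) {
      target <- candidates[which.min(means[candidates])]
      members <- active[labels[active] == target]
      sub_d <- stats::as.dist(as.matrix(d)[members, members])
      sub_range <- 2:max(2, min(max(k_range), length(members) - 1))
      sub_sel <- select_k(sub_d, k_range = sub_range, method = method, seed = seed, ...)
      proposal <- labels
      proposal[members] <- paste0(target, ".", sub_sel$labels)
      new_prof <- silhouette_profile(stats::as.dist(dm), proposal[active])
      new_means <- new_prof$cluster_means[paste0(target, ".", unique(sub_sel$labels))]
      # a split is kept only if it carves out a genuinely well-clustered
      # sub-class, not merely a marginal rearrangement
      if (max(new_means, na.rm = TRUE) > means[[target]] + 1e-9 &&
          max(new_means, na.rm = TRUE) >= high_threshold) {
        labels <- proposal
        log <- c(log, sprintf("iteration %d: split cluster '%s' (mean s %.3f, n = %d) into %d sub-clusters (means %s)",
                              iter, target, means[[target]], length(members), sub_sel$k,
                              paste(sprintf("%.3f", new_means), collapse = "/")))
        next
      }
      no_split <- c(no_split, member_key(target))
      log <- c(log, sprintf("iteration %d: rejected split of cluster '%s' (no high-silhouette sub-cluster)",
                            iter, target))
      next
    }
    converged <- TRUE
    break
  }
  if (!converged) {
    cond <- structure(class = c("commclass_refine_error", "error", "condition"),
                      list(message = paste0("refinement did not converge in ", max_iterations,
                                            " iterations; log:\n", paste(log, collapse = "\n")),
                           call = sys.call(-1), log = log))
    stop(cond)
  }
  sub_d <- stats::as.dist(as.matrix(d)[active, active])
  if (!is.null(selection$k_scan) && nrow(selection$k_scan) > 1 && length(removed)) {
    selection <- select_k(sub_d, k_range = k_range, method = method, seed = seed, ...)
  }
  .assemble_solution(d, labels[active], proportions, selection, removed, log)
}

.assemble_solution <- function(d, labels, proportions, selection, removed, log) {
  active <- names(labels)
  sub_d <- stats::as.dist(as.matrix(d)[active, active])
  # renumber classes by decreasing size for stable reporting
  sizes <- sort(table(labels), decreasing = TRUE)
  new_ids <- stats::setNames(seq_along(sizes), names(sizes))
  labels_int <- stats::setNames(as.integer(new_ids[as.character(labels)]), active)
  prof <- silhouette_profile(sub_d, labels_int)
  p_active <- proportions[active, , drop = FALSE]
  dominant <- vapply(seq_along(sizes), function(cl) {
    med <- apply(p_active[labels_int == cl, , drop = FALSE], 2, stats::median)
    colnames(p_active)[which.max(med)]
  }, character(1))
  names(dominant) <- seq_along(sizes)
  structure(list(labels = labels_int,
                 k = length(sizes),
                 sizes = as.integer(sizes),
                 silhouette = prof,
                 selection = selection,
                 dominant_taxa = dominant,
                 outliers = prof$samples$sample[prof$samples$s < 0],
                 removed_samples = removed,
                 refinement_log = log,
                 proportions = proportions,
                 dist = d),
            class = "community_classes")
}

#' @export
print.community_classes <- function(x, ...) {
  cat("Community classes: ", x$k, " classes over ", length(x$labels),
      " samples (", x$method %||% "hclust", ", ", x$metric %||% "bray-curtis", ")\n", sep = "")
  cat("  mean silhouette width:", format(x$silhouette$mean, digits = 3), "\n")
  tab <- data.frame(class = seq_len(x$k), n = x$sizes,
                    dominant_taxon = unname(x$dominant_taxa),
                    mean_silhouette = round(unname(x$silhouette$cluster_means[as.character(seq_len(x$k))]), 3))
  print(tab, row.names = FALSE)
  if (length(x$outliers))
    cat("  outliers (negative silhouette):", length(x$outliers), "\n")
  if (length(x$removed_samples))
    cat("  removed by <2-sample rule:", paste(x$removed_samples, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.community_classes <- function(object, ...) {
  structure(list(fit = object,
                 k_scan = object$selection$k_scan,
                 ambiguous = isTRUE(object$selection$ambiguous),
                 ambiguous_k = object$selection$ambiguous_k,
                 log = object$refinement_log),
            class = "summary.community_classes")
}

#' @export
print.summary.community_classes <- function(x, ...) {
  print(x$fit)
  cat("\nSilhouette scan:\n")
  print(transform(x$k_scan, silhouette = round(silhouette, 4)), row.names = FALSE)
  if (x$ambiguous)
    cat("scan ambiguous between k in {", paste(x$ambiguous_k, collapse = ", "), "}\n")
  if (length(x$log)) cat("\nRefinement log:\n", paste(" -", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Plot a community-class solution in principal-coordinate space
#'
#' Ordinates the fit's dissimilarity matrix with [pcoa()] and draws the first
#' two axes with samples coloured by class; outliers are marked with a cross.
#'
#' @param x A `community_classes` object.
#' @param axes Which two ordination axes to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.community_classes <- function(x, axes = c(1, 2), ...) {
  active <- names(x$labels)
  ord <- pcoa(stats::as.dist(as.matrix(x$dist)[active, active]), n_axes = max(axes))
  xy <- ord$coordinates[, axes, drop = FALSE]
  cols <- x$labels
  graphics::plot(xy, col = cols, pch = 19,
                 xlab = paste0("PCo", axes[1]), ylab = paste0("PCo", axes[2]), ...)
  out <- active %in% x$outliers
  if (any(out)) graphics::points(xy[out, , drop = FALSE], pch = 4, cex = 1.4)
  graphics::legend("topright", legend = paste0(seq_len(x$k), ": ", x$dominant_taxa),
                   col = seq_len(x$k), pch = 19, cex = 0.8, bty = "n")
  invisible(ord)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
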