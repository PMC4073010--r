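# Principal coordinate analysis (classical metric scaling) of a
# dissimilarity matrix, for visualising community classes.

#' Principal coordinate analysis
#'
#' Classical scaling of the double-centred squared dissimilarities. Axes are
#' ordered by decreasing eigenvalue; axes with non-positive eigenvalues are
#' reported but excluded from the coordinates (no Cailliez/Lingoes
#' correction is applied). Each axis's sign is fixed so that its
#' largest-magnitude loading is positive, making outputs reproducible.
#'
#' @param d A `dist` object or square symmetric matrix.
#' @param n_axes Number of coordinate axes requested (1 <= n_axes < n).
#' @return Object of class `pcoa_ordination`: `coordinates` (n x m, m <=
#'   `n_axes`, column-centred), `eigenvalues` (all, descending),
#'   `negative_eigenvalues`, and `relative_eig` (positive eigenvalues as
#'   fractions of their sum).
#' @export
pcoa <- function(d, n_axes = 2) {
  d <- .check_dist(d)
  n <- attr(d, "Size")
  if (n_axes < 1 || n_axes > n - 1) stop("n_axes must lie in [1, n - 1]")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  tol <- 1e-9 * max(abs(eig), 1)
  n_pos <- sum(eig > tol)
  m <- min(n_axes, max(n_pos, 1))
  coords <- fit$points[, seq_len(min(m, ncol(fit$points))), drop = FALSE]
  # deterministic axis orientation
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords,
                 eigenvalues = eig,
                 negative_eigenvalues = eig[eig < -tol],
                 relative_eig = eig[eig > tol] / sum(eig[eig > tol]),
                 n_axes = ncol(coords)),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat("PCoA: ", nrow(x$coordinates), " samples on ", x$n_axes, " axes\n", sep = "")
  cat("  variance explained:",
      paste(sprintf("%.1f%%", 100 * x$relative_eig[seq_len(x$n_axes)]), collapse = ", "), "\n")
  if (length(x$negative_eigenvalues))
    cat("  ", length(x$negative_eigenvalues),
        " negative eigenvalues reported and excluded\n", sep = "")
  invisible(x)
}

#' Write ordination coordinates as a tab-delimited table
#'
#' @param ord A [pcoa()] result.
#' @param path Output path.
#' @param labels Optional class labels (named by sample id) appended as a
#'   `class` column.
#' @return `path`, invisibly.
#' @export
write_ordination <- function(ord, path, labels = NULL) {
  df <- data.frame(sample_id = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  if (!is.null(labels)) df$class <- labels[df$sample_id]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
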