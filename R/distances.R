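# Pairwise dissimilarity matrices. Distances are stats::dist objects with a
# "metric" attribute; helpers convert to/from square tab-delimited files.

.check_proportions <- function(p) {
  if (!is.matrix(p) || !is.numeric(p)) stop("expected a numeric proportion matrix")
  if (nrow(p) < 2) stop("at least two samples are required")
  if (any(p < 0) || any(p > 1 + 1e-9)) stop("proportions must lie in [0, 1]")
  if (any(abs(rowSums(p) - 1) > 1e-6))
    stop("rows must sum to 1; call to_proportions() first")
  invisible(p)
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(i, j) = sum_k |y_ik - y_jk| / sum_k (y_ik + y_jk) over the shared taxon
#' axis, computed on per-sample proportions. 0 means identical genus
#' composition; 1 means no genus is shared.
#'
#' @param p Proportion matrix (samples x taxa), rows summing to 1.
#' @return A `dist` object with `attr(, "metric") == "bray-curtis"`.
#' @export
bray_curtis <- function(p) {
  .check_proportions(p)
  d <- vegan::vegdist(p, method = "bray")
  attr(d, "metric") <- "bray-curtis"
  d
}

#' Root Jensen-Shannon divergence between samples
#'
#' Each row is smoothed with a pseudocount, renormalised, and the square root
#' of the base-2 Jensen-Shannon divergence is taken, giving a metric bounded
#' by 1.
#'
#' @param p Proportion matrix (samples x taxa), rows summing to 1.
#' @param pseudocount Small positive value added to every cell before
#'   renormalisation, so zero cells do not produce infinite log-ratios.
#' @return A `dist` object with `attr(, "metric") == "root-jsd-base2"`.
#' @export
jensen_shannon <- function(p, pseudocount = 1e-6) {
  .check_proportions(p)
  if (length(pseudocount) != 1 || !is.finite(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be a single positive value")
  q <- p + pseudocount
  q <- q / rowSums(q)
  n <- nrow(q)
  # H(m) - (H(p) + H(q))/2 with base-2 entropies, expanded over all pairs
  h <- function(v) -rowSums(v * log2(v))
  hr <- h(q)
  d2 <- matrix(0, n, n, dimnames = list(rownames(q), rownames(q)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      m <- (q[i, ] + q[j, ]) / 2
      jsd <- -sum(m * log2(m)) - (hr[i] + hr[j]) / 2
      d2[i, j] <- d2[j, i] <- sqrt(max(jsd, 0))
    }
  }
  d <- stats::as.dist(d2)
  attr(d, "metric") <- "root-jsd-base2"
  d
}

#' Write a dissimilarity matrix as a square tab-delimited file
#'
#' @param d A `dist` object or square symmetric matrix with ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1] <- "sample_id"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a square tab-delimited dissimilarity matrix
#'
#' @param path Path written by [write_distance_matrix()] (or any square
#'   id-headed matrix file).
#' @return A `dist` object.
#' @export
read_distance_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m)) stop("distance matrix file is not square")
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix file is not symmetric")
  stats::as.dist(m)
}
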