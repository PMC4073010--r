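# Genus-by-sample count tables: reading, validation, copy-number scaling,
# proportion transform and rarefaction. Tables are base matrices with
# rownames = sample ids and colnames = genus labels.

#' Validate a genus count table
#'
#' Checks the invariants every downstream step assumes: a numeric matrix of
#' non-negative, finite counts with unique, non-empty sample (row) and genus
#' (column) names.
#'
#' @param x A numeric matrix, samples in rows, genus-level taxa in columns.
#' @param integer_counts Require whole-number entries (TRUE for raw read
#'   counts; scaled tables are real-valued).
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant.
#' @export
validate_count_table <- function(x, integer_counts = TRUE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("count table must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("count table must have sample ids as rownames and taxon labels as colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate sample ids: ", paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate taxon labels: ", paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (any(!is.finite(x)))
    stop("count table contains non-finite entries")
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at sample '%s', taxon '%s'",
                 rownames(x)[bad[1]], colnames(x)[bad[2]]))
  }
  if (integer_counts && any(abs(x - round(x)) > 1e-8))
    stop("count table contains non-integer entries; use integer_counts = FALSE for scaled tables")
  invisible(x)
}

#' Read a tab-delimited genus count table
#'
#' The expected layout is the one genus-level classifiers emit: a header row
#' of genus labels, one row per sample with the sample id in the first column,
#' and read counts in the remaining cells.
#'
#' @param path Path to a UTF-8, tab-delimited file.
#' @return A validated integer count matrix (samples x taxa).
#' @export
read_count_table <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(raw) < 2) stop("expected a sample-id column plus at least one taxon column")
  ids <- raw[[1]]
  taxa <- colnames(raw)[-1]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  colnames(cells) <- taxa   # data-frame subsetting would de-duplicate labels
  num <- suppressWarnings(array(as.numeric(cells), dim = dim(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(cells), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at sample '%s', taxon '%s': '%s'",
                 ids[bad[1]], colnames(cells)[bad[2]], cells[bad[1], bad[2]]))
  }
  dimnames(num) <- list(ids, colnames(cells))
  validate_count_table(num)
  num
}

#' Write a count table in the package's tab-delimited dialect
#'
#' @param x Count (or real-valued abundance) matrix, samples x taxa.
#' @param path Output path.
#' @param id_column Header for the sample-id column.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(x, path, id_column = "sample_id") {
  df <- data.frame(rownames(x), x, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a genus-to-16S-copy-number map
#'
#' Two tab-delimited columns: genus label, average 16S rRNA gene copy number
#' for species of that genus. All copy numbers must be positive.
#'
#' @param path Path to the file (a header row is detected and skipped).
#' @return Named numeric vector of copy numbers.
#' @export
read_copy_numbers <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t", quote = "",
                           comment.char = "", colClasses = "character")
  if (ncol(raw) < 2) stop("copy-number file must have two tab-delimited columns")
  if (is.na(suppressWarnings(as.numeric(raw[1, 2])))) raw <- raw[-1, , drop = FALSE]
  cn <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(cn)) stop("non-numeric copy number for genus '", raw[[1]][which(is.na(cn))[1]], "'")
  names(cn) <- raw[[1]]
  if (anyDuplicated(names(cn))) stop("duplicate genus in copy-number map")
  if (any(cn <= 0)) stop("copy numbers must be positive")
  cn
}

#' Scale read counts by 16S gene copy number
#'
#' Divides each genus's reads by that genus's average 16S rRNA gene copy
#' number, so that multi-copy taxa are not over-counted. Genera missing from
#' the map fall back to `default` and are recorded in the
#' `"defaulted_taxa"` attribute (and messaged).
#'
#' @param x Count matrix (samples x taxa).
#' @param copy_numbers Named numeric vector, genus -> average copy number.
#' @param default Copy number for genera absent from the map; 1 leaves their
#'   counts unchanged.
#' @return Real-valued scaled abundance matrix with the same dimnames.
#' @export
scale_by_copy_number <- function(x, copy_numbers, default = 1) {
  validate_count_table(x)
  if (length(default) != 1 || !is.finite(default) || default <= 0)
    stop("default copy number must be a single positive value")
  if (any(copy_numbers <= 0) || any(!is.finite(copy_numbers)))
    stop("copy numbers must be positive and finite")
  cn <- copy_numbers[colnames(x)]
  missing_taxa <- colnames(x)[is.na(cn)]
  cn[is.na(cn)] <- default
  if (length(missing_taxa))
    message(length(missing_taxa), " taxa missing from copy-number map, using default ",
            default, ": ", paste(missing_taxa, collapse = ", "))
  out <- sweep(x, 2, cn, "/")
  attr(out, "defaulted_taxa") <- missing_taxa
  out
}

#' Transform an abundance table to per-sample proportions
#'
#' Each row is divided by its total, so rows sum to one. Applied to
#' copy-number-scaled counts before distance computation and to rarefied raw
#' counts before diversity computation.
#'
#' @param x Non-negative abundance matrix (samples x taxa).
#' @return Matrix of proportions; every row sums to 1.
#' @export
to_proportions <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  totals <- rowSums(x)
  zero <- totals <= 0
  if (any(zero))
    stop("sample(s) with zero total abundance: ", paste(rownames(x)[zero], collapse = ", "))
  out <- x / totals
  attr(out, "defaulted_taxa") <- NULL
  out
}

#' Rarefy a count table to a common read depth
#'
#' Subsamples each sample's reads to exactly `depth` without replacement
#' (hypergeometric), removing depth bias before diversity estimation.
#' Samples with fewer than `depth` reads are dropped; their ids are kept in
#' the `"dropped_samples"` attribute and messaged.
#'
#' @param x Integer count matrix (samples x taxa).
#' @param depth Target reads per sample (>= 1).
#' @param seed Optional integer seed for the subsampling draw.
#' @return Rarefied count matrix whose rows each sum to `depth`.
#' @export
rarefy_counts <- function(x, depth = 1000, seed = NULL) {
  validate_count_table(x)
  if (length(depth) != 1 || depth < 1) stop("depth must be a positive integer")
  depth <- as.integer(round(depth))
  if (!is.null(seed)) set.seed(seed)
  keep <- rowSums(x) >= depth
  dropped <- rownames(x)[!keep]
  if (length(dropped))
    message(length(dropped), " sample(s) below depth ", depth, " dropped: ",
            paste(dropped, collapse = ", "))
  if (!any(keep)) stop("all samples fall below the rarefaction depth ", depth)
  kept <- x[keep, , drop = FALSE]
  at_depth <- rowSums(kept) == depth
  out <- kept
  if (any(!at_depth))
    # counts are validated integers; rrarefy's large-minimum-count heuristic
    # warning does not apply
    out[!at_depth, ] <- suppressWarnings(
      vegan::rrarefy(kept[!at_depth, , drop = FALSE], depth))
  storage.mode(out) <- "integer"
  attr(out, "dropped_samples") <- dropped
  out
}
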