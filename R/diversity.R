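# Alpha diversity, habitat typing and demographic associations. Shannon
# diversity is computed on counts rarefied to a common depth; habitats fall
# into type I (low diversity, one dominant genus, well-separated classes)
# or type II (diverse, diffusely structured) by the median Shannon index and
# the overall silhouette of the habitat's class solution.

#' Per-sample Shannon diversity after rarefaction
#'
#' Rarefies each sample to `depth` reads (samples below depth are dropped),
#' converts to proportions, and returns H' = -sum p_i ln p_i (natural log).
#'
#' @param counts Integer count matrix (samples x taxa).
#' @param depth Rarefaction depth in reads.
#' @param seed Optional seed for the rarefaction draw.
#' @return Object of class `diversity_profile`: `h` (named per-sample H'),
#'   `median`, `depth`, and `dropped_samples`.
#' @export
shannon_diversity <- function(counts, depth = 1000, seed = NULL) {
  rare <- rarefy_counts(counts, depth = depth, seed = seed)
  p <- to_proportions(rare)
  h <- vegan::diversity(p, index = "shannon")
  structure(list(h = h, median = stats::median(h), depth = depth,
                 dropped_samples = attr(rare, "dropped_samples")),
            class = "diversity_profile")
}

#' @export
print.diversity_profile <- function(x, ...) {
  cat("Shannon diversity at depth ", x$depth, ": ", length(x$h),
      " samples, median H' = ", format(x$median, digits = 3), "\n", sep = "")
  if (length(x$dropped_samples))
    cat("  dropped below depth:", length(x$dropped_samples), "sample(s)\n")
  invisible(x)
}

#' Correlation between cluster separation and alpha diversity
#'
#' Pearson correlation of per-habitat overall silhouette widths against
#' per-habitat median Shannon indices; in practice strongly negative, since
#' one-genus-dominated (low diversity) habitats form the crispest classes.
#'
#' @param silhouette Per-habitat overall mean silhouette widths (>= 3).
#' @param shannon Matching per-habitat median Shannon indices.
#' @return Signed Pearson coefficient.
#' @export
correlate_silhouette_diversity <- function(silhouette, shannon) {
  if (length(silhouette) != length(shannon)) stop("vectors must have equal length")
  if (length(silhouette) < 3) stop("at least 3 habitats are required")
  if (stats::sd(silhouette) == 0 || stats::sd(shannon) == 0)
    stop("zero variance in silhouette or diversity values")
  stats::cor(silhouette, shannon, method = "pearson")
}

#' Classify a habitat as type I or type II
#'
#' Type I: median Shannon index strictly below `shannon_low` (default 1.5)
#' and overall silhouette at least `silhouette_high` (default 0.5) — low
#' diversity with well-separated, one-genus-dominated classes. Everything
#' else is type II. Vectorised.
#'
#' @param median_shannon Median Shannon index (natural log).
#' @param silhouette Overall mean silhouette of the habitat's solution.
#' @param shannon_low,silhouette_high Typing thresholds.
#' @return Character vector of "I"/"II".
#' @export
classify_habitat_type <- function(median_shannon, silhouette,
                                  shannon_low = 1.5, silhouette_high = 0.5) {
  if (any(silhouette < -1 | silhouette > 1)) stop("silhouette must lie in [-1, 1]")
  ifelse(median_shannon < shannon_low & silhouette >= silhouette_high, "I", "II")
}

#' Categorise body-mass index
#'
#' Standard categories: `<25`, `25-<30`, `>=30`.
#'
#' @param bmi Numeric BMI values.
#' @return Factor with the three categories.
#' @export
categorize_bmi <- function(bmi) {
  cut(bmi, breaks = c(-Inf, 25, 30, Inf), right = FALSE,
      labels = c("<25", "25-<30", ">=30"))
}

#' Test demographic factors against community classes
#'
#' Categorical factors (gender, location, race/ethnicity, BMI category) are
#' tested with Fisher's exact test on the class-by-level count table;
#' continuous factors (age, pH) with one-way ANOVA across classes. A numeric
#' column named `bmi` is first categorised with [categorize_bmi()]. P-values
#' are Bonferroni-corrected within the family of factors tested in this
#' call.
#'
#' @param solution A `community_classes` fit, or a vector of class labels
#'   named by sample id.
#' @param metadata Data frame of per-sample factors, rownames (or a
#'   `sample_id` column) matching the solution's samples.
#' @param factors Columns to test (default: all non-id columns).
#' @param alpha Family-wise significance level after correction.
#' @param mc_limit Table size (total count) above which the exact test
#'   switches to seeded Monte-Carlo p-values.
#' @param mc_draws Monte-Carlo draws for large tables.
#' @param seed Optional seed for Monte-Carlo p-values.
#' @return Data frame: factor, test, raw `p`, Bonferroni `p_adj`,
#'   `significant`. Single-level factors are skipped with a message.
#' @export
associate <- function(solution, metadata, factors = NULL, alpha = 0.05,
                      mc_limit = 400, mc_draws = 1e5, seed = NULL) {
  labels <- if (inherits(solution, "community_classes")) solution$labels else solution
  if (is.null(names(labels))) stop("class labels must be named by sample id")
  metadata <- as.data.frame(metadata)
  if (is.null(rownames(metadata)) || all(rownames(metadata) == as.character(seq_len(nrow(metadata))))) {
    idcol <- intersect(c("sample_id", "sample", "subject_id"), colnames(metadata))
    if (length(idcol)) rownames(metadata) <- metadata[[idcol[1]]]
  }
  shared <- intersect(names(labels), rownames(metadata))
  if (length(shared) < 3) stop("metadata covers fewer than 3 clustered samples")
  labels <- factor(labels[shared])
  metadata <- metadata[shared, , drop = FALSE]
  if (is.null(factors))
    factors <- setdiff(colnames(metadata), c("sample_id", "sample", "subject_id"))
  if (!all(factors %in% colnames(metadata)))
    stop("unknown factor(s): ", paste(setdiff(factors, colnames(metadata)), collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(factors, function(f) {
    v <- metadata[[f]]
    if (is.numeric(v) && tolower(f) == "bmi") v <- categorize_bmi(v)
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) {
        message("factor '", f, "' is constant; skipped")
        return(NULL)
      }
      p <- summary(stats::aov(v ~ labels))[[1]][["Pr(>F)"]][1]
      data.frame(factor = f, test = "anova", p = p)
    } else {
      v <- factor(v)
      if (nlevels(droplevels(v)) < 2) {
        message("factor '", f, "' has a single level; skipped")
        return(NULL)
      }
      tab <- table(labels, v)
      p <- if (sum(tab) > mc_limit)
        stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value
      else
        tryCatch(stats::fisher.test(tab, workspace = 2e7)$p.value,
                 error = function(e)
                   stats::fisher.test(tab, simulate.p.value = TRUE, B = mc_draws)$p.value)
      data.frame(factor = f, test = "fisher", p = p)
    }
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable factor")
  out$p_adj <- stats::p.adjust(out$p, method = "bonferroni")
  out$significant <- out$p_adj < alpha
  rownames(out) <- NULL
  out
}

#' Test a single taxon's abundance against a binary factor
#'
#' Two-sided Mann-Whitney-Wilcoxon rank-sum test of a genus's relative
#' abundance between the two levels of a factor (e.g. gender), with
#' Bonferroni correction over the family of taxa being screened.
#'
#' @param abund Proportion matrix (samples x genera).
#' @param taxon Genus to test.
#' @param group Binary factor, named by sample id or in row order.
#' @param n_family Number of taxa in the screened family (Bonferroni
#'   multiplier).
#' @param alpha Significance level after correction.
#' @return One-row data frame: taxon, test, p, p_adj, significant.
#' @export
taxon_vs_group <- function(abund, taxon, group, n_family = 1, alpha = 0.05) {
  if (!taxon %in% colnames(abund)) stop("taxon '", taxon, "' not in the table")
  x <- abund[, taxon]
  if (!is.null(names(group))) group <- group[rownames(abund)]
  group <- factor(group)
  if (nlevels(droplevels(group)) != 2) stop("group must have exactly 2 levels")
  if (stats::sd(x) == 0) {
    warning("constant abundances for '", taxon, "'; p set to 1")
    p <- 1
  } else {
    p <- stats::wilcox.test(x ~ group, exact = NULL)$p.value
  }
  p_adj <- min(1, p * n_family)
  data.frame(taxon = taxon, test = "wilcoxon", p = p, p_adj = p_adj,
             significant = p_adj < alpha)
}
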