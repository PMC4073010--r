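# End-to-end pipeline runner behind the command-line wrapper (exec/commclass).
# Each command wires the package functions together, writes tab-delimited
# results plus a JSON manifest (parameters, seed, input checksums, version)
# into the output directory, and cleans up partial outputs on failure.

#' Default pipeline configuration
#'
#' Mirrors the standard settings of the typing recipe: Bray-Curtis
#' dissimilarity, complete linkage, silhouette scan over k = 2..9 with the
#' 0.02 ambiguity margin, rarefaction to 1,000 reads, 999 permutations with
#' the p < 0.01 and 50%-presence indicator rules, Bonferroni correction at
#' alpha = 0.05.
#'
#' @return Named list of defaults; override entries via the `config`
#'   argument of [run_pipeline()].
#' @export
default_run_config <- function() {
  list(metric = "bray-curtis", method = "hclust", k = NULL, k_range = 2:9,
       ambiguity_threshold = 0.02, high_threshold = 0.4, split_threshold = 0.2,
       refine = TRUE, depth = 1000, n_perm = 999, p_max = 0.01,
       min_presence = 0.5, alpha = 0.05, n_axes = 2, preset = "type_II_stool_like",
       n_subjects = 150, seed = 1, outdir = ".")
}

#' Read a pipeline configuration file
#'
#' @param path JSON (or YAML, if the yaml package is installed) file of
#'   configuration entries; unknown keys are rejected.
#' @return Configuration list merged over [default_run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package not installed")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  merge_run_config(cfg)
}

#' @rdname read_run_config
#' @param config Named list of overrides.
#' @export
merge_run_config <- function(config = list()) {
  base <- default_run_config()
  extra_ok <- c("abundance", "copy_numbers", "metadata", "labels", "abundance2",
                "switch_diagonal", "factors", "command")
  unknown <- setdiff(names(config), c(names(base), extra_ok))
  if (length(unknown)) stop("unknown config entries: ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Run one pipeline command
#'
#' Commands: `simulate` (write a synthetic table plus truth labels),
#' `cluster` (fit [community_classes()] and write per-sample labels and
#' silhouettes plus a JSON run summary), `indicators`, `compare` (ARI across
#' habitats), `stability`, `diversity`, `associate`, and `ordinate`. All
#' outputs land in `config$outdir` together with `manifest.json`; on error
#' the files written so far are removed.
#'
#' @param command One of the commands above.
#' @param config Named list of overrides of [default_run_config()], or a
#'   path readable by [read_run_config()]. Input paths: `abundance`,
#'   `abundance2` (second visit), `copy_numbers`, `metadata`, `labels`.
#' @return Invisibly, the list of files written.
#' @export
run_pipeline <- function(command = c("simulate", "cluster", "indicators",
                                     "compare", "stability", "diversity",
                                     "associate", "ordinate"),
                         config = list()) {
  command <- match.arg(command)
  cfg <- if (is.character(config)) read_run_config(config) else merge_run_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  out <- function(name) {
    f <- file.path(cfg$outdir, name)
    written <<- c(written, f)
    f
  }
  tryCatch({
    .run_command(command, cfg, out)
    inputs <- unlist(cfg[intersect(c("abundance", "abundance2", "copy_numbers",
                                     "metadata", "labels"), names(cfg))])
    manifest <- list(command = command,
                     parameters = cfg[setdiff(names(cfg), "outdir")],
                     input_md5 = if (length(inputs)) as.list(tools::md5sum(inputs)) else list(),
                     package_version = as.character(utils::packageVersion("commclass")),
                     outputs = basename(written))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, null = "null", digits = NA)
    invisible(written)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

.run_command <- function(command, cfg, out) {
  load_abund <- function(path) read_count_table(path)
  switch(command,
    simulate = {
      spec <- sim_preset(cfg$preset, n_subjects = cfg$n_subjects)
      if (!is.null(cfg$switch_diagonal)) {
        k <- spec$n_classes
        sm <- matrix((1 - cfg$switch_diagonal) / (k - 1), k, k)
        diag(sm) <- cfg$switch_diagonal
        spec <- community_sim_spec(n_subjects = spec$n_subjects,
                                   n_taxa = length(spec$taxa),
                                   n_classes = k, mixing = spec$mixing,
                                   dominance = spec$dominance,
                                   base_concentration = spec$base_concentration,
                                   signature_taxa = spec$signature_taxa,
                                   switch_matrix = sm)
      }
      if (is.null(spec$switch_matrix)) {
        sim <- simulate_habitat(spec, seed = cfg$seed)
        write_count_table(sim$counts, out("counts.tsv"))
        utils::write.table(data.frame(sample_id = names(sim$classes),
                                      class = sim$classes),
                           out("truth_labels.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      } else {
        sim <- simulate_longitudinal(spec, seed = cfg$seed)
        write_count_table(sim$visit1, out("counts_visit1.tsv"))
        write_count_table(sim$visit2, out("counts_visit2.tsv"))
        utils::write.table(data.frame(sample_id = names(sim$classes1),
                                      class_visit1 = sim$classes1,
                                      class_visit2 = sim$classes2),
                           out("truth_labels.tsv"), sep = "\t", quote = FALSE,
                           row.names = FALSE)
      }
    },
    cluster = {
      counts <- load_abund(cfg$abundance)
      cn <- if (!is.null(cfg$copy_numbers)) read_copy_numbers(cfg$copy_numbers)
      fit <- community_classes(counts, copy_numbers = cn, metric = cfg$metric,
                               method = cfg$method, k = cfg$k,
                               k_range = cfg$k_range, refine = cfg$refine,
                               ambiguity_threshold = cfg$ambiguity_threshold,
                               high_threshold = cfg$high_threshold,
                               split_threshold = cfg$split_threshold,
                               seed = cfg$seed)
      utils::write.table(data.frame(sample_id = names(fit$labels),
                                    label = fit$labels,
                                    silhouette = fit$silhouette$samples$s),
                         out("classes.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      summary_json <- list(k = fit$k,
                           k_scan = fit$selection$k_scan,
                           ambiguous = isTRUE(fit$selection$ambiguous),
                           ambiguous_k = fit$selection$ambiguous_k,
                           mean_silhouette = fit$silhouette$mean,
                           dominant_taxa = as.list(fit$dominant_taxa),
                           outliers = fit$outliers,
                           removed_samples = fit$removed_samples,
                           refinement_log = fit$refinement_log,
                           seed = cfg$seed)
      jsonlite::write_json(summary_json, out("cluster_summary.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    },
    indicators = {
      counts <- load_abund(cfg$abundance)
      p <- to_proportions(counts)
      labels <- .read_labels(cfg$labels)
      iv <- indval(p, labels, n_perm = cfg$n_perm, seed = cfg$seed)
      sel <- select_indicators(iv, p_max = cfg$p_max,
                               min_presence = cfg$min_presence)
      utils::write.table(sel, out("indicators.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    compare = {
      tables <- lapply(cfg$abundance, load_abund)
      names(tables) <- names(cfg$abundance) %||% paste0("habitat", seq_along(tables))
      ari <- cross_habitat_ari(tables, k_range = cfg$k_range,
                               metric = cfg$metric, method = cfg$method)
      write_distance_matrix(ari, out("ari_matrix.tsv"))
    },
    stability = {
      ts <- stability(load_abund(cfg$abundance), load_abund(cfg$abundance2),
                      metric = cfg$metric, method = cfg$method,
                      k_range = cfg$k_range, refine = cfg$refine, seed = cfg$seed)
      trans <- matrix(as.integer(ts$transitions), nrow(ts$transitions),
                      dimnames = dimnames(ts$transitions))
      jsonlite::write_json(list(classes = rownames(trans),
                                transitions = trans,
                                maintained_fraction = ts$maintained_fraction,
                                ari = ts$ari, n_subjects = ts$n_subjects),
                           out("stability.json"), auto_unbox = TRUE,
                           pretty = TRUE, digits = NA)
    },
    diversity = {
      div <- shannon_diversity(load_abund(cfg$abundance), depth = cfg$depth,
                               seed = cfg$seed)
      utils::write.table(data.frame(sample_id = names(div$h), shannon = div$h),
                         out("shannon.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    },
    associate = {
      labels <- .read_labels(cfg$labels)
      metadata <- utils::read.table(cfg$metadata, header = TRUE, sep = "\t",
                                    row.names = 1, check.names = FALSE)
      res <- associate(labels, metadata, factors = cfg$factors,
                       alpha = cfg$alpha, seed = cfg$seed)
      utils::write.table(res, out("associations.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    ordinate = {
      p <- to_proportions(load_abund(cfg$abundance))
      ord <- pcoa(bray_curtis(p), n_axes = cfg$n_axes)
      write_ordination(ord, out("ordination.tsv"))
    })
}

.read_labels <- function(path) {
  if (is.null(path)) stop("a labels file (sample_id, label) is required")
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  stats::setNames(df[[2]], df[[1]])
}
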