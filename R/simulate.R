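# Dirichlet-multinomial simulator of genus-level count tables with planted
# community classes, longitudinal class switching and metadata associations.
# Each class is a Dirichlet distribution over the taxa whose signature genus
# concentration is multiplied by a dominance factor; per-sample read depths
# are log-normal and counts multinomial. High dominance gives
# one-genus-dominated, low-diversity ("type I") communities with crisp
# classes; low dominance over a flat base gives diverse, weakly separated
# ("type II") communities.

.default_genus_labels <- function(n_taxa) {
  anchors <- c("Bacteroides", "Prevotella", "Ruminococcus", "Lactobacillus",
               "Gardnerella", "Propionibacterium", "Staphylococcus",
               "Corynebacterium", "Moraxella", "Streptococcus", "Haemophilus",
               "Veillonella", "Neisseria", "Treponema", "Porphyromonas",
               "Atopobium", "Sneathia", "Megasphaera", "Dialister", "Finegoldia")
  if (n_taxa <= length(anchors)) return(anchors[seq_len(n_taxa)])
  c(anchors, sprintf("Genus_%02d", seq_len(n_taxa - length(anchors))))
}

#' Specify a synthetic community-class habitat
#'
#' Defines the generative model: `n_classes` Dirichlet components over
#' `taxa`, each with a flat `base_concentration` and one signature genus
#' whose concentration is multiplied by `dominance`; subjects are assigned
#' classes by `mixing`, read depths are log-normal, and optional visit-2
#' switching and metadata models plant longitudinal and demographic
#' structure.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param n_taxa Number of genus-level taxa (labelled with familiar genus
#'   names for readability).
#' @param n_classes Number of planted community classes.
#' @param mixing Class mixing proportions (sum to 1); default equalish with
#'   decreasing weights.
#' @param dominance Multiplier(s) applied to each class's signature genus
#'   concentration; scalar or one per class. Larger values give stronger
#'   single-genus dominance (lower diversity, crisper classes).
#' @param base_concentration Dirichlet concentration shared by all taxa
#'   before the signature boost.
#' @param signature_taxa Signature genus per class (defaults to the first
#'   `n_classes` taxa).
#' @param depth_meanlog,depth_sdlog Log-normal read-depth parameters
#'   (default median 5,000 reads, so rarefaction to 1,000 rarely drops
#'   samples).
#' @param switch_matrix Optional class-by-class visit-2 transition
#'   probability matrix (rows summing to 1).
#' @param metadata_model Optional per-factor class-conditional model; see
#'   [metadata_model()].
#' @param seed Default seed carried with the spec.
#' @return Object of class `community_sim_spec`.
#' @export
community_sim_spec <- function(n_subjects = 200, n_taxa = 50, n_classes = 3,
                               mixing = NULL, dominance = 75,
                               base_concentration = 0.05,
                               signature_taxa = NULL,
                               depth_meanlog = log(5000), depth_sdlog = 0.5,
                               switch_matrix = NULL, metadata_model = NULL,
                               seed = NULL) {
  taxa <- .default_genus_labels(n_taxa)
  if (is.null(mixing)) {
    mixing <- rev(seq_len(n_classes))
    mixing <- mixing / sum(mixing)
  }
  if (length(mixing) != n_classes) stop("mixing must have one entry per class")
  if (abs(sum(mixing) - 1) > 1e-8) stop("mixing proportions must sum to 1")
  if (any(mixing <= 0)) stop("mixing proportions must be positive")
  dominance <- rep_len(dominance, n_classes)
  if (any(dominance <= 0) || base_concentration <= 0)
    stop("concentrations must be positive")
  if (is.null(signature_taxa)) signature_taxa <- taxa[seq_len(n_classes)]
  if (!all(signature_taxa %in% taxa)) stop("signature taxa must be among the taxa")
  conc <- matrix(base_concentration, n_classes, length(taxa),
                 dimnames = list(paste0("class", seq_len(n_classes)), taxa))
  for (c in seq_len(n_classes))
    conc[c, signature_taxa[c]] <- base_concentration * dominance[c]
  if (!is.null(switch_matrix)) {
    switch_matrix <- as.matrix(switch_matrix)
    if (!all(dim(switch_matrix) == n_classes))
      stop("switch_matrix must be ", n_classes, " x ", n_classes)
    if (any(switch_matrix < 0) || any(abs(rowSums(switch_matrix) - 1) > 1e-8))
      stop("switch_matrix rows must be probability distributions")
  }
  structure(list(n_subjects = n_subjects, taxa = taxa, n_classes = n_classes,
                 mixing = mixing, dominance = dominance,
                 base_concentration = base_concentration,
                 signature_taxa = signature_taxa, concentrations = conc,
                 depth_meanlog = depth_meanlog, depth_sdlog = depth_sdlog,
                 switch_matrix = switch_matrix, metadata_model = metadata_model,
                 seed = seed),
            class = "community_sim_spec")
}

#' Habitat presets mirroring the observed habitat archetypes
#'
#' `"type_I_vagina_like"`: three classes, one holding ~85% of subjects, very
#' high single-genus dominance (low Shannon diversity, silhouette well above
#' 0.5). `"type_II_stool_like"`: three moderately dominated classes of
#' comparable size (enterotype-like). `"type_II_oral_like"`: two weakly
#' separated classes over a flat, diverse background (silhouette below 0.2).
#'
#' @param name Preset name.
#' @param n_subjects Number of subjects (default 150).
#' @param seed Optional default seed stored in the spec.
#' @return A [community_sim_spec()].
#' @export
sim_preset <- function(name = c("type_I_vagina_like", "type_II_stool_like",
                                "type_II_oral_like"),
                       n_subjects = 150, seed = NULL) {
  name <- match.arg(name)
  switch(name,
    type_I_vagina_like = community_sim_spec(
      n_subjects = n_subjects, n_classes = 3, mixing = c(0.85, 0.09, 0.06),
      dominance = 1250, base_concentration = 0.02,
      signature_taxa = c("Lactobacillus", "Gardnerella", "Prevotella"),
      seed = seed),
    type_II_stool_like = community_sim_spec(
      n_subjects = n_subjects, n_classes = 3, mixing = c(0.5, 0.3, 0.2),
      dominance = 50, base_concentration = 0.05,
      signature_taxa = c("Bacteroides", "Prevotella", "Ruminococcus"),
      seed = seed),
    type_II_oral_like = community_sim_spec(
      n_subjects = n_subjects, n_classes = 2, mixing = c(0.5, 0.5),
      dominance = 4, base_concentration = 1,
      signature_taxa = c("Streptococcus", "Neisseria"),
      seed = seed))
}

.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), n, length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

.draw_counts <- function(spec, classes, ids) {
  n <- length(classes)
  depths <- pmax(1L, as.integer(round(stats::rlnorm(n, spec$depth_meanlog,
                                                    spec$depth_sdlog))))
  counts <- matrix(0L, n, length(spec$taxa), dimnames = list(ids, spec$taxa))
  for (i in seq_len(n)) {
    p <- .rdirichlet(1, spec$concentrations[classes[i], ])
    counts[i, ] <- stats::rmultinom(1, depths[i], p)[, 1]
  }
  counts
}

#' Simulate a genus count table with planted community classes
#'
#' Per subject: draw a class from the mixing proportions, genus proportions
#' from that class's Dirichlet, a read depth from the log-normal, and counts
#' from a multinomial.
#'
#' @param spec A [community_sim_spec()].
#' @param seed Seed for the draw (overrides `spec$seed`).
#' @return List with `counts` (subjects x taxa integer matrix) and `classes`
#'   (named true class labels).
#' @export
simulate_habitat <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_sim_spec"))
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  classes <- sample.int(spec$n_classes, spec$n_subjects, replace = TRUE,
                        prob = spec$mixing)
  names(classes) <- ids
  list(counts = .draw_counts(spec, classes, ids), classes = classes)
}

#' Simulate two visits with community-class switching
#'
#' Visit 1 is drawn as in [simulate_habitat()]; each subject's visit-2 class
#' is drawn from the `switch_matrix` row of its visit-1 class, and visit-2
#' abundances are re-drawn from the visit-2 class.
#'
#' @param spec A [community_sim_spec()] with a `switch_matrix`.
#' @param seed Seed for the draw (overrides `spec$seed`).
#' @return List with `visit1`, `visit2` (count matrices over the same
#'   subject ids) and `classes1`, `classes2`.
#' @export
simulate_longitudinal <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "community_sim_spec"))
  if (is.null(spec$switch_matrix))
    stop("spec has no switch_matrix; set one in community_sim_spec()")
  seed <- seed %||% spec$seed
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  classes1 <- sample.int(spec$n_classes, spec$n_subjects, replace = TRUE,
                         prob = spec$mixing)
  classes2 <- vapply(classes1, function(c)
    sample.int(spec$n_classes, 1, prob = spec$switch_matrix[c, ]), integer(1))
  names(classes1) <- names(classes2) <- ids
  list(visit1 = .draw_counts(spec, classes1, ids),
       visit2 = .draw_counts(spec, classes2, ids),
       classes1 = classes1, classes2 = classes2)
}

#' Class-conditional metadata model
#'
#' Describes how demographic factors depend on the planted class.
#' Categorical factors give a class-by-level probability matrix; continuous
#' factors give per-class normal means and a common sd. The default model
#' plants the associations typically reported for skin/vaginal classes: a
#' gender imbalance (odds ratio ~5 between class 1 and the others), a ~4
#' year age offset for class 1, and class-independent location, race and
#' BMI.
#'
#' @param n_classes Number of classes the model must cover.
#' @param gender_male_prob Per-class probability of "male".
#' @param age_mean Per-class mean age (years).
#' @param age_sd Common age standard deviation.
#' @param null_model If TRUE, every factor is class-independent (for null
#'   calibration).
#' @return A named list of factor models, for [simulate_metadata()].
#' @export
metadata_model <- function(n_classes = 3,
                           gender_male_prob = c(0.7, rep(0.3, n_classes - 1)),
                           age_mean = c(34, rep(30, n_classes - 1)),
                           age_sd = 5, null_model = FALSE) {
  if (null_model) {
    gender_male_prob <- rep(0.5, n_classes)
    age_mean <- rep(32, n_classes)
  }
  gender_male_prob <- rep_len(gender_male_prob, n_classes)
  age_mean <- rep_len(age_mean, n_classes)
  list(
    gender = list(type = "categorical", levels = c("male", "female"),
                  probs = cbind(gender_male_prob, 1 - gender_male_prob)),
    age = list(type = "continuous", mean = age_mean, sd = age_sd),
    location = list(type = "categorical", levels = c("StLouis", "Houston"),
                    probs = matrix(0.5, n_classes, 2)),
    race = list(type = "categorical",
                levels = c("hispanic", "not_hispanic"),
                probs = matrix(c(0.2, 0.8), n_classes, 2, byrow = TRUE)),
    bmi = list(type = "continuous", mean = rep(26, n_classes), sd = 4)
  )
}

#' Simulate per-sample metadata conditional on planted classes
#'
#' @param classes Named class labels (from [simulate_habitat()]).
#' @param model A [metadata_model()] (or the `metadata_model` of a spec).
#' @param factors Which factors to draw (default: all in the model; unknown
#'   names error).
#' @param seed Optional seed.
#' @return Data frame with rownames = sample ids and one column per factor.
#' @export
simulate_metadata <- function(classes, model = metadata_model(max(classes)),
                              factors = names(model), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!all(factors %in% names(model)))
    stop("unknown factor(s): ", paste(setdiff(factors, names(model)), collapse = ", "))
  n <- length(classes)
  cols <- lapply(factors, function(f) {
    m <- model[[f]]
    if (identical(m$type, "categorical")) {
      if (nrow(m$probs) < max(classes)) stop("model for '", f, "' covers too few classes")
      vapply(classes, function(c)
        sample(m$levels, 1, prob = m$probs[c, ]), character(1))
    } else {
      stats::rnorm(n, mean = m$mean[classes], sd = m$sd)
    }
  })
  names(cols) <- factors
  out <- data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- names(classes)
  out
}
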