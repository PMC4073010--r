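# commclass

Identification and characterisation of bacterial **community classes** —
enterotypes and their analogues in other body habitats — from genus-level
16S rRNA count tables.

Human-associated microbial communities often fall into a small number of
recurring configurations: stool samples split into *Bacteroides*-,
*Prevotella*- and *Ruminococcus*-dominated enterotypes, vaginal samples into
*Lactobacillus*-dominated versus anaerobic communities, skin into
*Propionibacterium*/*Staphylococcus*/*Corynebacterium* classes. `commclass`
implements the complete typing pipeline for anyone with a genus-by-sample
read-count table: it finds the classes, decides how many there are, names
them by their dominant genera, identifies the indicator taxa that define
them, and quantifies how classes agree across habitats and persist over
time.

## The method

Starting from a count table with samples in rows and genus-level taxa in
columns:

1. **Copy-number scaling.** Each genus's reads are divided by its average
   16S rRNA gene copy number so multi-copy taxa are not over-counted, then
   each sample is transformed to proportions *y*<sub>*i,k*</sub>.
2. **Dissimilarity.** The Bray-Curtis dissimilarity
   *d*(*i*, *j*) = Σ<sub>*k*</sub> |*y*<sub>*i,k*</sub> − *y*<sub>*j,k*</sub>| / Σ<sub>*k*</sub> (*y*<sub>*i,k*</sub> + *y*<sub>*j,k*</sub>)
   is computed for every sample pair (root Jensen-Shannon divergence with
   k-medoids is available as a replication path).
3. **Clustering and model selection.** Complete-linkage hierarchical
   clustering is cut at each candidate *k*; each partition is scored by the
   average silhouette width *s*(*i*) = (*b*(*i*) − *a*(*i*)) / max(*a*(*i*), *b*(*i*)),
   and the *k* with the highest mean silhouette wins. Near-ties (within
   0.02) are flagged for inspection.
4. **Refinement.** Two rules codify what an analyst would do by hand: a
   low-silhouette cluster sitting beside a well-formed one is re-clustered
   at higher *k* and the split is kept when it carves out a genuinely
   well-clustered sub-class; clusters with fewer than two samples are
   removed and the scan redone. Samples with negative silhouette are
   flagged as outliers.
5. **Characterisation.** Dufrene-Legendre indicator values
   *d*<sub>*i,c*</sub> = *f*<sub>*i,c*</sub> × *a*<sub>*i,c*</sub> with
   permutation p-values identify the genera defining each class (kept at
   p < 0.01 and ≥ 50% presence); the adjusted Rand index measures class
   agreement between habitats and between visits; rarefaction-based Shannon
   diversity together with the silhouette separates low-diversity,
   one-genus-dominated "type I" habitats from diverse, diffusely structured
   "type II" habitats; Fisher's exact test, ANOVA and rank-sum tests (with
   Bonferroni correction) relate classes to demographic factors.

A seeded Dirichlet-multinomial simulator generates genus tables with
planted classes, longitudinal switching and metadata associations, so every
stage of the pipeline is testable without any data download.

## Worked example

```r
library(commclass)

spec <- sim_preset("type_II_stool_like", n_subjects = 150, seed = 42)
sim  <- simulate_habitat(spec)           # counts + planted classes
fit  <- community_classes(sim$counts)    # the full typing pipeline
fit
#> Community classes: 3 classes over 150 samples (hclust, bray-curtis)
#>   mean silhouette width: 0.376
#>  class  n dominant_taxon mean_silhouette
#>      1 63    Bacteroides           0.384
#>      2 49     Prevotella           0.409
#>      3 38   Ruminococcus           0.322
#>   outliers (negative silhouette): 4

adjusted_rand_index(fit$labels, sim$classes)
#> 0.95

iv <- indval(to_proportions(sim$counts), fit$labels, n_perm = 199, seed = 42)
head(select_indicators(iv), 3)
#>          genus cluster    f     a     d     p selected
#>    Bacteroides       1 1.00 0.967 0.967 0.005     TRUE
#>     Prevotella       2 1.00 0.939 0.939 0.005     TRUE
#>   Ruminococcus       3 0.92 0.979 0.902 0.005     TRUE

div <- shannon_diversity(sim$counts, depth = 1000, seed = 42)
classify_habitat_type(div$median, fit$silhouette$mean)
#> "II"
```

The fit recovers the three planted enterotype-like classes (ARI 0.95
against the planted labels), names each by its dominant genus, and the
three planted signature genera emerge as the top indicator taxa. The
habitat's median Shannon index (1.39) and moderate silhouette classify it
as a type II (diverse, moderately separated) habitat. `plot(fit)` draws the
samples in principal-coordinate space coloured by class.

A command-line wrapper is installed as `exec/commclass`:

```sh
Rscript exec/commclass simulate --outdir sim --seed 3
Rscript exec/commclass cluster --abundance sim/counts.tsv --outdir run --seed 3
```

## Package layout

- `R/tables.R` — count-table I/O, copy-number scaling, proportions, rarefaction
- `R/distances.R` — Bray-Curtis and root Jensen-Shannon dissimilarities
- `R/silhouette.R`, `R/clustering.R` — silhouette profiles, clusterers, k selection, subsampling
- `R/community-classes.R` — the central `community_classes()` fit and refinement rules
- `R/indicators.R` — Dufrene-Legendre indicator values and selection rules
- `R/comparison.R` — adjusted Rand index, cross-habitat agreement, visit-to-visit stability
- `R/diversity.R` — Shannon diversity, habitat typing, demographic associations
- `R/ordination.R` — principal coordinate analysis
- `R/simulate.R` — Dirichlet-multinomial generator with planted structure
- `R/pipeline.R`, `exec/commclass` — end-to-end runner and CLI

See `vignettes/community-classes.Rmd` for the methodological details and
the reasoning behind the defaults.
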