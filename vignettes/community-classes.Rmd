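---
title: "Identifying microbial community classes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying microbial community classes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commclass)
```

## The problem

Genus-level 16S rRNA surveys of a body habitat produce a count table:
samples in rows, genera in columns, cells holding read counts. In many
habitats these samples are not spread uniformly over composition space but
concentrate around a few recurring configurations — *community classes*
(called enterotypes in stool). `commclass` asks, for a given habitat: do
such classes exist, how many are there, which genera define them, do the
same subjects fall into corresponding classes in other habitats, and do
subjects keep their class over time?

Clustering is treated here as an exploratory description, not a biological
proof of discreteness: the silhouette scan, ambiguity flag and refinement
log are designed to expose exactly how firm (or soft) the class structure
is.

## The typing pipeline

**Normalisation.** Read counts are divided by each genus's average 16S
gene copy number (a user-supplied two-column table; unmapped genera default
to 1.0, i.e. neutral scaling, and are logged) and converted to per-sample
proportions. Copy-number-scaled proportions feed the clustering; *raw*
counts rarefied to a fixed depth feed the diversity computation. These are
deliberately separate paths: copy-number correction removes a
multiplicative bias that would distort composition comparisons, while
rarefaction removes the depth dependence of diversity estimates.

**Dissimilarity.** Bray-Curtis on proportions is the main metric: bounded
in [0, 1], zero for identical composition, one for disjoint genus support.
It is not a metric in the triangle-inequality sense, which the downstream
steps (hierarchical clustering, silhouettes, PCoA) do not require. The
replication path uses the square root of the Jensen-Shannon divergence
with base-2 logarithms, which *is* a metric bounded by 1; rows are smoothed
with a pseudocount (default `1e-6`, applied before renormalisation) so
zero cells do not generate infinite log-ratios. The pseudocount only needs
to be well below the smallest meaningful proportion; at typical read
depths (thousands) anything at or below 1e-4 gives indistinguishable
distances.

**Clustering.** Complete linkage is the default agglomeration rule because
it produces compact clusters, which matches the phenomenon being sought —
tight groups dominated by one genus. `stats::hclust`/`cutree` stand behind
this step; ties in merge order follow their documented lexicographic
convention, so dendrograms are reproducible. Two alternatives operate on
the same dissimilarity matrix: `cluster::fanny` for fuzzy memberships
(membership exponent default 2, hard labels by maximal membership) and
partitioning around medoids (`cluster::pam`, greedy build + swap, plus 10
seeded random-restart initialisations keeping the best objective).

**Choosing k.** For each k in the scan range (default 2–9, wide enough for
every habitat structure we target) the partition is scored by the overall
mean silhouette width

\[ s(i) = \frac{b(i) - a(i)}{\max(a(i), b(i))} \]

with a(i) the mean dissimilarity of sample i to its own cluster's other
members and b(i) the smallest mean dissimilarity to any other cluster.
The k with the highest mean wins. Members of singleton clusters are
assigned s(i) = 0 (the standard convention: a singleton is neither well
nor badly clustered). When a competitor comes within 0.02 of the winner
the selection is flagged *ambiguous* — the margin below which two scans
are practically indistinguishable and a human would inspect both.

**Refinement.** Two rules encode that inspection:

* *Split rule.* If a cluster's mean silhouette falls below 0.2 while some
  other cluster sits at or above 0.4, the weak cluster's members are
  re-scanned at higher k. The split is accepted only if it carves out a
  sub-cluster whose mean silhouette beats the old mean *and* reaches the
  0.4 "high" bar — a heterogeneous group may legitimately leave behind a
  diffuse residue, but the split must produce at least one genuinely
  well-formed class. Requiring a high sub-cluster (rather than any
  improvement) is what keeps the iteration from endlessly rearranging
  diffuse clusters; rejected splits are remembered by member set and not
  retried.
* *Removal rule.* Clusters with fewer than two samples are removed and
  the silhouette scan is redone on the remaining samples. A class defined
  by one sample is not a population structure.

Iteration stops at a fixed point, with a cap (default 10) after which the
procedure errors with its log attached rather than returning a partition
it could not stabilise. The thresholds 0.4/0.2 are exposed as arguments;
they were fixed once, at design time, to reproduce the qualitative pattern
of the worked inspection they imitate (a 0.59/0.15 two-cluster solution
splitting into 0.49 and a near-zero residue). Samples with negative
silhouette are reported as outliers but kept in their classes; each class
is named by the genus with the highest median relative abundance among its
members.

These rules approximate, but cannot guarantee to match, an expert's
habitat-specific judgement — the expert may bring outside biological
knowledge that no threshold encodes. The refinement log exists so that
every automatic decision can be audited.

## Indicator genera

For genus i and cluster c, f is the fraction of cluster-c samples where
the genus is present (presence meaning proportion strictly > 0), a is
cluster c's share of the per-cluster mean abundances (so a sums to 1
across clusters), and the indicator value is d = f × a. Significance comes
from permuting sample labels: the statistic is each genus's maximum d over
clusters, and p = (1 + exceedances) / (1 + permutations) with 999
permutations by default — the add-one form guarantees p > 0 and makes the
test properly conservative. The p-value attaches to the argmax cluster.
Reported indicators are those with p < 0.01 that are present in at least
50% of the samples of at least one cluster; both thresholds are arguments.
Whether f is computed on counts or proportions is immaterial, since only
presence/absence enters it.

## Agreement and stability

The adjusted Rand index is computed from the label contingency table with
the permutation-model chance correction (1 for identical partitions,
expectation 0 under independence; the degenerate case where the correction
denominator vanishes — both partitions trivial — is defined as 1). For
habitat pairs, each habitat is re-clustered on the subjects shared by the
pair before comparison; the number of classes is re-selected on that
subset by default (the shared subset is a different cohort and deserves
its own scan), with a `fixed_k` option to carry over the full-cohort k.

Visit-to-visit stability pools both visits' samples and clusters them
*jointly*, so that visit-1 and visit-2 labels live in the same class
system and the subject-level transition matrix is directly meaningful.
The maintained fraction is the trace of that matrix over the number of
paired subjects.

## Diversity and habitat types

Shannon diversity H′ = −Σ p log p (natural logarithm) is computed per
sample after rarefying to 1,000 reads without replacement; samples below
the depth are dropped and listed. Habitats are then typed: **type I**
requires median H′ strictly below 1.5 *and* overall silhouette at least
0.5 — low-diversity habitats dominated by a single genus, whose classes
are crisp; everything else is **type II**. Across habitats the overall
silhouette and median diversity are strongly anti-correlated; the package
reports the signed Pearson coefficient as computed (negative), since
dominance by one genus simultaneously lowers entropy and tightens
clusters.

## Demographic associations

Categorical factors (gender, location, race/ethnicity, BMI categorised as
<25, 25–<30, ≥30) are tested against class membership with Fisher's exact
test; continuous factors (age, pH) with one-way ANOVA across classes.
Exact r×c p-values are computed by network enumeration for small tables
and by seeded Monte-Carlo (10⁵ draws) when the total count exceeds 400,
where enumeration becomes unreliable. Single-taxon comparisons between two
groups use the two-sided Mann-Whitney-Wilcoxon test. The Bonferroni family
is the set of factors tested in one `associate()` call (one habitat's
report); the correction is p·m capped at 1, and significance means
corrected p < 0.05. The family definition is a choice — there is no single
canonical family for such a report — and each result row records its raw
and corrected p so other corrections can be applied downstream.

## Ordination

PCoA is classical scaling of the double-centred squared dissimilarities
(`stats::cmdscale`). Axes are ordered by eigenvalue; negative eigenvalues
(expected for Bray-Curtis, which is not Euclidean-embeddable) are reported
but their axes excluded, with no Cailliez/Lingoes correction — the plot is
a visual companion to the clustering, not the inference itself. Each
axis's sign is fixed by making its largest-magnitude loading positive, so
coordinates are reproducible run to run.

## The synthetic generator

`community_sim_spec()` defines a Dirichlet-multinomial model: each class
is a Dirichlet distribution over the taxa with a flat base concentration
(default 0.05 over 50 genera) and one signature genus whose concentration
is multiplied by a *dominance* factor; subjects draw a class from the
mixing proportions, proportions from the class Dirichlet, a read depth
from a log-normal (median 5,000, so rarefaction to 1,000 rarely drops
anything), and counts from a multinomial. Dominance is the single knob
that moves a habitat along the type II → type I axis: raising it
simultaneously lowers Shannon diversity and raises the silhouette of the
fitted classes, which is the mechanism behind the observed
silhouette-diversity anti-correlation.

Longitudinal data re-draw each subject's visit-2 class from a
class-to-class transition matrix and then re-draw abundances; metadata are
drawn from class-conditional categorical or normal models (the default
plants a gender odds ratio of about 5 and a 4-year age offset on class 1,
with location, race and BMI class-independent).

Three presets encode the habitat archetypes: `type_I_vagina_like` (three
classes, one holding ~85% of subjects, very high dominance),
`type_II_stool_like` (three moderately dominated classes, 50/30/20
mixing), and `type_II_oral_like` (two weakly separated classes over a
flat, diverse background). Their dominance values (1250, 50, 4 on base
concentrations 0.02, 0.05, 1) were calibrated once at design time so the
presets land in their intended silhouette regimes (≳0.9, ~0.3–0.4, <0.05)
and keep the type I / type II ordering.

**What the generator does not emulate.** Real genus tables have heavier
tails, cross-taxon correlations (co-exclusion, phylogenetic structure),
contamination, and classes that are less cleanly Dirichlet; cohort
metadata confound each other rather than depending only on class. Tests
passing on generator output therefore demonstrate that the pipeline's
machinery is correct and powered under its own assumptions, not that any
particular real habitat will yield the same classes.

## Numerical and reproducibility choices

* Every stochastic operation (rarefaction, permutations, restarts,
  simulation, Monte-Carlo p-values) takes an explicit seed; the pipeline
  runner records the seed and input checksums in a JSON manifest.
* Proportion rows are validated to sum to 1 within 1e-9; silhouette,
  indicator and ARI computations are validated in the test suite against
  independent brute-force oracles at 1e-12.
* Degenerate inputs fail loudly with the offending sample or factor named:
  all-zero samples, single-cluster silhouettes, all-zero dissimilarity
  matrices, single-level factors, subsamples larger than the cohort.
* Validation problem sizes were chosen to exercise the method at realistic
  scale while keeping the whole suite fast: planted-recovery runs use
  60–200 subjects and 50 genera (the scale of one real habitat's cohort),
  permutation tests 199–999 permutations, and the subsampling analysis
  50 replicates per size.

## Known limitations

* The refinement rules are a fixed-threshold surrogate for expert
  inspection; on habitats with genuinely ambiguous structure (silhouette
  near the thresholds) the chosen k should be read together with the
  ambiguity flag and the full k scan, not as a point estimate.
* Bray-Curtis ignores phylogenetic relatedness; UniFrac-style distances
  are out of scope.
* The exact test's Monte-Carlo fallback makes very small p-values (below
  about 1e-5) resolution-limited for large tables.
* Copy-number maps are taken as given; the package does not ship one,
  since copy-number resources are versioned and the choice belongs to the
  analyst.
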