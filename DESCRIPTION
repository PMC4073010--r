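Package: commclass
Title: Community Class Identification from Genus-Level Microbiome Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identification and characterisation of bacterial community classes
    (enterotypes and their body-habitat analogues) from genus-level 16S rRNA
    count tables. Implements the full typing pipeline: 16S copy-number scaling,
    proportion transform, Bray-Curtis and root Jensen-Shannon dissimilarities,
    complete-linkage hierarchical, fuzzy and k-medoids clustering, silhouette
    based selection of the number of classes with ambiguity flagging and
    rule-based refinement, Dufrene-Legendre indicator genera with permutation
    tests, adjusted Rand index agreement across habitats and visits,
    rarefaction-based Shannon diversity and habitat typing, demographic
    association tests, principal coordinate ordination, and a seeded
    Dirichlet-multinomial simulator of genus tables with planted classes,
    longitudinal switching and metadata associations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vegan,
    cluster,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
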