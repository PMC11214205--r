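Package: holosel
Title: Holobiont Selection Analysis for Gut-Microbiota Enterotypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study host-genetic selection on gut-microbiota
    enterotypes in livestock populations. Provides genus-level abundance
    table handling (rarefaction, diversity, compositional transforms and
    filters), enterotype stratification by Jensen-Shannon divergence and
    partitioning around medoids with a stability filter, pedigree-based
    animal-model REML (average-information with EM fallback) for
    heritability, common-litter effects and genetic correlations, a
    liability-threshold simulator of a three-generation divergent breeding
    scheme on enterotype-driving taxa, fixed-effects line-contrast response
    analysis, and a shotgun-metagenomics layer (marker-gene quantification
    of metagenomic species, KEGG-ortholog roll-ups, Wilcoxon/Benjamini-
    Hochberg/Cliff's-Delta differential abundance and hypergeometric
    pathway enrichment). All analyses are exercisable on synthetic data
    produced by the included generators.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    vegan,
    emmeans,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
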