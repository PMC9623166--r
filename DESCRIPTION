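Package: rhizocore
Title: Core Co-Occurrence Network Modules and Keystone Taxa in Soil Microbiomes
Version: 0.1.0
Authors@R:
    person("Rhizocore", "Developers", email = "rhizocore@example.org",
           role = c("aut", "cre"))
Description: Infers microbial co-occurrence networks from OTU abundance
    tables (pairwise Spearman correlations with magnitude and significance
    thresholds), detects modules by modularity maximisation, identifies
    keystone taxa by a composite of degree, closeness and betweenness
    centrality, and links module abundance and richness to soil
    carbon- and nitrogen-cycling functional potential (functional-gene
    qPCR abundances, RubisCO activity, potential nitrification and
    denitrification rates). Includes soil process-rate estimation from
    raw assay data, 16S-identity mapping of OTUs to reference genomes
    with per-genome functional-gene content comparison, treatment-level
    statistics (ANOVA with Tukey HSD, Bray-Curtis, PERMANOVA), and a
    fully seeded synthetic community generator with planted module
    structure so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    vegan,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
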