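Package: compng
Title: Compositional Neural Gas Analysis of Marine Photoheterotroph Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of aerobic anoxygenic phototroph (AAP)
    amplicon communities profiled by pufM metabarcoding. Provides strict
    readers and writers for ASV count, taxonomy and sample-metadata tables;
    prevalence and read-depth filtering, taxonomic agglomeration, pseudo-count
    centered log-ratio (CLR) transformation and Aitchison distances; a
    from-scratch neural gas vector quantizer that clusters samples into
    best-matching units (BMUs) and links them to averaged biotic and abiotic
    environmental factors; repeated-rarefaction alpha diversity (observed
    richness, Shannon, Pielou); one-way PERMANOVA and PERMDISP permutation
    tests on distance matrices; and the concordance analysis between FISH-IR
    microscopy counts and metabarcoding pseudoabundances. A synthetic-data
    generator with planted compositional clusters and cluster-linked
    environmental gradients makes the whole pipeline testable without
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
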