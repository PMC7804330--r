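Package: seedmir
Title: miRNA Discovery and Expression Dynamics in Developing Seeds from
    Small RNA Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for calling known and novel microRNAs from
    small-RNA sequencing of developing seeds and for analysing their
    expression dynamics across a timepoint series. Known miRNAs are assigned
    with position-constrained mismatch rules against a miRBase-like
    reference; novel miRNAs are called from folded genomic windows using
    eight structural hairpin criteria (stem base pairs, free energy, hairpin
    and loop lengths, biased bulges, mature-region pairing, stem occupancy
    and the minimal folding energy index). Downstream stages cover
    reads-per-million normalisation, expression filtering, ANOVA and
    pairwise t-test differential expression with Benjamini-Hochberg
    correction, hierarchical clustering of abundance archetypes, PCA,
    thresholded Pearson co-expression networks, complementarity-scored
    target prediction, degradome cleavage-category calling and bipartite
    miRNA-to-function networks. A synthetic-data generator with planted
    ground truth supports end-to-end validation, and curated catalogs of
    miRNAs expressed in developing common bean (Phaseolus vulgaris) seeds
    are bundled.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    data.table,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
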