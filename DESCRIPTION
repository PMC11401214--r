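Package: nanomatch
Title: Nanobody Candidate Identification from VHH Amplicon Sequencing and Serum Proteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies nanobody (VHH) candidates by combining high-throughput
    amplicon sequencing of camelid heavy-chain-only antibody repertoires with
    mass-spectrometry peptide identifications from antigen-purified serum.
    Builds a translated VHH protein database from paired-end amplicon reads
    (overlap merging, IUPAC-aware fuzzy primer location, ORF extraction,
    hinge-variant classification, deduplication with read-count tracking),
    annotates framework and CDR regions by conserved anchor motifs with an
    IMGT-style position map, digests the database in silico under Expasy
    protease rules (trypsin, chymotrypsin high and low specificity), maps
    observed peptides back to sequences under isoleucine/leucine equivalence,
    scores sequences by CDR-weighted coverage, groups them into CDR3
    clonotypes, computes peptide uniqueness scores, and ranks and filters
    candidates (cross-antigen and VH-hallmark GLEW filters). A seeded
    simulator generates synthetic repertoires, reads and peptide observations
    with ground truth so the whole pipeline is testable end to end. Also
    includes a primer-coverage survey for repertoire-wide evaluation of
    primer designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
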