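Package: motifregulon
Title: Single-Genome Transcription-Factor Regulon Inference via Two-Block
    Motif Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers the putative regulon of a bacterial transcription factor
    from a single genome.  Starting from expression (and optional knockout
    fitness) data, a TF-seeded biclustering step estimates a high-confidence
    set of co-regulated genes, which is reduced to operon-head genes by a
    correlation-based adjacency filter.  A sequential Monte Carlo sampler
    then discovers the TF's binding motif of unknown width in the upstream
    sequences, using a two-block position-weight-matrix model whose core
    blocks are tested for palindromic, direct-repeat or inverted-repeat
    symmetry by a symmetrised cross-entropy measure.  The genome is scanned
    with the discovered motif using log-likelihood-ratio scores and exact
    p-values from the standard score-distribution dynamic program, and
    accepted sites are paired bidirectionally with downstream genes (with
    optional operon extension and intragenic sites) to assemble the regulon.
    Seeded generators for synthetic genomes, planted motifs, expression
    biclusters, operon structures and fitness matrices provide a fully
    self-contained test surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
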