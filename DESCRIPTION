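Package: domainprofiler
Title: Domain-Level Annotation and Length-Normalized Profiling of
    Short-Read Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Assigns short-read local-alignment hits to specific protein
    domains by intersecting subject (amino-acid) alignment coordinates
    with precomputed Pfam-style domain envelopes in a reference
    annotation table, using a configurable minimum-overlap rule
    (default: more than 20 aligned amino acids inside the envelope).
    Localized hit counts are expanded by read-cluster multiplicities,
    normalized for domain length against the longest domain considered,
    and rarefied to a fixed depth. Downstream profile analytics cover
    Bray-Curtis dissimilarity, complete-linkage clustering, Shannon
    diversity, and structure-versus-function dissimilarity correlation.
    Includes parsers for MG-RAST-style similarity ("650") and sequence
    agglomeration ("330") stage files and a synthetic-data generator
    with constructive ground truth for offline benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    vegan,
    ape,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
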