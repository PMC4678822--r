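Package: teindel
Title: Split-Read Detection of Transposable Element Insertions and Depletions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calls novel transposable-element (TE) insertions and reference-TE
    depletions from short genomic reads using a split-read strategy: reads that
    fail to map end-to-end to the reference genome or to TE consensus sequences
    are split into 22-nt termini, the termini are mapped independently, and
    discordant terminus pairs (one unique genome anchor plus a TE-consensus hit,
    or two distant unique genome anchors) are clustered into insertion and
    depletion calls. Each call carries a coverage ratio (CR) quantifying
    variant-versus-reference read support, a local-alignment score-ratio filter
    removes reads from unannotated repeats, and calls are annotated against gene
    and RepeatMasker-style tracks. Includes genomic landscape binning,
    per-family profiles, cross-sample comparison by rounded coordinates, and a
    fully deterministic synthetic-fixture generator (toy genomes, planted
    variants at chosen allele fractions, error-bearing reads) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Rcpp,
    methods,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
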