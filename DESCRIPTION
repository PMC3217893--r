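Package: dgetag
Title: Digital Gene Expression Tag Profiling with Gene-Model Extension
    and RNA-Seq Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of SAGE-like digital gene expression (DGE) tag
    libraries against predicted cDNA gene models. Performs in-silico
    restriction digestion (DpnII/NlaIII) of transcript models to build a
    per-model tag catalogue with authentic-tag identification and
    artifact-tag classification, extends gene models by genomic flanks to
    recover tags lost to truncated UTR annotations, classifies tag matches
    into five positional regions, matches observed 16-nt tags at zero
    mismatches, resolves tags shared among paralogous models to their
    authentic owner, normalizes counts to tags per million and RPKM,
    screens for fold-change differences with an expression floor, tests
    differential expression between unreplicated libraries with a
    conditional negative-binomial test, and measures trend concordance
    between DGE and RNA-Seq quantifications. Includes a deterministic
    synthetic-data generator (genomes, models, tag libraries, reads) with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
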