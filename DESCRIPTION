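Package: iridyn
Title: Intron Retention Dynamics from Read Coverage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies per-intron retention from RNA-seq read coverage as
    the intron retention index (IRI), the ratio of mean read depth over a
    shared intronic region to that over its flanking shared exonic regions.
    Reduces multi-isoform gene models to regions shared by every annotated
    isoform, applies coverage-completeness and IRI range filters, classifies
    retention trajectories across a time course (five-rule scheme against a
    monotone reference sequence) or between two conditions (delta-IRI with a
    t-test), relates retention changes to steady-state expression changes,
    and screens RNA-binding proteins and candidate target introns by binding
    density and expression criteria. A synthetic-data module generates gene
    models, genome sequence, per-base coverage and binding sites with known
    retention trajectories and a degradation factor coupling retention to
    expression, so every stage is verifiable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
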