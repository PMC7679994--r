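Package: polymeth
Title: Comparative Methylome Analysis for Polyploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Windowed differential-methylation analysis between genotypes of
    a polyploid plant from whole-genome bisulfite sequencing counts:
    binomial methylcytosine calling against the bisulfite non-conversion
    rate, 200-bp window DMR detection with Fisher's exact test and
    per-context effect-size gates, methylation-restoration analysis across a
    genome-merger series, DMR annotation to genes and transposable elements
    with hypergeometric enrichment, metagene and meta-TE profiles,
    transposable-element absence-variant calling from split and discordant
    read pairs, and reciprocal-best-hit homoeolog dyad and triad
    identification across subgenomes. Includes a seeded synthetic-data
    generator with planted ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
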