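Package: snoquant
Title: PolyA-Neutral Quantification of Multi-Copy ncRNA Families from Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Cluster-aware quantification of small non-coding RNA expression
    from stranded short-read (28 nt) sequencing. Duplicated ncRNA loci are
    merged into clusters, shared identical k-mers between paralogs are used to
    partition clusters into read-discriminable groups, and unique reads are
    counted at mRNA, cluster, group, member and arbitrary-region scope, with
    RPKM normalization carrying Poisson counting uncertainties. Includes a
    synthetic-data generator (toy genomes with controlled k-mer sharing, a
    Poisson read simulator and an exact-match toy aligner) so the whole
    pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer,
    igraph,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Matrix
Config/testthat/edition: 3
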