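Package: tssoccupancy
Title: TSS-Centered Histone-Mark Occupancy Profiling, Clustering and
    Expression Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for TSS-centered analysis of ChIP-seq coverage pileups:
    collapsing UCSC refGene annotation to one longest transcript per gene,
    depth-scaling bedGraph pileups to one million mappable reads, building
    strand-oriented genes-by-bins occupancy matrices over +/-5 kb of each
    transcription start site in 100-bp bins, partitioning genes into ordered
    occupancy classes by k-means, metagene and genotype-difference profiles,
    gene-set classification and EASE-score (modified one-sided Fisher)
    enrichment with Benjamini-Hochberg correction, and delta-delta-Ct
    relative-expression statistics for unpaired and paired qPCR designs.
    Includes a synthetic-data generator with four occupancy archetypes and
    planted genotype effects for offline, ground-truth-aware testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils
Suggests:
    GenomicRanges,
    jsonlite,
    mclust,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
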