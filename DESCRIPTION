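Package: telopirna
Title: Telomeric piRNA Cluster Profiling with Supporting qPCR and Cytology Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for strand-specific length profiling of small RNAs
    from a telomeric transposon piRNA cluster: 3'-linker trimming by exact 6-mer
    detection, exact full-length genome mapping on both strands, ncRNA/pre-miRNA
    read removal, depth-normalized strand-split length histograms, 19-22 nt versus
    23-29 nt size-class quantification (excluding the 21 nt endo-siRNA peak),
    cluster attribution of telomeric reads, and the ping-pong 10 nt 5'-overlap
    signature. Companion tools compute efficiency-corrected ChIP-qPCR percent
    input, fold change versus wild type, relative genomic copy number against a
    single-copy reference, and per-embryo anaphase/telophase bridge statistics.
    A synthetic-data module generates toy genomes, genotype-specific libraries,
    qPCR plates and embryo count tables with ground truth for parameter-recovery
    testing.
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
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods,
    graphics
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
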