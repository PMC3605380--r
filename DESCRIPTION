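Package: plastidkit
Title: Chloroplast Genome Assembly and Pooled SNP Discovery from
    Whole-Genome Shotgun Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for assembling whole chloroplast
    (plastid) genomes from whole-genome shotgun short reads without a
    close reference, and for detecting chloroplast SNPs in pooled
    samples. Provides a read simulator for circular quadripartite
    plastomes (LSC-IRb-SSC-IRa), quality trimming and deterministic
    subsampling, a de Bruijn unitig assembler run at two k-mer sizes,
    Karlin-Altschul E-value binning of contigs against a plastome
    database, two-overlapping-reference scaffolding that recovers both
    inverted repeats, pooled-sample SNP calling with minimum variant
    frequency and coverage thresholds, and median-joining chlorotype
    networks for phylogeography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
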