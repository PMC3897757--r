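Package: ldhier
Title: Hierarchical Visualization of Perfect-LD Blocks as Genome Browser Tracks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds "LD architectures" from unphased diploid genotype panels:
    blocks (clusters) of SNPs in perfect linkage disequilibrium (r^2 = 1)
    that are hierarchically ordered by their pairwise LD, centered on a
    gene, a reference SNP, a genomic region, or a whole chromosome.
    Pairwise r^2 is estimated natively by two-locus EM haplotype-frequency
    estimation; blocks are clustered by average linkage on 1 - r^2
    distances; results are exported as UCSC-compatible BED12 custom tracks
    and per-cluster SNP-id lists. Includes a reader for linkage-format
    (PED/MAP or PED/INFO) genotype data, a loader for precomputed pairwise
    r^2 tables, and a seeded simulator of panels with planted LD blocks.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    BiocGenerics,
    igraph,
    jsonlite,
    rtracklayer,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
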