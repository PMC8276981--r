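Package: methylkin
Title: Tile-Based Differential DNA Methylation Analysis for
    Intergenerational Sperm Methylome Studies
Version: 0.1.0
Authors@R:
    person("Methylkin", "Developers", email = "methylkin@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing sperm DNA methylomes across generations
    from reduced representation bisulfite sequencing (RRBS) count data.
    Implements 100 bp tile-based differential methylation calling with
    Benjamini-Hochberg control, per-CpG differential methylation and
    bedtools-style merging of proximal differentially methylated CpGs
    into regions, a cross-cohort overlap taxonomy (identical, nested,
    partial), genomic element and CpG island shore/shelf/open-sea
    annotation, repeat-class and young LINE-1 (L1Md) enrichment,
    developmental methylation-timing classification against whole-genome
    bin backgrounds, and ChIP RPKM joint profiles.  A beta-binomial
    synthetic-cohort generator with planted intergenerational
    epimutations provides ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
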