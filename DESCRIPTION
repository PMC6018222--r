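Package: panrescue
Title: Pan-Genome Analysis of Draft Bacterial Genomes with Read-Based
    Gene Rescue and Frameshift Repair
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline that improves the represented gene
    repertoire of draft prokaryotic genomes before comparative analysis.
    Reads that fail to map to the input contigs are assembled into candidate
    contigs, screened against the existing assembly, and appended when novel
    and at least 200 bp long.  Assembly-induced frameshifts -- single-base
    indels that split one gene into two consecutive coding sequences with
    the same product -- are detected from the annotation and repaired by a
    read pileup consensus against a reference gene, gated by a completeness
    threshold.  The improved gene sets then feed a native pan-genome
    analysis: all-vs-all protein similarity, thresholded gene-family
    clustering, core/accessory/unique partition, permutation pan/core
    curves with a Heaps-law openness fit, and a UPGMA tree on gene
    presence/absence.  A synthetic pan-genome and read simulator with a
    ground-truth manifest provides a fully reproducible test bed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
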