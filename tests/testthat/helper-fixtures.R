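# Shared fixture builders.  Everything is generated in code; nothing is
# read from stored data files.

# tiny deterministic genome: two genes on one contig with known intervals
tiny_genome <- function(genome_id = "T1") {
  spacer1 <- "GGATTAGCCA"
  geneA <- "ATGAAACCCGGGTTTACAGATAAA" # 24 nt: M K P G F T D K (no stop yet)
  geneA <- paste0(geneA, "TAA")
  spacer2 <- "CCTTAGGAACTAGGCA"
  geneB_fwd <- paste0("ATG", "GATTACGATTACGATTAC", "TGA")
  geneB <- revcomp(geneB_fwd)
  spacer3 <- "TTGGCCAATT"
  chrom <- paste0(spacer1, geneA, spacer2, geneB, spacer3)
  sA <- nchar(spacer1)
  eA <- sA + nchar(geneA)
  sB <- eA + nchar(spacer2)
  eB <- sB + nchar(geneB)
  feats <- data.frame(
    contig_id = "c1", start = c(sA, sB), end = c(eA, eB),
    strand = c("+", "-"),
    product = c("alpha protein", "beta protein"),
    locus_id = c("T1_g1", "T1_g2"), stringsAsFactors = FALSE)
  genome_annotation(genome_id, stats::setNames(chrom, "c1"), feats)
}

# EMBL fixture with three CDS features exercising the coordinate and
# qualifier rules (plain, complement, missing /product)
embl_fixture_file <- function() {
  path <- tempfile(fileext = ".embl")
  writeLines(c(
    "ID   ctgA; SV 1; linear; genomic DNA; STD; PRO; 30 BP.",
    "FH   Key             Location/Qualifiers",
    "FT   source          1..30",
    "FT   CDS             10..18",
    "FT                   /locus_tag=\"L1\"",
    "FT                   /product=\"DNA gyrase subunit A\"",
    "FT   CDS             complement(20..28)",
    "FT                   /locus_tag=\"L2\"",
    "FT                   /product=\"recombinase RecA\"",
    "FT   CDS             2..7",
    "FT                   /locus_tag=\"L3\"",
    "SQ   Sequence 30 BP;",
    "     atgaaacccg ggtttacaga tagcatgtaa",
    "//"), path)
  path
}

# read table from raw sequences
reads_from_seqs <- function(seqs, prefix = "r") {
  data.frame(id = sprintf("%s%03d", prefix, seq_along(seqs)),
             seq = seqs, qual = strrep("I", nchar(seqs)),
             mate = rep("unpaired", length(seqs)),
             orientation = rep("forward", length(seqs)),
             stringsAsFactors = FALSE)
}

# tiling error-free reads over a region: fixed step and length
tiling_reads <- function(region, read_len = 100L, step = 50L) {
  starts <- unique(c(seq(1L, nchar(region) - read_len + 1L, by = step),
                     nchar(region) - read_len + 1L))
  reads_from_seqs(substring(region, starts, starts + read_len - 1L))
}

random_dna_str <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# truth-derived reference databases from a simulate_pangenome() result
truth_ref_dbs <- function(sim) {
  nt <- sim$truth$family_seqs
  names(nt) <- sprintf("%s %s", names(nt),
                       sim$truth$family_products[names(nt)])
  prot <- vapply(sim$truth$family_seqs, function(s)
    sub("[*]$", "", translate_dna(s)), character(1))
  names(prot) <- names(nt)
  list(nt = nt, prot = prot)
}

# normalized family partition (set of member-key sets) for comparisons
family_sets <- function(keys_by_family) {
  unname(sort(vapply(keys_by_family, function(x)
    paste(sort(x), collapse = ","), character(1))))
}
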