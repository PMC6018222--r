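#' @importFrom Biostrings readBStringSet readDNAStringSet writeXStringSet
#'   BStringSet DNAStringSet getGeneticCode reverseComplement
#' @importFrom stats setNames
NULL

# Internal coordinates are 0-based half-open everywhere; EMBL and GFF3 are
# 1-based inclusive and converted only at the format boundary.

IUPAC_AMBIG <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Normalize a DNA string
#'
#' Uppercases, maps U to T, collapses IUPAC ambiguity codes to N, and rejects
#' anything outside the resulting `{A,C,G,T,N}` alphabet.  N never counts as a
#' match in any aligner in this package.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @keywords internal
normalize_dna <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  x <- chartr(paste(IUPAC_AMBIG, collapse = ""),
              strrep("N", length(IUPAC_AMBIG)), x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1], regexpr("[^ACGTN]", x[bad][1]))
    stop("invalid DNA character '", ch, "' in sequence", call. = FALSE)
  }
  x
}

#' Read a FASTA file
#'
#' @param path path to a FASTA file.
#' @param alphabet `"dna"` (normalized: uppercase, U->T, ambiguity codes to N)
#'   or `"protein"` (uppercased, `*` allowed).
#' @return named character vector of sequences; names are the full header
#'   lines.  Duplicate ids and empty files are errors.
#' @export
read_fasta <- function(path, alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- names(ss)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id \"", ids[duplicated(ids)][1], "\" in ", path,
         call. = FALSE)
  }
  seqs <- as.character(ss)
  seqs <- if (alphabet == "dna") normalize_dna(seqs) else toupper(seqs)
  setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Read a FASTQ file (Sanger / Phred+33)
#'
#' @param path path to a FASTQ file.
#' @param mate mate label to assign to every read (`"unpaired"`, `"mate1"`,
#'   `"mate2"`).
#' @return a read table: `id`, `seq`, `qual`, `mate`, `orientation`.
#' @export
read_fastq <- function(path, mate = "unpaired") {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  qual <- as.character(S4Vectors::mcols(ss)$qualities)
  data.frame(id = names(ss), seq = normalize_dna(as.character(ss)),
             qual = qual, mate = mate, orientation = "forward",
             stringsAsFactors = FALSE)
}

#' Write a read table to FASTQ
#' @param reads read table with `id`, `seq`, `qual`.
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(nchar(reads$seq) == nchar(reads$qual)))
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+", reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Reverse complement
#' @param x character vector of DNA sequences over `{A,C,G,T,N}`.
#' @return reverse-complemented sequences.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate DNA in frame 0
#'
#' Straight codon-table lookup (NCBI table 11 by default): no
#' initiator-codon remapping (only [find_orfs()] applies start-codon
#' semantics), trailing partial codons dropped, internal stops rendered
#' `*`, codons containing N rendered `X`.
#'
#' @param seq a single DNA string, length >= 3.
#' @param table NCBI genetic code id.
#' @return protein string.
#' @export
translate_dna <- function(seq, table = 11L) {
  stopifnot(nchar(seq) >= 3L)
  code <- Biostrings::getGeneticCode(as.character(table))
  n <- nchar(seq) %/% 3L
  codons <- substring(seq, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Construct a genome annotation
#'
#' The central container: a genome id, its contigs (with an
#' original/rescued provenance tag) and its CDS features in 0-based
#' half-open coordinates, sorted by (contig, start).  Repaired gene
#' sequences from frameshift adjustment are carried as supplementary
#' records; contig sequences are never edited by repair.
#'
#' @param genome_id single string, unique within a project.
#' @param contigs named character vector of contig sequences, or a data frame
#'   with columns `id`, `seq`, `origin`.
#' @param features data frame with columns `contig_id`, `start`, `end`,
#'   `strand` (`+`/`-`), `product`, `locus_id`; zero-row allowed.
#' @param repaired_genes named character vector of consensus gene sequences
#'   keyed by locus id (frameshift repairs).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(genome_id, contigs, features = NULL,
                              repaired_genes = character()) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (!is.data.frame(contigs)) {
    stopifnot(!is.null(names(contigs)))
    contigs <- data.frame(id = names(contigs), seq = unname(contigs),
                          origin = "original", stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "seq", "origin") %in% names(contigs)),
            all(nzchar(contigs$id)), !anyDuplicated(contigs$id),
            all(nchar(contigs$seq) >= 1L),
            all(contigs$origin %in% c("original", "rescued")))
  if (is.null(features)) {
    features <- empty_features()
  }
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  req <- c("contig_id", "start", "end", "strand", "product", "locus_id")
  stopifnot(all(req %in% names(features)))
  if (nrow(features)) {
    stopifnot(all(features$contig_id %in% contigs$id),
              all(features$strand %in% c("+", "-")))
    len <- setNames(nchar(contigs$seq), contigs$id)
    ok <- features$start >= 0 & features$start < features$end &
      features$end <= len[features$contig_id]
    if (!all(ok)) {
      stop("feature out of contig bounds: locus ",
           features$locus_id[!ok][1], call. = FALSE)
    }
    features <- features[order(match(features$contig_id, contigs$id),
                               features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  structure(list(genome_id = genome_id, contigs = contigs,
                 features = features, repaired_genes = repaired_genes),
            class = "genome_annotation")
}

empty_features <- function() {
  data.frame(contig_id = character(), start = integer(), end = integer(),
             strand = character(), product = character(),
             locus_id = character(), stringsAsFactors = FALSE)
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation> ", x$genome_id, ": ",
      nrow(x$contigs), " contig(s), ",
      sum(nchar(x$contigs$seq)), " bp, ",
      nrow(x$features), " CDS feature(s)",
      if (length(x$repaired_genes)) {
        paste0(", ", length(x$repaired_genes), " repaired gene(s)")
      } else "",
      "\n", sep = "")
  invisible(x)
}

#' Contig sequences of an annotation as a named vector
#' @param ann a `genome_annotation`.
#' @return named character vector.
#' @export
contig_seqs <- function(ann) {
  setNames(ann$contigs$seq, ann$contigs$id)
}

#' Extract gene (CDS) nucleotide sequences in gene orientation
#'
#' Repaired loci take their sequence from the supplementary consensus
#' records rather than from the contig.
#'
#' @param ann a `genome_annotation`.
#' @return named character vector keyed by locus id.
#' @export
gene_seqs <- function(ann) {
  fx <- ann$features
  if (!nrow(fx)) return(setNames(character(), character()))
  cs <- contig_seqs(ann)
  out <- substring(cs[fx$contig_id], fx$start + 1L, fx$end)
  neg <- fx$strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  out <- setNames(unname(out), fx$locus_id)
  rep_ids <- intersect(names(ann$repaired_genes), fx$locus_id)
  out[rep_ids] <- ann$repaired_genes[rep_ids]
  out
}

#' Write a tabular output file (TSV with header row)
#' @param df data frame.
#' @param path output path.
#' @export
write_tsv_file <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a tabular file written by [write_tsv_file()]
#' @param path path to TSV.
#' @return data frame.
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

gff3_encode <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  x <- gsub("&", "%26", x, fixed = TRUE)
  x
}

#' Write annotation features as GFF3
#'
#' Internal 0-based half-open coordinates are emitted 1-based inclusive
#' with a `##gff-version 3` directive and per-contig sequence-region
#' pragmas.
#'
#' @param ann a `genome_annotation`.
#' @param path output path.
#' @export
write_gff3 <- function(ann, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(ann$contigs))) {
    writeLines(sprintf("##sequence-region %s 1 %d", ann$contigs$id[i],
                       nchar(ann$contigs$seq[i])), con)
  }
  fx <- ann$features
  if (nrow(fx)) {
    attrs <- sprintf("ID=%s;product=%s", gff3_encode(fx$locus_id),
                     gff3_encode(fx$product))
    lines <- sprintf("%s\tpanrescue\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                     fx$contig_id, fx$start + 1L, fx$end, fx$strand, attrs)
    writeLines(lines, con)
  }
  invisible(path)
}
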