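# Local-alignment helpers shared by the rescue filter, the annotator and
# the pan-genome similarity stage: Smith-Waterman via
# Biostrings::pairwiseAlignment plus Karlin-Altschul e-values.
# Nucleotide searches use +1/-3 with ungapped constants lambda = 1.33,
# K = 0.621; protein searches use BLOSUM62 with gap open 11 / extend 1 and
# gapped constants lambda = 0.267, K = 0.041.  The significance threshold
# is 1e-5 throughout the pipeline.

NT_KA <- list(lambda = 1.33, K = 0.621)
AA_KA <- list(lambda = 0.267, K = 0.041)

nt_submat <- function(match = 1, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", ] <- mismatch   # N never counts as a match
  m[, "N"] <- mismatch
  m
}

#' Karlin-Altschul e-value
#'
#' `E = K * m * n * exp(-lambda * S)` for a local alignment of score `S` in
#' a search space of query length `m` against database length `n`.
#'
#' @param score alignment score.
#' @param m,n query and database lengths.
#' @param constants list with `lambda` and `K`.
#' @return the expected number of chance alignments at this score.
#' @export
ka_evalue <- function(score, m, n, constants = NT_KA) {
  constants$K * m * n * exp(-constants$lambda * score)
}

# best local nucleotide alignment of query (either strand) against subject;
# returns score and the aligned subject span
nt_local_align <- function(query, subject, match = 1, mismatch = -3,
                           gap_open = 5, gap_ext = 2) {
  mat <- nt_submat(match, mismatch)
  best <- NULL
  for (q in c(query, revcomp(query))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_ext)
    if (is.null(best) || Biostrings::score(aln) > best$score) {
      rng <- Biostrings::subject(aln)
      best <- list(score = Biostrings::score(aln),
                   subject_start = Biostrings::start(rng) - 1L,
                   subject_end = Biostrings::end(rng))
    }
  }
  best
}

# local protein alignment; identity over alignment columns, coverage as
# aligned span over each sequence's length
aa_local_align <- function(query, subject, gap_open = 11, gap_ext = 1) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = gap_open, gapExtension = gap_ext)
  ncol_aln <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nmatch <- Biostrings::nmatch(aln)
  qspan <- Biostrings::width(Biostrings::pattern(aln))
  sspan <- Biostrings::width(Biostrings::subject(aln))
  list(score = Biostrings::score(aln),
       identity = if (ncol_aln > 0) nmatch / ncol_aln else 0,
       coverage_q = qspan / nchar(query),
       coverage_s = sspan / nchar(subject),
       q_start = Biostrings::start(Biostrings::pattern(aln)),
       q_span = qspan)
}

# amino-acid k-mer sets for prefiltering candidate pairs before full
# Smith-Waterman; two unrelated proteins rarely share a 5-mer
aa_kmer_sets <- function(seqs, k = 5L) {
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character())
    unique(substring(s, seq_len(L - k + 1L), k:L))
  })
}

# strip a trailing stop and validate translatability; returns NA when the
# protein has internal stops (untranslatable beyond tolerance)
protein_of <- function(nt_seq, table = 11L) {
  if (nchar(nt_seq) < 6L) return(NA_character_)
  aa <- translate_dna(nt_seq, table)
  aa <- sub("\\*$", "", aa)
  if (grepl("*", aa, fixed = TRUE)) return(NA_character_)
  if (!nzchar(aa)) return(NA_character_)
  aa
}
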