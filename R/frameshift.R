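# Frameshift handling: candidate detection as runs of consecutive
# same-product CDSs, reference selection by protein search against a local
# nucleotide database, pileup consensus of the raw reads against the
# reference, and admission of repairs that meet the completeness threshold
# (default 70% of reference positions covered).

#' Repair parameters
#'
#' @param completeness_min fraction of reference positions that must be
#'   covered for a repaired gene to be admitted (default 0.70).
#' @param max_intergenic_gap maximum gap in bp between consecutive CDSs of
#'   a candidate (default 300).
#' @param min_depth minimum read depth for a consensus position to count as
#'   covered (default 1).
#' @param excluded_products normalized products that never form candidates.
#' @param evalue_threshold reference-search e-value threshold.
#' @return a `repair_params` list.
#' @export
repair_params <- function(completeness_min = 0.70,
                          max_intergenic_gap = 300L, min_depth = 1L,
                          excluded_products = "hypothetical protein",
                          evalue_threshold = 1e-5) {
  stopifnot(completeness_min > 0, completeness_min <= 1, min_depth >= 1L)
  structure(list(completeness_min = completeness_min,
                 max_intergenic_gap = as.integer(max_intergenic_gap),
                 min_depth = as.integer(min_depth),
                 excluded_products = excluded_products,
                 evalue_threshold = evalue_threshold),
            class = "repair_params")
}

normalize_product <- function(x) {
  gsub("\\s+", " ", trimws(tolower(x)))
}

#' Detect frameshift candidates as consecutive same-product CDSs
#'
#' Scans each contig's ordered features; a maximal run of two or more
#' adjacent CDSs with equal normalized product (case-folded,
#' whitespace-collapsed), the same strand, and inter-feature gap at most
#' `max_intergenic_gap` becomes one candidate.  Excluded products (by
#' default `"hypothetical protein"`, which carries no frameshift signal)
#' never form candidates and are ignored when judging adjacency: the
#' junction between two halves of a broken gene often harbors spurious
#' unannotated ORFs, which must not mask the same-product run.  Every
#' feature ends up in exactly one candidate or in the clean set.
#'
#' @param ann a [genome_annotation()] (features sorted).
#' @param params a [repair_params()].
#' @return list: `candidates` (list of `frameshift_candidate`: `genome_id`,
#'   `contig_id`, `strand`, `product`, `members` (feature rows),
#'   `member_seqs`, `span`), and `clean` (feature data frame).
#' @export
detect_frameshift_candidates <- function(ann, params = repair_params()) {
  fx <- ann$features
  gseqs <- gene_seqs(ann)
  excluded <- normalize_product(params$excluded_products)
  candidates <- list()
  in_candidate <- rep(FALSE, nrow(fx))
  for (cid in unique(fx$contig_id)) {
    rows <- which(fx$contig_id == cid &
                    !(normalize_product(fx$product) %in% excluded))
    if (length(rows) < 2L) next
    np <- normalize_product(fx$product[rows])
    run_start <- 1L
    flush <- function(a, b) {
      if (b - a < 1L) return()
      if (np[a] %in% excluded) return()
      idx <- rows[a:b]
      in_candidate[idx] <<- TRUE
      members <- fx[idx, , drop = FALSE]
      candidates[[length(candidates) + 1L]] <<- structure(list(
        genome_id = ann$genome_id, contig_id = cid,
        strand = members$strand[1], product = members$product[1],
        members = members,
        member_seqs = gseqs[members$locus_id],
        span = c(min(members$start), max(members$end))),
        class = "frameshift_candidate")
    }
    for (i in seq_along(rows)[-1]) {
      joined <- np[i] == np[i - 1L] &&
        fx$strand[rows[i]] == fx$strand[rows[i - 1L]] &&
        (fx$start[rows[i]] - fx$end[rows[i - 1L]]) <=
          params$max_intergenic_gap
      if (!joined) {
        flush(run_start, i - 1L)
        run_start <- i
      }
    }
    flush(run_start, length(rows))
  }
  list(candidates = candidates,
       clean = fx[!in_candidate, , drop = FALSE])
}

aa_bitscore <- function(score) {
  (AA_KA$lambda * score - log(AA_KA$K)) / log(2)
}

#' Select the reference gene for a frameshift candidate
#'
#' Member translations are searched against the translated reference
#' nucleotide database; the reference with the best cumulative bit score
#' among those with at least one member hit at or below the e-value
#' threshold is returned.  Ties go to the lexicographically smaller
#' reference id.
#'
#' @param candidate a `frameshift_candidate`.
#' @param reference_nt_db named character vector of reference gene
#'   nucleotide sequences (non-empty).
#' @param params a [repair_params()].
#' @return the reference id, or `NA_character_` when nothing hits
#'   (candidate unrepairable).
#' @export
select_reference <- function(candidate, reference_nt_db,
                             params = repair_params()) {
  stopifnot(length(reference_nt_db) > 0L)
  hdr <- split_fasta_headers(names(reference_nt_db))
  ref_prot <- vapply(unname(reference_nt_db), protein_of, character(1))
  ok <- !is.na(ref_prot)
  if (!any(ok)) return(NA_character_)
  ids <- hdr$id[ok]
  ref_prot <- ref_prot[ok]
  n_db <- sum(nchar(ref_prot))
  ref_kmers <- aa_kmer_sets(ref_prot)
  members <- vapply(candidate$member_seqs, protein_of, character(1))
  members <- members[!is.na(members)]
  if (length(members) == 0L) return(NA_character_)
  cum_bits <- setNames(numeric(length(ids)), ids)
  any_hit <- setNames(logical(length(ids)), ids)
  for (m in members) {
    qk <- unlist(aa_kmer_sets(list(m)))
    cand <- which(vapply(ref_kmers, function(rk) any(qk %in% rk),
                         logical(1)))
    for (j in cand) {
      a <- aa_local_align(m, ref_prot[j])
      bits <- aa_bitscore(a$score)
      e <- nchar(m) * n_db * 2^(-bits)
      cum_bits[j] <- cum_bits[j] + bits
      if (e <= params$evalue_threshold) any_hit[j] <- TRUE
    }
  }
  if (!any(any_hit)) return(NA_character_)
  eligible <- which(any_hit)
  best <- eligible[order(-cum_bits[eligible], ids[eligible])][1]
  ids[best]
}

#' Pileup consensus of reads against a reference gene
#'
#' Reads are placed on the reference with the rescue mapper; each position
#' takes the majority base among covering reads (ties resolved to the
#' reference base), positions below `min_depth` emit N.  Completeness is
#' the fraction of reference positions covered at `min_depth`; the
#' consensus always has the reference length (ungapped pileup).
#'
#' @param reads read table.
#' @param reference_seq single reference nucleotide sequence (non-empty).
#' @param mapper a [mapper_params()].
#' @param min_depth minimum depth for a covered position.
#' @return list: `consensus` (string), `completeness` (fraction),
#'   `mean_depth`.
#' @export
pileup_consensus <- function(reads, reference_seq,
                             mapper = mapper_params(), min_depth = 1L) {
  stopifnot(nchar(reference_seq) > 0L)
  L <- nchar(reference_seq)
  bases <- c("A", "C", "G", "T")
  counts <- matrix(0L, nrow = 4L, ncol = L, dimnames = list(bases, NULL))
  if (!is.null(reads) && nrow(reads) > 0L) {
    pl <- place_reads(reads, c(ref = reference_seq), mapper)$placements
    for (i in seq_len(nrow(pl))) {
      rseq <- reads$seq[pl$read[i]]
      rlen <- nchar(rseq)
      if (pl$strand[i] == "-") {
        rseq <- revcomp(rseq)
        fwd_pos <- L - (pl$pos[i] + rlen)
      } else {
        fwd_pos <- pl$pos[i]
      }
      idx <- fwd_pos + seq_len(rlen)          # 1-based reference positions
      inb <- idx >= 1L & idx <= L
      rb <- strsplit(rseq, "", fixed = TRUE)[[1]][inb]
      keep <- rb %in% bases
      pos_keep <- idx[inb][keep]
      tab <- cbind(match(rb[keep], bases), pos_keep)
      for (r in seq_len(nrow(tab))) {
        counts[tab[r, 1], tab[r, 2]] <- counts[tab[r, 1], tab[r, 2]] + 1L
      }
    }
  }
  depth <- colSums(counts)
  ref_chars <- strsplit(reference_seq, "", fixed = TRUE)[[1]]
  cons <- character(L)
  for (p in seq_len(L)) {
    if (depth[p] < min_depth) {
      cons[p] <- "N"
      next
    }
    mx <- max(counts[, p])
    top <- bases[counts[, p] == mx]
    cons[p] <- if (ref_chars[p] %in% top) ref_chars[p] else top[1]
  }
  list(consensus = paste(cons, collapse = ""),
       completeness = mean(depth >= min_depth),
       mean_depth = mean(depth))
}

#' Repair frameshift candidates by reference-guided consensus
#'
#' For each candidate a reference is chosen, the raw reads are piled up
#' against it, and the repair is admitted when completeness reaches the
#' threshold.  Admitted candidates have their member CDSs replaced by one
#' CDS (span of the members, product preserved) whose gene sequence is the
#' consensus, carried as a supplementary gene record -- contig sequences
#' are never edited.  Inadmissible or unrepairable candidates keep their
#' original members.  The report counts candidates before and after
#' (remaining = not repaired).
#'
#' @param ann a [genome_annotation()].
#' @param candidates list from [detect_frameshift_candidates()].
#' @param reads read table of the genome's raw reads.
#' @param reference_nt_db named character vector of reference gene
#'   sequences (may be empty: everything is then unrepairable).
#' @param params a [repair_params()].
#' @param mapper a [mapper_params()].
#' @return list: `annotation` (repaired), `repairs` (data frame: product,
#'   members, reference, completeness, admitted), `n_candidates_before`,
#'   `n_candidates_after`.
#' @export
repair_genome <- function(ann, candidates, reads, reference_nt_db,
                          params = repair_params(),
                          mapper = mapper_params()) {
  fx <- ann$features
  repaired_genes <- ann$repaired_genes
  rows <- list()
  drop_loci <- character()
  add_feats <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    ref_id <- if (length(reference_nt_db)) {
      select_reference(cand, reference_nt_db, params)
    } else NA_character_
    completeness <- NA_real_
    admitted <- FALSE
    consensus <- NA_character_
    if (!is.na(ref_id)) {
      hdr <- split_fasta_headers(names(reference_nt_db))
      ref_seq <- unname(reference_nt_db[match(ref_id, hdr$id)])
      pc <- pileup_consensus(reads, ref_seq, mapper, params$min_depth)
      completeness <- pc$completeness
      admitted <- completeness >= params$completeness_min
      if (admitted) {
        consensus <- pc$consensus
        consensus <- substring(consensus, 1L,
                               (nchar(consensus) %/% 3L) * 3L)
      }
    }
    locus <- cand$members$locus_id[1]
    if (admitted) {
      drop_loci <- c(drop_loci, cand$members$locus_id)
      add_feats[[length(add_feats) + 1L]] <- data.frame(
        contig_id = cand$contig_id, start = cand$span[1],
        end = cand$span[2], strand = cand$strand, product = cand$product,
        locus_id = locus, stringsAsFactors = FALSE)
      repaired_genes[locus] <- consensus
    }
    rows[[ci]] <- data.frame(
      genome_id = cand$genome_id, contig_id = cand$contig_id,
      product = cand$product, n_members = nrow(cand$members),
      loci = paste(cand$members$locus_id, collapse = ","),
      reference = ref_id, completeness = completeness,
      admitted = admitted, stringsAsFactors = FALSE)
  }
  new_fx <- fx[!(fx$locus_id %in% drop_loci), , drop = FALSE]
  if (length(add_feats)) {
    new_fx <- rbind(new_fx, do.call(rbind, add_feats))
  }
  repairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(genome_id = character(), contig_id = character(),
               product = character(), n_members = integer(),
               loci = character(), reference = character(),
               completeness = numeric(), admitted = logical())
  list(annotation = genome_annotation(ann$genome_id, ann$contigs, new_fx,
                                      repaired_genes),
       repairs = repairs,
       n_candidates_before = length(candidates),
       n_candidates_after = sum(!repairs$admitted))
}
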