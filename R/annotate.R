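# Intrinsic annotator: maximal-ORF calling on both strands plus product
# assignment by best protein hit against a user-supplied reference set.
# Product strings come from the reference FASTA descriptions; ORFs without
# an acceptable hit become "hypothetical protein".

#' Annotator parameters
#'
#' @param min_orf_nt minimum ORF length in nt, start through stop inclusive
#'   (multiple of 3; default 120).
#' @param start_codons accepted start codons.
#' @param table NCBI genetic code id (default 11, bacterial).
#' @param product_min_identity minimum identity of the best reference hit.
#' @param product_min_coverage minimum query coverage of the best hit.
#' @return an `annotator_params` list.
#' @export
annotator_params <- function(min_orf_nt = 120L,
                             start_codons = c("ATG", "GTG", "TTG"),
                             table = 11L, product_min_identity = 0.5,
                             product_min_coverage = 0.7) {
  stopifnot(min_orf_nt %% 3L == 0L, min_orf_nt >= 3L,
            product_min_identity > 0, product_min_identity <= 1,
            product_min_coverage > 0, product_min_coverage <= 1)
  structure(list(min_orf_nt = as.integer(min_orf_nt),
                 start_codons = start_codons, table = as.integer(table),
                 product_min_identity = product_min_identity,
                 product_min_coverage = product_min_coverage),
            class = "annotator_params")
}

orfs_one_strand <- function(seq, strand, contig_len, params) {
  out <- list()
  L <- nchar(seq)
  for (f in 0:2) {
    if (L - f < 3L) next
    codon_pos <- seq(f, L - 3L, by = 3L)       # 0-based codon starts
    codons <- substring(seq, codon_pos + 1L, codon_pos + 3L)
    is_stop <- codons %in% STOP_CODONS
    is_start <- codons %in% params$start_codons
    stop_idx <- which(is_stop)
    seg_begin <- 1L
    for (k in stop_idx) {
      if (k > seg_begin) {
        rel <- match(TRUE, is_start[seg_begin:(k - 1L)])
        if (!is.na(rel)) {
          a <- codon_pos[seg_begin + rel - 1L]
          b <- codon_pos[k] + 3L
          if (b - a >= params$min_orf_nt) {
            # map to forward-strand coordinates
            iv <- if (strand == "+") c(a, b) else
              c(contig_len - b, contig_len - a)
            out[[length(out) + 1L]] <- data.frame(
              start = iv[1], end = iv[2], strand = strand,
              stringsAsFactors = FALSE)
          }
        }
      }
      seg_begin <- k + 1L
    }
  }
  out
}

#' Find all maximal ORFs on both strands of a contig
#'
#' An ORF runs from the first in-frame start codon after a stop (or the
#' contig edge) to the next in-frame stop inclusive; only the longest ORF
#' per (frame, stop) is reported.  Coordinates are 0-based half-open on the
#' forward strand regardless of ORF strand.
#'
#' @param contig_seq a single contig sequence.
#' @param params an [annotator_params()].
#' @return data frame: `start`, `end`, `strand`, sorted by (start, end).
#' @export
find_orfs <- function(contig_seq, params = annotator_params()) {
  L <- nchar(contig_seq)
  out <- c(orfs_one_strand(contig_seq, "+", L, params),
           orfs_one_strand(revcomp(contig_seq), "-", L, params))
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

split_fasta_headers <- function(headers) {
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), headers)
  data.frame(id = id, desc = desc, stringsAsFactors = FALSE)
}

#' Assign products to ORFs from a reference protein set
#'
#' Each ORF translation is searched against the reference proteins
#' (k-mer prefilter, then Smith-Waterman with BLOSUM62, gap open 11 /
#' extend 1).  The best hit meeting the identity and query-coverage
#' thresholds donates its FASTA description as the product; ties are broken
#' by higher score then lexicographically smaller reference id.  ORFs
#' without an acceptable hit become `"hypothetical protein"`.
#'
#' @param orfs ORF table from [find_orfs()] with a `contig_id` column.
#' @param contigs named character vector of contig sequences.
#' @param reference_proteins named character vector (headers may carry a
#'   description after the id); may be empty.
#' @param params an [annotator_params()].
#' @return the ORF table with a `product` column.
#' @export
assign_products <- function(orfs, contigs, reference_proteins,
                            params = annotator_params()) {
  orfs$product <- rep("hypothetical protein", nrow(orfs))
  orfs$ref_len <- rep(NA_integer_, nrow(orfs))
  if (nrow(orfs) == 0L) return(orfs)
  if (length(reference_proteins) > 0L) {
    hdr <- split_fasta_headers(names(reference_proteins))
    ord <- order(hdr$id)
    refs <- toupper(sub("\\*$", "", unname(reference_proteins)))[ord]
    hdr <- hdr[ord, , drop = FALSE]
    ref_kmers <- aa_kmer_sets(refs)
    for (i in seq_len(nrow(orfs))) {
      gseq <- substring(contigs[[orfs$contig_id[i]]],
                        orfs$start[i] + 1L, orfs$end[i])
      if (orfs$strand[i] == "-") gseq <- revcomp(gseq)
      prot <- protein_of(gseq, params$table)
      if (is.na(prot)) next
      # in-frame start codons (aa offsets): a maximal ORF may begin at a
      # spurious upstream start, so the coverage gate may re-anchor the
      # query at the start codon nearest the alignment's query start
      offs <- seq(0L, nchar(gseq) - 6L, by = 3L)
      start_offs_aa <- offs[substring(gseq, offs + 1L, offs + 3L) %in%
                              params$start_codons] %/% 3L
      qk <- unlist(aa_kmer_sets(list(prot)))
      cand <- which(vapply(ref_kmers, function(rk)
        any(qk %in% rk), logical(1)))
      best <- NULL
      for (j in cand) {
        a <- aa_local_align(prot, refs[j])
        if (a$identity < params$product_min_identity) next
        cov <- a$coverage_q
        if (cov < params$product_min_coverage) {
          anchor <- start_offs_aa[start_offs_aa <= a$q_start - 1L]
          if (length(anchor)) {
            cov <- a$q_span / (nchar(prot) - max(anchor))
          }
        }
        if (cov < params$product_min_coverage) next
        if (is.null(best) || a$score > best$score) {
          best <- list(score = a$score, desc = hdr$desc[j],
                       ref_len = nchar(refs[j]))
        }
      }
      if (!is.null(best)) {
        orfs$product[i] <- best$desc
        orfs$ref_len[i] <- best$ref_len
      }
    }
  }
  orfs
}

# homology-guided start-site refinement: a maximal ORF begins at the first
# in-frame start codon after a stop, which may sit upstream of the true
# gene start; when a reference hit exists, move the start to the in-frame
# start codon whose protein length is closest to the reference's
# (ties: most upstream)
refine_starts <- function(orfs, contigs, params) {
  for (i in seq_len(nrow(orfs))) {
    if (is.na(orfs$ref_len[i])) next
    a <- orfs$start[i]
    b <- orfs$end[i]
    gseq <- substring(contigs[[orfs$contig_id[i]]], a + 1L, b)
    if (orfs$strand[i] == "-") gseq <- revcomp(gseq)
    offs <- seq(0L, b - a - 6L, by = 3L)
    codons <- substring(gseq, offs + 1L, offs + 3L)
    cand <- offs[codons %in% params$start_codons]
    if (length(cand) == 0L) next
    aa_len <- (b - a - cand) %/% 3L - 1L
    pick <- cand[order(abs(aa_len - orfs$ref_len[i]), cand)][1]
    if (pick == 0L) next
    if ((b - a - pick) < params$min_orf_nt) next
    if (orfs$strand[i] == "+") orfs$start[i] <- a + pick
    else orfs$end[i] <- b - pick
  }
  orfs
}

# shadow-ORF suppression: an ORF without a reference hit that overlaps a
# product-assigned CDS by more than half of its own length is almost always
# a spurious call in the shadow of the real gene (reverse strand or
# alternate frame) and is dropped, as standard gene callers do
suppress_shadow_orfs <- function(orfs, max_overlap_frac = 0.5) {
  hyp <- which(orfs$product == "hypothetical protein")
  real <- which(orfs$product != "hypothetical protein")
  if (length(hyp) == 0L || length(real) == 0L) return(orfs)
  drop <- logical(nrow(orfs))
  for (i in hyp) {
    same <- real[orfs$contig_id[real] == orfs$contig_id[i]]
    if (length(same) == 0L) next
    ov <- pmax(0L, pmin(orfs$end[same], orfs$end[i]) -
                 pmax(orfs$start[same], orfs$start[i]))
    drop[i] <- max(ov) > max_overlap_frac * (orfs$end[i] - orfs$start[i])
  }
  orfs[!drop, , drop = FALSE]
}

#' Annotate a genome: ORF calling plus product assignment
#'
#' @param ann a [genome_annotation()] (features, if any, are replaced).
#' @param reference_proteins named character vector of reference proteins.
#' @param params an [annotator_params()].
#' @return a [genome_annotation()] with fresh CDS features; locus ids are
#'   `<genome>_<serial>` in (contig, start) order.
#' @export
annotate_genome <- function(ann, reference_proteins = character(),
                            params = annotator_params()) {
  cs <- contig_seqs(ann)
  all_orfs <- list()
  for (cid in names(cs)) {
    o <- find_orfs(cs[[cid]], params)
    if (nrow(o)) {
      o$contig_id <- cid
      all_orfs[[cid]] <- o
    }
  }
  if (length(all_orfs) == 0L) {
    return(genome_annotation(ann$genome_id, ann$contigs, empty_features()))
  }
  orfs <- do.call(rbind, c(all_orfs, list(make.row.names = FALSE)))
  orfs <- assign_products(orfs, cs, reference_proteins, params)
  orfs <- refine_starts(orfs, cs, params)
  orfs <- suppress_shadow_orfs(orfs)
  orfs <- orfs[order(match(orfs$contig_id, names(cs)), orfs$start,
                     orfs$end), , drop = FALSE]
  orfs$locus_id <- sprintf("%s_%05d", ann$genome_id, seq_len(nrow(orfs)))
  genome_annotation(ann$genome_id, ann$contigs,
                    orfs[c("contig_id", "start", "end", "strand",
                           "product", "locus_id")])
}
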