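# Gene-content rescue: reads that fail to map to the input contigs are
# assembled with a greedy exact-overlap assembler; assembled contigs are
# screened against the input assembly and appended when they have no
# significant hit (e-value 1e-5) and are at least 200 bp long.

#' Rescue-stage parameters
#'
#' @param min_contig_len length floor for admitting a rescued contig
#'   (default 200 bp).
#' @param evalue_threshold e-value at or below which a rescued contig is
#'   considered already represented (default 1e-5).
#' @param min_overlap minimum exact suffix-prefix overlap for the greedy
#'   assembler (default 30 bp).
#' @param min_assembly_identity identity required over the overlap
#'   (1 = exact; the assembler merges exact overlaps only).
#' @return a `rescue_params` list.
#' @export
rescue_params <- function(min_contig_len = 200L, evalue_threshold = 1e-5,
                          min_overlap = 30L, min_assembly_identity = 1) {
  stopifnot(min_contig_len >= 1L, evalue_threshold > 0, min_overlap >= 1L,
            min_assembly_identity > 0, min_assembly_identity <= 1)
  structure(list(min_contig_len = as.integer(min_contig_len),
                 evalue_threshold = evalue_threshold,
                 min_overlap = as.integer(min_overlap),
                 min_assembly_identity = min_assembly_identity),
            class = "rescue_params")
}

#' Assemble unmapped reads with a greedy overlap-layout-consensus engine
#'
#' Iteratively merges the pair of sequences with the longest exact
#' suffix-prefix overlap at or above `min_overlap`, considering both
#' strands, until no merge is possible.  Exact duplicates and reads
#' contained in another read (either orientation) are absorbed first.
#' Candidate overlaps are found through a hash of sequence prefixes, so
#' only exact-match positions are verified.  Deterministic given input
#' order: ties broken by longest overlap, then by the lexicographically
#' smallest merged id.
#'
#' @param reads read table (may be empty).
#' @param params a [rescue_params()].
#' @return named character vector of assembled contigs (names record the
#'   merge history), empty when `reads` is empty.
#' @export
assemble_unmapped <- function(reads, params = rescue_params()) {
  if (is.null(reads) || nrow(reads) == 0L) return(setNames(character(),
                                                           character()))
  min_o <- params$min_overlap
  # absorb duplicates and contained reads (either orientation)
  ids0 <- reads$id
  seqs0 <- reads$seq
  rcs0 <- revcomp(seqs0)
  ord <- order(-nchar(seqs0), seq_along(seqs0))
  ids <- character()
  seqs <- character()
  big <- "#"
  for (i in ord) {
    if (!grepl(seqs0[i], big, fixed = TRUE) &&
        !grepl(rcs0[i], big, fixed = TRUE)) {
      ids <- c(ids, ids0[i])
      seqs <- c(seqs, seqs0[i])
      big <- paste0(big, seqs0[i], "#")
    }
  }
  n <- length(seqs)
  if (n == 1L) return(setNames(seqs, ids))
  rcs <- revcomp(seqs)
  active <- rep(TRUE, n)
  # prefix hash: first min_o characters of each oriented sequence
  pref_env <- new.env(hash = TRUE, parent = emptyenv())
  add_prefixes <- function(i) {
    for (o in c(1L, 2L)) {
      s <- if (o == 1L) seqs[i] else rcs[i]
      if (nchar(s) < min_o) next
      key <- substr(s, 1L, min_o)
      pref_env[[key]] <- rbind(pref_env[[key]], c(i, o))
    }
  }
  oriented <- function(i, o) if (o == 1L) seqs[i] else rcs[i]
  # all suffix-prefix overlaps >= min_o from oriented sequence (i, o)
  overlaps_from <- function(i, o) {
    x <- oriented(i, o)
    nx <- nchar(x)
    if (nx <= min_o) return(NULL)
    starts <- 2L:(nx - min_o + 1L)
    kmers <- substring(x, starts, starts + min_o - 1L)
    rows <- list()
    for (w in seq_along(starts)) {
      hits <- get0(kmers[w], envir = pref_env, ifnotfound = NULL)
      if (is.null(hits)) next
      k <- nx - starts[w] + 1L
      for (h in seq_len(nrow(hits))) {
        j <- hits[h, 1L]
        if (j == i || !active[j]) next
        y <- oriented(j, hits[h, 2L])
        if (k > nchar(y) - 1L) next
        if (substring(x, starts[w], nx) == substring(y, 1L, k)) {
          rows[[length(rows) + 1L]] <- c(i, o, j, hits[h, 2L], k)
        }
      }
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }
  for (i in seq_len(n)) add_prefixes(i)
  tab <- do.call(rbind, lapply(seq_len(n), function(i)
    rbind(overlaps_from(i, 1L), overlaps_from(i, 2L))))
  repeat {
    if (is.null(tab) || nrow(tab) == 0L) break
    live <- active[tab[, 1L]] & active[tab[, 3L]]
    tab <- tab[live, , drop = FALSE]
    if (nrow(tab) == 0L) break
    top <- which(tab[, 5L] == max(tab[, 5L]))
    merged_ids <- paste(ids[tab[top, 1L]], ids[tab[top, 3L]], sep = "+")
    pick <- tab[top[order(merged_ids)[1]], ]
    x <- oriented(pick[1L], pick[2L])
    y <- oriented(pick[3L], pick[4L])
    merged <- paste0(x, substring(y, pick[5L] + 1L))
    active[c(pick[1L], pick[3L])] <- FALSE
    n <- n + 1L
    ids <- c(ids, paste(ids[pick[1L]], ids[pick[3L]], sep = "+"))
    seqs <- c(seqs, merged)
    rcs <- c(rcs, revcomp(merged))
    active <- c(active, TRUE)
    add_prefixes(n)
    tab <- rbind(tab, overlaps_from(n, 1L), overlaps_from(n, 2L))
  }
  setNames(seqs[active], ids[active])
}

#' Filter assembled contigs for novelty and length
#'
#' A rescued contig is discarded if it has a local-alignment hit against any
#' input contig with e-value at or below the threshold (Karlin-Altschul on
#' the best +1/-3 local alignment, either strand), or if it is shorter than
#' the length floor.  Survivors keep assembler output order and get ids
#' `rescued_001`, `rescued_002`, ...
#'
#' @param rescued named character vector from [assemble_unmapped()].
#' @param input_contigs named character vector of the original contigs.
#' @param params a [rescue_params()].
#' @return list: `admitted` (named character vector) and `report` (data
#'   frame: `id`, `length`, `best_evalue`, `decision`).
#' @export
filter_novel <- function(rescued, input_contigs, params = rescue_params()) {
  n_db <- sum(nchar(input_contigs))
  report <- list()
  admitted <- character()
  n_adm <- 0L
  for (i in seq_along(rescued)) {
    seq <- rescued[[i]]
    len <- nchar(seq)
    best_e <- Inf
    if (len >= 15L) {   # shorter than any meaningful alignment
      for (ct in input_contigs) {
        aln <- nt_local_align(seq, ct)
        e <- ka_evalue(aln$score, len, n_db, NT_KA)
        if (e < best_e) best_e <- e
      }
    }
    hit <- best_e <= params$evalue_threshold
    long_enough <- len >= params$min_contig_len
    decision <- if (hit) "discarded_hit" else if (!long_enough)
      "discarded_short" else "admitted"
    if (decision == "admitted") {
      n_adm <- n_adm + 1L
      admitted[sprintf("rescued_%03d", n_adm)] <- seq
    }
    report[[i]] <- data.frame(
      id = if (decision == "admitted") sprintf("rescued_%03d", n_adm) else
        names(rescued)[i],
      length = len, best_evalue = best_e, decision = decision,
      stringsAsFactors = FALSE)
  }
  list(admitted = admitted,
       report = if (length(report)) do.call(rbind, report) else
         data.frame(id = character(), length = integer(),
                    best_evalue = numeric(), decision = character()))
}

#' Run the full rescue stage on one genome
#'
#' classify -> assemble -> filter: reads unmapped against the input contigs
#' are assembled, screened, and admitted contigs are appended after the
#' original contigs (which are never modified or reordered) with origin
#' `rescued`.
#'
#' @param ann a [genome_annotation()].
#' @param reads read table for this genome.
#' @param mapper a [mapper_params()].
#' @param params a [rescue_params()].
#' @return list: `annotation` (input plus admitted contigs), `report`
#'   (filter report), `n_unmapped`.
#' @export
rescue_genome <- function(ann, reads, mapper = mapper_params(),
                          params = rescue_params()) {
  cls <- classify_reads(reads, contig_seqs(ann), mapper)
  rescued <- assemble_unmapped(cls$unmapped, params)
  flt <- filter_novel(rescued, contig_seqs(ann), params)
  contigs <- ann$contigs
  if (length(flt$admitted)) {
    contigs <- rbind(contigs,
                     data.frame(id = names(flt$admitted),
                                seq = unname(flt$admitted),
                                origin = "rescued", stringsAsFactors = FALSE))
  }
  list(annotation = genome_annotation(ann$genome_id, contigs, ann$features,
                                      ann$repaired_genes),
       report = flt$report, n_unmapped = nrow(cls$unmapped))
}
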