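# Seed-and-extend read mapper: exact k-mer seeds located in an index of the
# target sequences (both strands), ungapped extension over the full read,
# acceptance when the total mismatch fraction stays under a cap.  Parameter
# semantics follow the pipeline defaults: seed length 22, 0 seed mismatches,
# insert bounds 0-500.  N never counts as a match.

#' Mapper parameters
#'
#' @param seed_len exact seed length (>= 11; default 22).
#' @param seed_mismatches mismatches tolerated inside the seed (0 or 1).
#' @param minins,maxins insert-size bounds for paired reads (recorded for
#'   pair-status reporting; mapped classification is per-read).
#' @param max_total_mismatch_frac mismatch fraction cap over the whole read
#'   during ungapped extension.
#' @return a `mapper_params` list.
#' @export
mapper_params <- function(seed_len = 22L, seed_mismatches = 0L,
                          minins = 0L, maxins = 500L,
                          max_total_mismatch_frac = 0.1) {
  stopifnot(seed_len >= 11L, seed_mismatches %in% c(0L, 1L),
            minins <= maxins, max_total_mismatch_frac >= 0,
            max_total_mismatch_frac < 1)
  structure(list(seed_len = as.integer(seed_len),
                 seed_mismatches = as.integer(seed_mismatches),
                 minins = as.integer(minins), maxins = as.integer(maxins),
                 max_total_mismatch_frac = max_total_mismatch_frac),
            class = "mapper_params")
}

# index of all k-mers of the targets; one entry stream per (target, strand),
# positions on the stranded string.  Returns env kmer -> row indices.
build_kmer_index <- function(targets, k) {
  stopifnot(!is.null(names(targets)))
  streams <- list()
  for (i in seq_along(targets)) {
    for (s in c("+", "-")) {
      seq <- if (s == "+") targets[[i]] else revcomp(targets[[i]])
      L <- nchar(seq)
      if (L < k) next
      streams[[length(streams) + 1L]] <- data.frame(
        target = i, strand = s, pos = seq_len(L - k + 1L) - 1L,
        kmer = substring(seq, seq_len(L - k + 1L), k:L),
        stringsAsFactors = FALSE)
    }
  }
  entries <- do.call(rbind, streams)
  env <- new.env(hash = TRUE, parent = emptyenv())
  idx_by_kmer <- split(seq_len(nrow(entries)), entries$kmer)
  list2env(idx_by_kmer, envir = env)
  list(env = env, entries = entries[c("target", "strand", "pos")],
       targets = targets, rc_targets = vapply(targets, revcomp, character(1)),
       k = k)
}

kmer_variants <- function(kmer) {
  chars <- strsplit(kmer, "", fixed = TRUE)[[1]]
  out <- character()
  for (i in seq_along(chars)) {
    for (b in setdiff(c("A", "C", "G", "T"), chars[i])) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# mismatch count between read and target substring at offset; positions
# hanging over the target edge and any N count as mismatches
extension_mismatches <- function(read_int, target_int, offset) {
  L <- length(read_int)
  idx <- offset + seq_len(L)
  inb <- idx >= 1L & idx <= length(target_int)
  mm <- sum(!inb)
  r <- read_int[inb]
  t <- target_int[idx[inb]]
  n_code <- utf8ToInt("N")
  mm + sum(r != t | r == n_code | t == n_code)
}

# best ungapped placements of reads on stranded target strings.
# Returns, per read, the best hit (fewest mismatches; ties: + strand first,
# then smallest position) or no row if nothing passes the cap.
place_reads <- function(reads, targets, params = mapper_params(),
                        index = NULL, first_hit_only = FALSE) {
  k <- params$seed_len
  if (is.null(index)) index <- build_kmer_index(targets, k)
  target_ints <- lapply(seq_along(index$targets), function(i) {
    list("+" = utf8ToInt(index$targets[[i]]),
         "-" = utf8ToInt(index$rc_targets[[i]]))
  })
  n_too_short <- 0L
  hits <- vector("list", nrow(reads))
  for (ri in seq_len(nrow(reads))) {
    rseq <- reads$seq[ri]
    L <- nchar(rseq)
    if (L < k) {
      n_too_short <- n_too_short + 1L
      next
    }
    read_int <- utf8ToInt(rseq)
    max_mm <- floor(params$max_total_mismatch_frac * L)
    offs <- unique(c(seq(1L, L - k + 1L, by = k), L - k + 1L))
    best <- NULL
    for (o in offs) {
      seed <- substr(rseq, o, o + k - 1L)
      seeds <- seed
      if (params$seed_mismatches == 1L) seeds <- c(seed, kmer_variants(seed))
      rows <- unlist(lapply(seeds, function(s)
        get0(s, envir = index$env, ifnotfound = NULL)), use.names = FALSE)
      if (is.null(rows) || length(rows) == 0L) next
      ent <- index$entries[rows, , drop = FALSE]
      for (j in seq_len(nrow(ent))) {
        offset <- ent$pos[j] - (o - 1L)   # 0-based read start on the strand
        tint <- target_ints[[ent$target[j]]][[ent$strand[j]]]
        mm <- extension_mismatches(read_int, tint, offset)
        if (mm > max_mm) next
        cand <- list(read = ri, target = ent$target[j],
                     strand = ent$strand[j], pos = offset, mismatches = mm)
        better <- is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches &&
             (cand$strand == "+" && best$strand == "-")) ||
          (mm == best$mismatches && cand$strand == best$strand &&
             cand$pos < best$pos)
        if (better) best <- cand
        if (first_hit_only && !is.null(best)) break
      }
      if (first_hit_only && !is.null(best)) break
    }
    if (!is.null(best)) hits[[ri]] <- as.data.frame(best)
  }
  placements <- if (any(!vapply(hits, is.null, logical(1)))) {
    do.call(rbind, hits)
  } else {
    data.frame(read = integer(), target = integer(), strand = character(),
               pos = integer(), mismatches = integer())
  }
  list(placements = placements, n_too_short = n_too_short, index = index)
}

#' Classify reads as mapped or unmapped against a set of contigs
#'
#' A read is mapped iff some exact seed of length `seed_len` occurs in a
#' contig (either strand) and ungapped extension over the full read stays
#' within the mismatch-fraction cap.  Paired reads are evaluated
#' independently.  Reads shorter than the seed are classified unmapped and
#' counted in a warning counter.
#'
#' @param reads read table (`id`, `seq`, ...).
#' @param contigs named character vector of contig sequences (non-empty).
#' @param params a [mapper_params()].
#' @return list: `mapped_ids` (character), `unmapped` (read table subset in
#'   input order), `n_too_short`.
#' @export
classify_reads <- function(reads, contigs, params = mapper_params()) {
  stopifnot(length(contigs) > 0L)
  res <- place_reads(reads, contigs, params, first_hit_only = TRUE)
  mapped <- rep(FALSE, nrow(reads))
  mapped[res$placements$read] <- TRUE
  list(mapped_ids = reads$id[mapped],
       unmapped = reads[!mapped, , drop = FALSE],
       n_too_short = res$n_too_short)
}
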