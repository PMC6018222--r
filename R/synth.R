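# Synthetic pan-genome, draft, frameshift and read generator with a
# ground-truth manifest.  This is the package's test bed: a shared core gene
# pool plus genome-specific accessory genes, draft fragmentation with gene
# loss, injected single-base indels that split one gene into two
# same-product CDSs, and error-bearing reads at a stated coverage.

STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# intergenic spacer: random sequence seeded with stop codons (forward and
# reverse-strand alphabets) at random offsets every ~6-18 bp, emulating
# the stop-dense composition of real intergenic DNA so that spacers do
# not harbor spurious long ORFs; sequences stay random, so spacers of
# different genomes share no long exact repeats
random_spacer <- function(n) {
  s <- strsplit(random_dna(n), "", fixed = TRUE)[[1]]
  stops6 <- c("TAA", "TAG", "TGA", "TTA", "CTA", "TCA")
  p <- 1L
  repeat {
    p <- p + sample(6:18, 1L)
    if (p + 2L > n) break
    s[p:(p + 2L)] <- strsplit(sample(stops6, 1L), "", fixed = TRUE)[[1]]
  }
  paste(s, collapse = "")
}

# coding gene: ATG start, stop-free body, one terminal stop codon
random_gene <- function(len_nt) {
  len_nt <- max(9L, (len_nt %/% 3L) * 3L)
  n_body <- len_nt %/% 3L - 2L
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1L, paste, collapse = "")
  codons <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(codons, n_body, replace = TRUE), collapse = ""),
         sample(STOP_CODONS, 1L))
}

# per-site substitutions at sub_rate, never creating an in-frame stop and
# never touching the start or terminal stop codon
mutate_gene <- function(seq, sub_rate) {
  if (sub_rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  cand <- which(stats::runif(n) < sub_rate)
  cand <- cand[cand > 3L & cand <= n - 3L]
  for (i in cand) {
    codon_start <- ((i - 1L) %/% 3L) * 3L + 1L
    for (b in sample(setdiff(c("A", "C", "G", "T"), chars[i]))) {
      codon <- chars[codon_start:(codon_start + 2L)]
      codon[i - codon_start + 1L] <- b
      if (!(paste(codon, collapse = "") %in% STOP_CODONS)) {
        chars[i] <- b
        break
      }
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a bacterial pan-genome with known family structure
#'
#' Builds an ancestral gene pool (core families present in every genome,
#' accessory families assigned to random genome subsets with
#' P(subset size k) proportional to 2^-k), derives per-genome gene copies by
#' per-site substitution that avoids premature stops, and concatenates the
#' genes with random intergenic spacers (50-500 bp) into one chromosome per
#' genome.
#'
#' @param n_genomes number of genomes (>= 2).
#' @param n_core number of core gene families (>= 0; if 0, accessory genes
#'   must make every genome non-empty).
#' @param accessory_rate each genome draws Poisson(accessory_rate *
#'   max(n_core, 1)) accessory genes.
#' @param gene_len_range gene length range in nt (rounded to codons).
#' @param sub_rate per-site substitution probability, in `[0, 0.2)`.
#' @param seed integer seed; the whole simulation is reproducible from it.
#' @param accessory_max_genomes cap on accessory subset size (1 forces every
#'   accessory family to be unique).
#' @return list with `genomes` (named list of [genome_annotation()]) and
#'   `truth` (a `truth_manifest`: `gene_catalog`, `placements`,
#'   `dropped_genes`, `injected_frameshifts`, `family_partition`).
#' @export
simulate_pangenome <- function(n_genomes, n_core, accessory_rate = 0.3,
                               gene_len_range = c(300L, 900L),
                               sub_rate = 0.02, seed = 1L,
                               accessory_max_genomes = n_genomes) {
  stopifnot(n_genomes >= 2L, n_core >= 0L, sub_rate >= 0, sub_rate < 0.2,
            accessory_rate >= 0, accessory_max_genomes >= 1L)
  withr::with_seed(seed, {
    genome_ids <- sprintf("G%02d", seq_len(n_genomes))
    fam_seq <- character()
    fam_prod <- character()
    fam_members <- list()  # family -> genome ids carrying it
    add_family <- function(genomes_in) {
      idx <- length(fam_seq) + 1L
      fid <- sprintf("F%04d", idx)
      len <- sample(seq(gene_len_range[1], gene_len_range[2]), 1L)
      fam_seq[[fid]] <<- random_gene(len)
      fam_prod[[fid]] <<- sprintf("putative protein PF%04d", idx)
      fam_members[[fid]] <<- genomes_in
      fid
    }
    for (i in seq_len(n_core)) add_family(genome_ids)
    quota <- stats::rpois(n_genomes, accessory_rate * max(n_core, 1L))
    names(quota) <- genome_ids
    while (sum(quota) > 0L) {
      eligible <- genome_ids[quota > 0L]
      kmax <- min(accessory_max_genomes, length(eligible))
      k <- sample.int(kmax, 1L, prob = 2^-(seq_len(kmax)))
      members <- eligible[sample.int(length(eligible), k)]
      add_family(members)
      quota[members] <- quota[members] - 1L
    }
    carried <- lapply(genome_ids, function(g) {
      names(fam_members)[vapply(fam_members, function(m) g %in% m,
                                logical(1))]
    })
    names(carried) <- genome_ids
    if (any(lengths(carried) == 0L)) {
      stop("parameters produce an empty genome", call. = FALSE)
    }
    genomes <- list()
    placements <- list()
    for (g in genome_ids) {
      fams <- sample(carried[[g]])  # shuffled gene order
      parts <- character(2L * length(fams) + 1L)
      feats <- vector("list", length(fams))
      pos <- 0L
      parts[1] <- random_spacer(sample(50:500, 1L))
      pos <- nchar(parts[1])
      for (i in seq_along(fams)) {
        fid <- fams[i]
        gseq <- mutate_gene(fam_seq[[fid]], sub_rate)
        strand <- sample(c("+", "-"), 1L)
        placed <- if (strand == "+") gseq else revcomp(gseq)
        gene_id <- sprintf("%s_%s", g, fid)
        feats[[i]] <- data.frame(
          contig_id = "chr", start = pos, end = pos + nchar(placed),
          strand = strand, product = fam_prod[[fid]], locus_id = gene_id,
          stringsAsFactors = FALSE)
        parts[2L * i] <- placed
        spacer <- random_spacer(sample(50:500, 1L))
        parts[2L * i + 1L] <- spacer
        pos <- pos + nchar(placed) + nchar(spacer)
      }
      chrom <- paste(parts, collapse = "")
      features <- do.call(rbind, feats)
      genomes[[g]] <- genome_annotation(g, setNames(chrom, "chr"), features)
      placements[[g]] <- data.frame(
        genome_id = g, gene_id = features$locus_id,
        family_id = sub("^.*_", "", features$locus_id),
        contig_id = features$contig_id, start = features$start,
        end = features$end, strand = features$strand,
        stringsAsFactors = FALSE)
    }
    n_mem <- lengths(fam_members)
    category <- ifelse(n_mem == n_genomes, "core",
                       ifelse(n_mem == 1L, "unique", "accessory"))
    truth <- structure(list(
      genomes = genome_ids,
      gene_catalog = data.frame(
        gene_id = unlist(lapply(genome_ids, function(g)
          sprintf("%s_%s", g, carried[[g]]))),
        family_id = unlist(carried),
        protein_len = unlist(lapply(genome_ids, function(g)
          nchar(fam_seq[carried[[g]]]) %/% 3L - 1L)),
        row.names = NULL, stringsAsFactors = FALSE),
      family_products = setNames(unlist(fam_prod), names(fam_seq)),
      family_seqs = setNames(unlist(fam_seq), names(fam_seq)),
      placements = do.call(rbind, c(placements, list(make.row.names = FALSE))),
      dropped_genes = data.frame(genome_id = character(),
                                 gene_id = character(),
                                 stringsAsFactors = FALSE),
      injected_frameshifts = data.frame(genome_id = character(),
                                        gene_id = character(),
                                        pos = integer(), kind = character(),
                                        stringsAsFactors = FALSE),
      family_partition = data.frame(family_id = names(fam_members),
                                    category = unname(category),
                                    stringsAsFactors = FALSE)),
      class = "truth_manifest")
    list(genomes = genomes, truth = truth)
  })
}

#' Fragment a simulated genome into a draft
#'
#' Cuts the chromosome at random intergenic positions, optionally drops
#' whole contigs (recording their genes as lost), discards fragments below
#' a length floor, and re-maps features to contig coordinates.
#'
#' @param genome a [genome_annotation()] (single contig).
#' @param n_breaks number of random intergenic cut points.
#' @param drop_prob probability that each resulting contig is dropped.
#' @param min_fragment fragments shorter than this are discarded (recorded).
#' @param seed integer seed.
#' @param force_drop indices of fragments to drop regardless of `drop_prob`.
#' @return list with `annotation` (the draft) and `delta` (data frame of
#'   dropped genes: `genome_id`, `gene_id`, plus `discarded_fragments`).
#' @export
make_draft <- function(genome, n_breaks, drop_prob, min_fragment = 1L,
                       seed = 1L, force_drop = integer()) {
  stopifnot(n_breaks >= 0L, drop_prob >= 0, drop_prob <= 1,
            nrow(genome$contigs) == 1L)
  withr::with_seed(seed, {
    chrom <- genome$contigs$seq[1]
    cid <- genome$contigs$id[1]
    L <- nchar(chrom)
    fx <- genome$features
    in_gene <- rep(FALSE, L)
    for (i in seq_len(nrow(fx))) {
      in_gene[(fx$start[i] + 1L):fx$end[i]] <- TRUE
    }
    allowed <- which(!in_gene)           # cut before this 1-based position
    allowed <- setdiff(allowed, 1L)
    cuts <- sort(allowed[sample.int(length(allowed),
                                    min(n_breaks, length(allowed)))])
    bounds <- c(0L, cuts - 1L, L)        # 0-based fragment boundaries
    starts <- bounds[-length(bounds)]
    ends <- bounds[-1]
    keep_frag <- (ends - starts) >= min_fragment
    dropped <- logical(length(starts))
    dropped[force_drop] <- TRUE
    rnd <- stats::runif(length(starts))
    dropped <- dropped | rnd < drop_prob
    contigs <- list()
    feats <- list()
    lost <- character()
    discarded <- data.frame(fragment = integer(), length = integer())
    for (i in seq_along(starts)) {
      sub_fx <- fx[fx$start >= starts[i] & fx$end <= ends[i], , drop = FALSE]
      if (!keep_frag[i]) {
        discarded <- rbind(discarded,
                           data.frame(fragment = i,
                                      length = ends[i] - starts[i]))
        lost <- c(lost, sub_fx$locus_id)
        next
      }
      if (dropped[i]) {
        lost <- c(lost, sub_fx$locus_id)
        next
      }
      new_id <- sprintf("%s_c%03d", cid, i)
      contigs[[new_id]] <- substring(chrom, starts[i] + 1L, ends[i])
      if (nrow(sub_fx)) {
        sub_fx$contig_id <- new_id
        sub_fx$start <- sub_fx$start - starts[i]
        sub_fx$end <- sub_fx$end - starts[i]
        feats[[new_id]] <- sub_fx
      }
    }
    if (length(contigs) == 0L) stop("all contigs dropped", call. = FALSE)
    ann <- genome_annotation(
      genome$genome_id, unlist(contigs),
      if (length(feats)) do.call(rbind, c(feats, list(make.row.names = FALSE)))
      else empty_features())
    delta <- data.frame(genome_id = rep(genome$genome_id, length(lost)),
                        gene_id = lost, stringsAsFactors = FALSE)
    list(annotation = ann, delta = delta, discarded_fragments = discarded)
  })
}

# apply a single-base indel at a forward-strand contig coordinate, shifting
# feature coordinates; `pos` is 0-based (ins: before pos; del: the base at pos)
apply_contig_indel <- function(ann, contig_id, pos, kind, base = "A") {
  ci <- match(contig_id, ann$contigs$id)
  seq <- ann$contigs$seq[ci]
  if (kind == "ins") {
    seq <- paste0(substring(seq, 1L, pos), base, substring(seq, pos + 1L))
    delta <- 1L
  } else {
    seq <- paste0(substring(seq, 1L, pos), substring(seq, pos + 2L))
    delta <- -1L
  }
  ann$contigs$seq[ci] <- seq
  sel <- ann$features$contig_id == contig_id & ann$features$start >= pos
  ann$features$start[sel] <- ann$features$start[sel] + delta
  sel <- ann$features$contig_id == contig_id & ann$features$end > pos
  ann$features$end[sel] <- ann$features$end[sel] + delta
  ann
}

#' Inject an assembly-like frameshift into a gene
#'
#' Inserts or deletes one base strictly inside the gene body and replaces
#' the gene's CDS by the two consecutive same-product CDSs a gene caller
#' would emit: the first ends at the first in-frame stop introduced by the
#' shift, the second starts at the next start codon in the shifted frame
#' (or, flagged, at the first codon after the stop when no start exists)
#' and runs to the original gene end.  Applying the inverse indel at the
#' same position restores the sequence and the single CDS.
#'
#' @param genome a [genome_annotation()].
#' @param gene_id locus id of the target gene (or of a previously split
#'   gene, identified by its `_1`/`_2` members).
#' @param pos 0-based offset strictly inside the gene body, in gene
#'   orientation.
#' @param kind `"ins"` or `"del"`.
#' @param seed optional seed for the inserted base.
#' @return the modified [genome_annotation()].
#' @export
inject_frameshift <- function(genome, gene_id, pos, kind = c("del", "ins"),
                              seed = NULL) {
  kind <- match.arg(kind)
  fx <- genome$features
  idx <- which(fx$locus_id == gene_id)
  split_ids <- paste0(gene_id, c("_1", "_2"))
  was_split <- length(idx) == 0L && all(split_ids %in% fx$locus_id)
  if (was_split) idx <- which(fx$locus_id %in% split_ids)
  if (length(idx) == 0L) stop("no such gene: ", gene_id, call. = FALSE)
  gstart <- min(fx$start[idx])
  gend <- max(fx$end[idx])
  strand <- fx$strand[idx[1]]
  contig_id <- fx$contig_id[idx[1]]
  product <- fx$product[idx[1]]
  glen <- gend - gstart
  stopifnot(pos > 0L, pos < glen)
  base <- if (is.null(seed)) "A" else
    withr::with_seed(seed, sample(c("A", "C", "G", "T"), 1L))
  # gene-orientation offset -> forward contig coordinate of the edit
  cpos <- if (strand == "+") gstart + pos else {
    if (kind == "ins") gstart + (glen - pos) else gstart + (glen - pos - 1L)
  }
  if (strand == "-" && kind == "ins") base <- revcomp(base)
  other <- setdiff(seq_len(nrow(fx)), idx)
  overlap <- fx$start[other] < gend & fx$end[other] > gstart &
    fx$contig_id[other] == contig_id
  if (any(overlap)) stop("target gene overlaps another feature",
                         call. = FALSE)
  genome <- apply_contig_indel(genome, contig_id, cpos, kind, base)
  fx <- genome$features
  idx <- which(fx$locus_id %in% c(gene_id, split_ids))
  gstart <- min(fx$start[idx])
  gend <- max(fx$end[idx])
  g2 <- substring(genome$contigs$seq[match(contig_id, genome$contigs$id)],
                  gstart + 1L, gend)
  if (strand == "-") g2 <- revcomp(g2)
  L2 <- nchar(g2)
  # first in-frame (frame 0) stop at or after the edited codon
  scan_from <- (pos %/% 3L)
  codon_starts <- seq(scan_from * 3L, L2 - 3L, by = 3L)
  codons <- substring(g2, codon_starts + 1L, codon_starts + 3L)
  stop_hit <- codon_starts[codons %in% STOP_CODONS]
  clean_now <- L2 %% 3L == 0L &&
    (length(stop_hit) == 0L || stop_hit[1] == L2 - 3L)
  map_back <- function(a, b) {
    # gene-orientation [a, b) -> forward-strand contig interval
    if (strand == "+") c(gstart + a, gstart + b)
    else c(gstart + (L2 - b), gstart + (L2 - a))
  }
  mk_feat <- function(a, b, locus) {
    iv <- map_back(a, b)
    data.frame(contig_id = contig_id, start = iv[1], end = iv[2],
               strand = strand, product = product, locus_id = locus,
               stringsAsFactors = FALSE)
  }
  if (clean_now) {
    if (!was_split) stop("indel does not disrupt the reading frame",
                         call. = FALSE)
    new_fx <- mk_feat(0L, L2, gene_id)
  } else {
    if (length(stop_hit) == 0L) {
      stop("no in-frame stop downstream of the indel: gene too short to split",
           call. = FALSE)
    }
    e1 <- stop_hit[1] + 3L
    f2 <- (L2 - 3L) %% 3L  # frame holding the original terminal stop
    s2_candidates <- seq(e1 + ((f2 - e1) %% 3L), L2 - 3L, by = 3L)
    starts_found <- s2_candidates[
      substring(g2, s2_candidates + 1L, s2_candidates + 3L) %in% START_CODONS]
    s2 <- if (length(starts_found)) starts_found[1] else s2_candidates[1]
    if (length(s2_candidates) == 0L || s2 >= L2 - 2L) {
      stop("no start position for the downstream fragment: gene too short",
           call. = FALSE)
    }
    new_fx <- rbind(mk_feat(0L, e1, paste0(gene_id, "_1")),
                    mk_feat(s2, L2, paste0(gene_id, "_2")))
  }
  keep <- genome$features[!(genome$features$locus_id %in%
                              c(gene_id, split_ids)), , drop = FALSE]
  genome_annotation(genome$genome_id, genome$contigs,
                    rbind(keep, new_fx), genome$repaired_genes)
}

#' Inject frameshifts into several genes of a genome
#'
#' Convenience driver: picks `n` distinct eligible genes (annotated product,
#' long enough to split), injects a random single-base indel at a random
#' interior position into each, and records the injections.  Genes where the
#' split is impossible (no downstream stop or start) are skipped and another
#' gene is tried.
#'
#' @param genome a [genome_annotation()].
#' @param n number of genes to disrupt.
#' @param seed integer seed.
#' @return list with `genome` (modified) and `injections` (data frame:
#'   `genome_id`, `gene_id`, `pos`, `kind`).
#' @export
inject_random_frameshifts <- function(genome, n, seed = 1L,
                                      min_gene_len = 500L) {
  withr::with_seed(seed, {
    fx <- genome$features
    eligible <- fx$locus_id[fx$product != "hypothetical protein" &
                              (fx$end - fx$start) >= min_gene_len]
    eligible <- sample(eligible)
    inj <- list()
    for (gid in eligible) {
      if (length(inj) >= n) break
      f <- fx[fx$locus_id == gid, ]
      glen <- f$end - f$start
      # keep both resulting fragments long enough for a gene caller to see
      pos <- sample(seq(150L, glen - 350L), 1L)
      kind <- sample(c("ins", "del"), 1L)
      res <- tryCatch(inject_frameshift(genome, gid, pos, kind),
                      error = function(e) NULL)
      if (is.null(res)) next
      genome <- res
      inj[[gid]] <- data.frame(genome_id = genome$genome_id, gene_id = gid,
                               pos = pos, kind = kind,
                               stringsAsFactors = FALSE)
    }
    if (length(inj) < n) {
      warning("only ", length(inj), " of ", n, " frameshifts injected")
    }
    list(genome = genome,
         injections = do.call(rbind, c(unname(inj),
                                       list(make.row.names = FALSE))))
  })
}

add_read_errors <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(chars)) < error_rate)
    for (i in hit) {
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate sequencing reads from a genome
#'
#' Uniform start positions, per-base substitution errors, optional FR
#' paired-end mode with a truncated-normal insert size.  The expected read
#' count is `coverage * genome_length / read_len` (counting both mates).
#'
#' @param genome a [genome_annotation()].
#' @param read_len read length (>= 20).
#' @param coverage target fold coverage (> 0).
#' @param error_rate per-base substitution probability.
#' @param paired emit FR mate pairs.
#' @param insert_mean,insert_sd insert-size distribution (paired mode);
#'   `insert_mean` must be >= `read_len`.
#' @param seed integer seed.
#' @return read table: `id`, `seq`, `qual`, `mate`, `orientation`.
#' @export
simulate_reads <- function(genome, read_len = 100L, coverage = 30,
                           error_rate = 0, paired = FALSE,
                           insert_mean = 300, insert_sd = 30, seed = 1L) {
  stopifnot(read_len >= 20L, coverage > 0)
  if (paired && insert_mean < read_len) {
    stop("insert_mean must be >= read_len in paired mode", call. = FALSE)
  }
  withr::with_seed(seed, {
    out <- list()
    for (ci in seq_len(nrow(genome$contigs))) {
      cid <- genome$contigs$id[ci]
      seq <- genome$contigs$seq[ci]
      L <- nchar(seq)
      if (L < read_len) next
      if (!paired) {
        n <- round(coverage * L / read_len)
        if (n == 0L) next
        starts <- sample.int(L - read_len + 1L, n, replace = TRUE)
        fwd <- stats::runif(n) < 0.5
        reads <- substring(seq, starts, starts + read_len - 1L)
        reads[!fwd] <- revcomp(reads[!fwd])
        reads <- add_read_errors(reads, error_rate)
        out[[cid]] <- data.frame(
          id = sprintf("%s_%s_r%06d", genome$genome_id, cid,
                       seq_along(reads)),
          seq = reads, qual = strrep("I", read_len), mate = "unpaired",
          orientation = ifelse(fwd, "forward", "reverse"),
          stringsAsFactors = FALSE)
      } else {
        n_pairs <- round(coverage * L / (2 * read_len))
        if (n_pairs == 0L) next
        ins <- pmax(read_len,
                    pmin(L, round(stats::rnorm(n_pairs, insert_mean,
                                               insert_sd))))
        starts <- vapply(ins, function(s)
          sample.int(L - s + 1L, 1L), integer(1))
        m1 <- substring(seq, starts, pmin(starts + read_len - 1L,
                                          starts + ins - 1L))
        m2 <- revcomp(substring(seq, pmax(starts, starts + ins - read_len),
                                starts + ins - 1L))
        m1 <- add_read_errors(m1, error_rate)
        m2 <- add_read_errors(m2, error_rate)
        ids <- sprintf("%s_%s_p%06d", genome$genome_id, cid,
                       seq_len(n_pairs))
        out[[cid]] <- rbind(
          data.frame(id = paste0(ids, "/1"), seq = m1,
                     qual = strrep("I", nchar(m1)), mate = "mate1",
                     orientation = "forward", stringsAsFactors = FALSE),
          data.frame(id = paste0(ids, "/2"), seq = m2,
                     qual = strrep("I", nchar(m2)), mate = "mate2",
                     orientation = "reverse", stringsAsFactors = FALSE))
      }
    }
    if (length(out) == 0L) {
      stop("no contig long enough to sample reads from", call. = FALSE)
    }
    do.call(rbind, c(unname(out), list(make.row.names = FALSE)))
  })
}

#' Write a truth manifest as TSV files
#'
#' @param truth a `truth_manifest`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_truth_manifest <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(truth$gene_catalog, file.path(dir, "gene_catalog.tsv"))
  write_tsv_file(truth$placements, file.path(dir, "placements.tsv"))
  write_tsv_file(truth$dropped_genes, file.path(dir, "dropped_genes.tsv"))
  write_tsv_file(truth$injected_frameshifts,
                 file.path(dir, "injected_frameshifts.tsv"))
  write_tsv_file(truth$family_partition,
                 file.path(dir, "family_partition.tsv"))
  invisible(dir)
}
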