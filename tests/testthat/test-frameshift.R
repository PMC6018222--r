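mk_feats <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(contig_id = "c1", start = r[[1]], end = r[[2]],
               strand = r[[3]], product = r[[4]], locus_id = r[[5]],
               stringsAsFactors = FALSE)))
}

ann_with <- function(feats, len = 3000L) {
  genome_annotation("G", c(c1 = random_dna_str(len, 7L)), feats)
}

test_that("adjacent same-product same-strand CDSs form one candidate", {
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "dnaA", "a"),
                           list(440L, 700L, "+", "dnaA", "b")))
  det <- detect_frameshift_candidates(ann)
  expect_length(det$candidates, 1L)
  expect_equal(nrow(det$candidates[[1]]$members), 2L)
  expect_equal(nrow(det$clean), 0L)
})

test_that("strand, gap, product normalization and exclusions gate runs", {
  # strand differs: no candidate
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "dnaA", "a"),
                           list(440L, 700L, "-", "dnaA", "b")))
  expect_length(detect_frameshift_candidates(ann)$candidates, 0L)
  # gap too large: no candidate
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "dnaA", "a"),
                           list(900L, 1200L, "+", "dnaA", "b")))
  expect_length(detect_frameshift_candidates(ann)$candidates, 0L)
  # product comparison is case-folded and whitespace-collapsed
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "DnaA  protein", "a"),
                           list(440L, 700L, "+", "dnaa protein", "b")))
  expect_length(detect_frameshift_candidates(ann)$candidates, 1L)
  # excluded product never forms a candidate
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "hypothetical protein",
                                "a"),
                           list(440L, 700L, "+", "hypothetical protein",
                                "b")))
  det <- detect_frameshift_candidates(ann)
  expect_length(det$candidates, 0L)
  expect_equal(nrow(det$clean), 2L)
  # an intervening excluded CDS does not break a same-product run
  ann <- ann_with(mk_feats(list(100L, 400L, "+", "dnaA", "a"),
                           list(410L, 530L, "-", "hypothetical protein",
                                "x"),
                           list(440L, 700L, "+", "dnaA", "b")))
  det <- detect_frameshift_candidates(ann)
  expect_length(det$candidates, 1L)
  expect_equal(nrow(det$clean), 1L)
})

test_that("detection partitions features between candidates and clean set", {
  sim <- simulate_pangenome(2L, 12L, accessory_rate = 0,
                            gene_len_range = c(600L, 900L), seed = 33L)
  inj <- inject_random_frameshifts(sim$genomes[[1]], 4L, seed = 34L)
  det <- detect_frameshift_candidates(inj$genome)
  n_members <- sum(vapply(det$candidates, function(x) nrow(x$members),
                          integer(1)))
  expect_equal(nrow(det$clean) + n_members, nrow(inj$genome$features))
  expect_length(det$candidates, 4L)
})

test_that("select_reference picks the homolog and breaks ties smaller-id", {
  sim <- simulate_pangenome(2L, 8L, accessory_rate = 0,
                            gene_len_range = c(600L, 900L), seed = 43L)
  refs <- truth_ref_dbs(sim)
  inj <- inject_random_frameshifts(sim$genomes[[1]], 2L, seed = 44L)
  det <- detect_frameshift_candidates(inj$genome)
  for (cand in det$candidates) {
    fam <- sub("^.*_(F[0-9]+)_.*$", "\\1",
               cand$members$locus_id[1])
    expect_identical(select_reference(cand, refs$nt), fam)
  }
  # no homolog in the database: unrepairable
  decoy <- c("Z001 decoy" = random_dna_str(600L, 45L))
  expect_true(is.na(select_reference(det$candidates[[1]], decoy)))
  # duplicate references tie-break to the lexicographically smaller id
  cand <- det$candidates[[1]]
  fam <- sub("^.*_(F[0-9]+)_.*$", "\\1", cand$members$locus_id[1])
  seq <- sim$truth$family_seqs[[fam]]
  db <- stats::setNames(c(seq, seq), c("B_ref same", "A_ref same"))
  expect_identical(select_reference(cand, db), "A_ref")
})

test_that("pileup consensus reproduces the reference under full coverage", {
  ref <- random_dna_str(600L, 53L)
  reads <- tiling_reads(ref, read_len = 100L, step = 20L)
  pc <- pileup_consensus(reads, ref)
  expect_identical(pc$consensus, ref)
  expect_equal(pc$completeness, 1.0)
  # reads covering only the first half
  half <- tiling_reads(substring(ref, 1L, 300L), read_len = 100L,
                       step = 20L)
  pc2 <- pileup_consensus(half, ref)
  expect_lt(abs(pc2$completeness - 0.5), 100 / 600)
  expect_identical(unique(strsplit(substring(pc2$consensus, 320L, 600L),
                                   "")[[1]]), "N")
  # no reads at all
  pc3 <- pileup_consensus(reads_from_seqs(character()), ref)
  expect_equal(pc3$completeness, 0)
  expect_identical(pc3$consensus, strrep("N", 600L))
})

test_that("majority voting corrects read errors and ties go to reference", {
  ref <- random_dna_str(400L, 57L)
  clean <- tiling_reads(ref, read_len = 100L, step = 10L)
  # corrupt one read at a known reference position
  pos <- 205L
  covering <- which(vapply(seq_len(nrow(clean)), function(i) {
    s <- regexpr(clean$seq[i], ref, fixed = TRUE)
    s <= pos && pos < s + 100L
  }, logical(1)))
  i <- covering[1]
  off <- pos - as.integer(regexpr(clean$seq[i], ref, fixed = TRUE)) + 1L
  b <- substr(clean$seq[i], off, off)
  substr(clean$seq[i], off, off) <- setdiff(c("A", "C", "G", "T"), b)[1]
  pc <- pileup_consensus(clean, ref)
  expect_identical(pc$consensus, ref)
})

test_that("repair replaces members, respects the completeness gate, and
           reduces the remaining-candidate count", {
  sim <- simulate_pangenome(2L, 12L, accessory_rate = 0,
                            gene_len_range = c(600L, 900L), seed = 63L)
  g <- sim$genomes[[1]]
  refs <- truth_ref_dbs(sim)
  inj <- inject_random_frameshifts(g, 4L, seed = 64L)
  det <- detect_frameshift_candidates(inj$genome)
  reads <- simulate_reads(g, coverage = 30, error_rate = 0, seed = 65L)
  rep <- repair_genome(inj$genome, det$candidates, reads, refs$nt)
  expect_true(all(rep$repairs$admitted))
  expect_equal(rep$n_candidates_before, length(det$candidates))
  expect_equal(rep$n_candidates_after, 0L)
  expect_lt(rep$n_candidates_after, rep$n_candidates_before)
  # each admitted repair decreases the CDS count by (members - 1)
  dec <- sum(rep$repairs$n_members[rep$repairs$admitted] - 1L)
  expect_equal(nrow(rep$annotation$features),
               nrow(inj$genome$features) - dec)
  # repaired gene sequences are consensus copies, multiples of 3
  expect_true(all(nchar(rep$annotation$repaired_genes) %% 3L == 0L))
  # an empty reference database leaves everything unrepairable
  rep0 <- repair_genome(inj$genome, det$candidates, reads, character())
  expect_equal(rep0$n_candidates_after, rep0$n_candidates_before)
  expect_identical(rep0$annotation$features, inj$genome$features)
})

test_that("the completeness threshold gates admission strictly", {
  ref <- random_dna_str(600L, 67L)
  # reads covering ~60% of the reference: below the default 0.70
  reads <- tiling_reads(substring(ref, 1L, 360L), read_len = 100L,
                        step = 20L)
  pc <- pileup_consensus(reads, ref)
  expect_lt(pc$completeness, 0.70)
  expect_gt(pc$completeness, 0.5)
  # the same coverage passes a 0.5 threshold: admissions are monotone in
  # the threshold
  admitted_at <- function(thr) pc$completeness >= thr
  expect_false(admitted_at(0.70))
  expect_true(admitted_at(0.50))
})
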