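---
title: "Methods: draft-genome gene rescue, frameshift repair and pan-genome analysis"
author: "panrescue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: draft-genome gene rescue, frameshift repair and pan-genome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Most bacterial genomes in public databases are unfinished: a draft is a
set of contigs with gaps, and genes that fall into a gap, or are split by
a spurious single-base indel from the assembly, are missing or broken in
the annotation.  When such drafts enter a pan-genome analysis the gene
repertoire is under-represented and the core/accessory partition is
biased.  `panrescue` addresses both failure modes before the comparative
step:

1. **Gene-content rescue.** Sequencing reads that fail to map back to the
   draft's contigs are assembled de novo; assembled contigs that are novel
   with respect to the draft and at least 200 bp long are appended to it.
2. **Frameshift repair.** Assembly-induced indels split one gene into two
   consecutive CDSs carrying the same product annotation.  Such runs are
   detected, a reference gene is chosen by protein similarity, the raw
   reads are piled up against it, and the consensus replaces the broken
   pair when at least 70% of the reference is covered.

The repaired gene sets then feed a native pan-genome analysis: all-vs-all
protein similarity, thresholded gene-family clustering, the
core/accessory/unique partition, permutation pan/core curves with a
Heaps-law openness fit, and a UPGMA tree on gene presence/absence.

## Stage models and parameters

### Read mapping (rescue classification)

The mapper is seed-and-extend: a read maps iff one of its exact seeds of
length `seed_len` (default 22 nt, non-overlapping windows plus the final
window) occurs in a contig on either strand and ungapped extension over
the whole read stays within `max_total_mismatch_frac` (default 0.10)
mismatches.  Positions hanging over a contig edge and every `N` count as
mismatches — `N` never counts as a match anywhere in the package.
`seed_mismatches` (0 or 1, default 0) optionally adds all one-substitution
seed variants.  `minins`/`maxins` (0/500) are recorded insert bounds for
paired libraries; mapped classification is per-read.  Against an
exhaustive ungapped-alignment oracle at the same mismatch cap the
classifier agrees on ≥ 95% of reads; the residual disagreement is reads
placeable only with an overhang, which the oracle cannot represent.

### Greedy assembly of unmapped reads

Exact duplicates and reads contained in another read (either orientation)
are absorbed first.  The assembler then repeatedly merges the pair of
sequences with the longest exact suffix–prefix overlap of at least
`min_overlap` (default 30 nt), considering both strands, until no merge
remains.  Candidate overlaps are found through a hash of sequence
prefixes, so only exact-match positions are verified.  Ties break by
longest overlap, then by the lexicographically smallest merged id, making
the output a deterministic function of the input order.  Overlaps must be
exact (`min_assembly_identity = 1`): correctness is auditable, and the
error models under which the package is validated use error-free reads
for assembly assertions.

### Admission of rescued contigs

A rescued contig is discarded if it aligns to any input contig with
e-value ≤ 1e-5, or if it is shorter than 200 bp; the two rules are applied
as a conjunction (the order is immaterial).  The e-value is
Karlin–Altschul, `E = K·m·n·exp(−λS)`, on the best local alignment score
under match +1 / mismatch −3, with ungapped nucleotide constants λ = 1.33,
K = 0.621, query length m and total input-assembly length n.  Admitted
contigs are appended after the originals, which are never modified or
reordered.

### Annotation

A local intrinsic annotator stands in for a remote annotation service.
`find_orfs` reports every maximal ORF on both strands: from the first
in-frame start codon (ATG/GTG/TTG) after a stop or the contig edge to the
next in-frame stop inclusive, at least `min_orf_nt` (120) long, one ORF
per (frame, stop).  Products come from the best Smith–Waterman hit
(BLOSUM62, gap open 11 / extend 1) against a user-supplied reference
protein set, gated at identity ≥ 0.5 and query coverage ≥ 0.7; ties break
by score then lexicographic reference id; misses become
`"hypothetical protein"`.

Three refinements make the caller usable on fragmented and broken genes:

* **Start refinement.** A maximal ORF may begin at a spurious upstream
  start codon.  When a reference hit exists, the start moves to the
  in-frame start codon whose protein length is closest to the
  reference's (ties: most upstream).
* **Coverage re-anchoring.** The halves of a frameshifted gene translate
  into proteins with unaligned junk at one end, which can push query
  coverage below the gate.  If the plain gate fails, coverage is
  recomputed over the query re-anchored at the in-frame start codon
  nearest the alignment's query start.
* **Shadow suppression.** A hypothetical ORF overlapping a
  product-assigned CDS by more than half of its own length is a shadow of
  the real gene (reverse strand or alternate frame) and is dropped, as
  standard callers do.

On a complete synthetic genome with the truth proteins as reference, the
annotator recovers ≥ 95% of true gene intervals exactly and assigns the
true product to every recovered gene (the test suite asserts this).

### Frameshift detection and repair

Candidates are maximal runs of ≥ 2 CDSs on one contig with equal
normalized product (case-folded, whitespace-collapsed), the same strand,
and inter-feature gap ≤ 300 bp.  Products in the excluded set (default
`"hypothetical protein"`) never form candidates, and they are also
ignored when judging adjacency: the junction between the two halves of a
broken gene is frame-garbage that often harbors spurious unannotated
ORFs, and a generic product carries no frameshift signal either way.
Every feature still lands in exactly one candidate or in the clean set.

For each candidate, member translations are searched against the
translated reference nucleotide database; the reference with the best
cumulative bit score among those with a member hit at e ≤ 1e-5 is chosen
(ties: smaller id).  The raw reads are then piled up on the reference
with the rescue mapper: each position takes the majority base among
covering reads, ties resolve to the reference base, and positions below
`min_depth` (1) emit `N`.  Completeness is the fraction of reference
positions covered at `min_depth`; a repair is admitted iff completeness ≥
0.70.  Admitted candidates have their members replaced by a single CDS
whose gene sequence is the consensus, carried as a supplementary gene
record — contig sequences are never edited, because downstream
comparative analysis consumes gene sequences, and the package takes no
position on re-coordinating a spliced contig.  Complete genomes get a
per-genome `repair` switch (off by default) rather than a guess about
whether finished assemblies should be touched.

### Comparative analysis

Every gene pair sharing at least two amino-acid 5-mers is aligned by
Smith–Waterman (BLOSUM62, 11/1); homologous pairs at the clustering
identity floor share dozens of 5-mers, so the prefilter does not lose
thresholded edges (asserted against a no-prefilter oracle).  An edge is
kept when e-value ≤ 1e-5, identity ≥ 0.7 over alignment columns, and
coverage ≥ 0.8 on **both** sequences (the stricter reading of a single
"coverage" threshold; a one-sided gate is available).  Families are the
connected components of the kept graph — deterministic and auditable —
with Markov clustering (expansion 2, inflation 1.5) offered as an
alternative that can only refine, never merge, components.  Family ids
sort by smallest member key, so results are invariant to genome input
order.  A family is core when it spans all genomes (possibly with several
paralogs from one genome), unique when it spans exactly one, accessory
otherwise.

Pan/core curves use seeded random genome permutations: at step N, pan is
the number of families seen among the first N genomes, core the number
present in all of them, and the new-gene count the number first observed
at N.  Heaps' law is fitted to the decay of new genes,
`n(N) = κ·N^(−α)`, by Levenberg–Marquardt least squares on the mean or
median aggregate over permutations at N ≥ 2, initialized from a log-log
regression (which is also the fallback when the nonlinear step is
degenerate — with three genomes there are only two fitting points, where
the log-log solution is already exact).  The pan-genome is called open
iff α ≤ 1, boundary inclusive.  The genome distance for the UPGMA tree is
Jaccard on family presence sets, agglomerated by arithmetic-mean linkage
with ultrametric branch lengths (node height = half the merge distance).

### Similarity percentages

The accuracy metric for a draft against its complete counterpart counts
draft genes whose amino-acid sequence exactly equals a family mate from
the complete genome (100% similarity means exact; the amino-acid level is
the deliberate reading of an ambiguous "similarity"), tallied separately
for core and accessory families, as a percentage of total products found,
printed to two decimals with round-half-up.

## The synthetic test bed

`simulate_pangenome` draws an ancestral gene pool: core families present
everywhere and accessory families assigned to random genome subsets with
P(subset size k) ∝ 2^−k, giving a mixture of shared-accessory and unique
families.  Genes are stop-free codon sequences (ATG … stop) of 300–900 nt;
per-genome copies mutate at a per-site rate (default 0.02) that never
creates an in-frame stop and never touches the start or terminal stop.
Genes are concatenated in shuffled order and random strands with
intergenic spacers of 50–500 bp into one chromosome per genome
(single-replicon by design; the method is replicon-agnostic).

Three generator choices deserve emphasis, because they define what
passing tests do and do not show:

* **Spacers are stop-dense.** Random DNA is seeded with stop codons (both
  strand alphabets) every ~6–18 bp, emulating the composition of real
  intergenic DNA.  Fully random spacers harbor many spurious ≥ 120 nt
  ORFs, which real annotators would not call; a fixed stop motif is not
  used because a shared repeat across genomes would make every rescued
  contig spuriously hit the input assembly.
* **Draft breaks coincide with coverage gaps.** `make_draft` cuts at
  intergenic positions, and the project generator samples reads per
  fragment, so no read spans a junction.  This mirrors real draft/read
  pairs, where contigs end precisely where read support ends; reads
  sampled from an unbroken chromosome would extend every rescued contig
  into its neighbors and (correctly) get it discarded as already
  represented.
* **Injected frameshifts are annotator-visible.** `inject_frameshift`
  applies one indel strictly inside a gene and replaces its CDS with the
  two features a caller would emit: up to the first in-frame stop after
  the indel, and from the next start codon in the shifted frame (flagged
  fallback: the first codon after the stop) to the original gene end.
  The random-injection driver targets genes ≥ 500 nt at positions
  150..len−350 so both fragments clear the 120 nt calling floor — a
  frameshift invisible to every annotator is outside the method's scope.

What the generator does **not** emulate: indel sequencing errors,
realistic quality strings, repeats and rearrangements, plasmids,
GC-content structure, and annotator idiosyncrasies of any specific
service.  Passing tests therefore demonstrate the pipeline's contracts
under clean, known-truth conditions, not performance on real sequencing
artifacts.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally; EMBL/GFF3 conversion
  happens only at the format boundary.  `join(...)` EMBL locations
  flatten to their outer span with a warning.
* IUPAC ambiguity codes collapse to `N` on input; `N` never matches.
* Translation is a plain table-11 codon lookup (no initiator remapping —
  only the ORF caller applies start-codon semantics); codons containing
  `N` render `X`; proteins with internal stops are excluded from
  comparative analysis with a warning.
* Assembler and clustering tie-breaks are lexicographic and documented
  above; every stochastic step takes an explicit seed, and the pipeline
  invariant "same config + seed ⇒ byte-identical outputs" is asserted in
  the test suite.
* Empty inputs: assembling zero reads yields zero contigs; a pileup with
  zero covering reads has completeness 0 and an all-`N` consensus; a
  clustering with zero kept edges yields all-singleton families; an
  all-zero new-gene series leaves α undefined and the pan-genome flagged
  closed.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in minutes on one CPU while every contract is
exercised end to end: genomes of 10–50 gene families (roughly 10–40 kb),
read sets at 15–30× coverage, 20 injected frameshifts for the recovery
experiment, a 5-genome / 50-core-family clustering recovery, 100
permutations for curve fitting, and a 3-genome full-pipeline determinism
check.  The pipeline itself has no built-in scale assumptions beyond
memory for the k-mer index and the all-vs-all candidate list.

## Known limitations

* The greedy exact-overlap assembler does not tolerate sequencing errors
  inside overlaps; with error-bearing reads the rescue stage degrades to
  admitting fewer, shorter contigs.
* The Karlin–Altschul constants are fixed defaults, not fitted to the
  scoring system per search; e-values are comparable within a run, not
  calibrated across arbitrary scoring changes.
* Spurious short ORFs surviving shadow suppression appear as singleton
  hypothetical families and inflate the unique-family count; they lower
  the fitted α but do not affect the clustering of annotated families.
* Reference selection assumes the reference database contains a close
  homolog; remote homologs below the product-assignment gates leave
  candidates unrepairable (reported, kept as-is).
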