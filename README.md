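# panrescue

Pan-genome analysis of draft bacterial genomes, with read-based gene
rescue and frameshift repair.

## The problem

Draft genomes — unfinished assemblies made of contigs with gaps —
dominate public databases, but their gene repertoire is incomplete:
genes fall into assembly gaps, and spurious single-base indels split one
gene into two broken coding sequences.  Feeding such drafts into a
pan-genome analysis under-counts gene families and biases the
core/accessory partition.  `panrescue` is for microbial comparative
genomicists who want to analyze drafts anyway: it restores missing gene
content from the raw sequencing reads before the comparative step, and
then runs the pan-genome analysis itself.

## What it does

For each draft genome with its reads:

1. **Rescue** — reads that fail to map to the contigs (seed-and-extend,
   22 nt exact seeds, ≤ 10% mismatches over the read) are assembled by a
   greedy exact-overlap assembler; assembled contigs with no significant
   hit against the input (Karlin–Altschul `E = K·m·n·e^{−λS}` ≤ 1e-5
   discards) and at least 200 bp long are appended to the assembly.
2. **Annotate** — maximal ORFs on both strands (≥ 120 nt), products by
   best Smith–Waterman hit (BLOSUM62, 11/1) against a reference protein
   set.
3. **Frameshift repair** — runs of consecutive same-product, same-strand
   CDSs are candidate broken genes; a reference gene is chosen by
   protein search, the reads are piled up against it, and the majority
   consensus replaces the broken pair when completeness (covered
   fraction of the reference) is ≥ 70%.

Across genomes it then computes gene families (all-vs-all protein
similarity; edges kept at e ≤ 1e-5, identity ≥ 0.7, coverage ≥ 0.8 on
both sequences; connected components, Markov clustering optional), the
core/accessory/unique partition, permutation pan/core curves with a
Heaps-law fit of the new-gene decay `n(N) = κ·N^{−α}` (open pan-genome
iff α ≤ 1), and a UPGMA tree on Jaccard distances over family presence.

A synthetic pan-genome generator with a ground-truth manifest
(`simulate_pangenome`, `make_draft`, `inject_frameshift`,
`simulate_reads`) provides a fully reproducible test bed.

## Worked example

```r
library(panrescue)

dir <- file.path(tempdir(), "demo")
pr  <- simulate_project(dir, n_genomes = 3, n_core = 15, seed = 42)
cfg <- read_project_config(pr$config)
run_pipeline(cfg)
out <- cfg$output_dir

do.call(rbind, lapply(c("G01", "G02"), function(g)
  read_tsv_file(file.path(out, g, "frameshift_report.tsv"))))
#>   genome_id                 product n_members completeness admitted
#> 1       G01 putative protein PF0007         2    1.0000000     TRUE
#> 2       G01 putative protein PF0001         2    0.9906760     TRUE
#> 3       G01 putative protein PF0016         2    0.9955107     TRUE
#> 4       G02 putative protein PF0013         2    0.9949495     TRUE
#> 5       G02 putative protein PF0003         2    1.0000000     TRUE
#> 6       G02 putative protein PF0001         2    1.0000000     TRUE
```

Each of the six frameshifts injected into the two draft genomes was
detected as a two-member same-product run and repaired: the read pileup
covered ≥ 99% of the chosen reference, clearing the 70% completeness
gate, so the two broken CDSs were merged back into one gene.

```r
read_tsv_file(file.path(out, "G01", "rescue_report.tsv"))
#>            id length best_evalue decision
#> 4 rescued_001   1432   0.4686665 admitted
```

The 1432 bp contig assembled from G01's unmapped reads — the fragment
deliberately dropped from that draft — has no significant hit against
the input contigs (best e-value 0.47, far above the 1e-5 discard
threshold) and passes the 200 bp floor, so it is appended and its genes
re-enter the analysis.

```r
read_tsv_file(file.path(out, "partition.tsv"))
#>    category n_families
#> 1      core         15
#> 2 accessory          2
#> 3    unique         52

read_tsv_file(file.path(out, "heaps.tsv"))
#>   aggregate    kappa     alpha open_pangenome
#> 1      mean 19.05683 0.1147325           TRUE
#> 2    median 16.87772 0.1701574           TRUE

readLines(file.path(out, "tree.nwk"))
#> (G02:0.3590909091,(G01:0.3222222222,G03:0.3222222222):0.03686868687);
```

All 15 simulated core families are recovered as core despite the
fragmentation, lost contig and injected frameshifts.  The fitted decay
exponent α ≤ 1 classifies the pan-genome open (the unique count includes
singleton hypothetical ORFs of the intrinsic gene caller; see the
methods vignette).  The Newick tree places the two drafts and the
complete genome at Jaccard presence distances.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/panrescue simulate --dir proj --genomes 4 --seed 1
Rscript inst/scripts/panrescue run --config proj/config.yaml
```

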