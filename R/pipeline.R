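# Pipeline orchestration: per draft genome rescue -> annotate -> frameshift
# detect/repair; per complete genome annotate only; then standardization,
# clustering, pan/core curves with the Heaps fit, the UPGMA tree and chart
# tables.  Stages communicate through files in the output directory and an
# append-only JSON-lines journal records step status, so an interrupted run
# resumes where it stopped.

`%||%` <- function(a, b) if (is.null(a)) b else a

journal_append <- function(path, step, genome, state, message = "") {
  rec <- list(step = step, genome = genome, state = state,
              time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              message = message)
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", sep = "",
      file = path, append = TRUE)
  invisible(rec)
}

journal_read <- function(path) {
  if (!file.exists(path)) {
    return(data.frame(step = character(), genome = character(),
                      state = character(), time = character(),
                      message = character(), stringsAsFactors = FALSE))
  }
  lines <- readLines(path)
  if (length(lines) == 0L) return(journal_read(tempfile()))
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}

step_is_done <- function(journal, step, genome, outputs) {
  rows <- journal[journal$step == step & journal$genome == genome, ,
                  drop = FALSE]
  if (nrow(rows) == 0L) return(FALSE)
  utils::tail(rows$state, 1L) == "done" && all(file.exists(outputs))
}

#' Read and validate a project configuration
#'
#' The YAML configuration lists the project name, the output directory,
#' the global seed, per-genome entries (contigs path, read paths with
#' library type and orientation, complete-genome flag, repair switch),
#' reference database paths, and optional parameter overrides for the
#' mapper, rescue, annotator, repair and clustering stages.
#'
#' @param path path to a YAML configuration file.
#' @return validated config list (class `project_config`).
#' @export
read_project_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  if (length(cfg$genomes) < 2L) {
    stop("comparative stages need >= 2 genomes", call. = FALSE)
  }
  ids <- vapply(cfg$genomes, function(g) g$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome_id in config",
                               call. = FALSE)
  for (i in seq_along(cfg$genomes)) {
    g <- cfg$genomes[[i]]
    g$contigs <- resolve(g$contigs)
    g$reads <- as.character(resolve(unlist(g$reads)))
    g$library <- g$library %||% "single"
    g$orientation <- g$orientation %||% "fr"
    g$complete <- isTRUE(g$complete)
    g$repair <- g$repair %||% !g$complete
    if (!file.exists(g$contigs)) {
      stop("contigs file missing for ", g$genome_id, ": ", g$contigs,
           call. = FALSE)
    }
    missing_reads <- g$reads[!file.exists(g$reads)]
    if (length(missing_reads)) {
      stop("read file missing for ", g$genome_id, ": ", missing_reads[1],
           call. = FALSE)
    }
    cfg$genomes[[i]] <- g
  }
  cfg$reference_proteins <- resolve(cfg$reference_proteins)
  cfg$reference_nt <- resolve(cfg$reference_nt)
  cfg$output_dir <- resolve(cfg$output_dir) %||% file.path(base, "output")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_permutations <- as.integer(cfg$n_permutations %||% 50L)
  cfg$mapper <- do.call(mapper_params, cfg$mapper %||% list())
  cfg$rescue <- do.call(rescue_params, cfg$rescue %||% list())
  cfg$annotator <- do.call(annotator_params, cfg$annotator %||% list())
  cfg$repair_cfg <- do.call(repair_params, cfg$repair_params %||% list())
  cfg$cluster <- do.call(cluster_params, cfg$cluster %||% list())
  structure(cfg, class = "project_config")
}

load_genome_reads <- function(g) {
  if (length(g$reads) == 0L) return(NULL)
  if (identical(g$library, "paired") && length(g$reads) == 2L) {
    rbind(read_fastq(g$reads[1], mate = "mate1"),
          read_fastq(g$reads[2], mate = "mate2"))
  } else {
    do.call(rbind, lapply(g$reads, read_fastq))
  }
}

# reconstruct a genome_annotation from the stage files on disk
load_stage_annotation <- function(embl_path, repaired_fasta, genome_id) {
  ann <- parse_embl_cds(embl_path, genome_id)
  rep_genes <- if (file.exists(repaired_fasta) &&
                   file.size(repaired_fasta) > 0L) {
    tryCatch(read_fasta(repaired_fasta), error = function(e) character())
  } else character()
  genome_annotation(genome_id, ann$contigs, ann$features, rep_genes)
}

#' Run the full pipeline
#'
#' Per draft genome: rescue, annotate, frameshift detect/repair; per
#' complete genome: annotate only.  Then standardize, cluster, partition,
#' curves, Heaps fit, tree and chart tables.  Steps already recorded done
#' in the journal (with their outputs present) are skipped on re-run; a
#' stage failure halts that genome's dependents while independent genomes
#' continue.
#'
#' @param config a `project_config` from [read_project_config()].
#' @return invisibly, a list with the journal path, output dir, and the
#'   per-stage results of the comparative analysis.
#' @export
run_pipeline <- function(config) {
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(out, "journal.jsonl")
  run_step <- function(step, genome, outputs, fun) {
    journal <- journal_read(jpath)
    if (step_is_done(journal, step, genome, outputs)) return(TRUE)
    journal_append(jpath, step, genome, "running")
    ok <- tryCatch({
      fun()
      TRUE
    }, error = function(e) {
      journal_append(jpath, step, genome, "failed", conditionMessage(e))
      FALSE
    })
    if (ok) journal_append(jpath, step, genome, "done")
    ok
  }
  ref_prot <- if (!is.null(config$reference_proteins)) {
    read_fasta(config$reference_proteins, alphabet = "protein")
  } else character()
  ref_nt <- if (!is.null(config$reference_nt)) {
    read_fasta(config$reference_nt)
  } else character()
  genome_ok <- logical(0)
  for (g in config$genomes) {
    gid <- g$genome_id
    gdir <- file.path(out, gid)
    dir.create(gdir, showWarnings = FALSE, recursive = TRUE)
    contigs_final <- file.path(gdir, "contigs_final.fasta")
    ok <- run_step("rescue", gid, contigs_final, function() {
      contigs <- read_fasta(g$contigs)
      ann <- genome_annotation(gid, contigs)
      if (g$complete || length(g$reads) == 0L) {
        write_fasta(contig_seqs(ann), contigs_final)
        write_tsv_file(data.frame(id = character(), length = integer(),
                                  best_evalue = numeric(),
                                  decision = character()),
                       file.path(gdir, "rescue_report.tsv"))
      } else {
        reads <- load_genome_reads(g)
        res <- rescue_genome(ann, reads, config$mapper, config$rescue)
        write_fasta(contig_seqs(res$annotation), contigs_final)
        write_tsv_file(res$report, file.path(gdir, "rescue_report.tsv"))
      }
    })
    embl0 <- file.path(gdir, "annotation.embl")
    ok <- ok && run_step("annotate", gid,
                         c(embl0, file.path(gdir, "annotation.gff3")),
                         function() {
      contigs <- read_fasta(contigs_final)
      ann <- annotate_genome(genome_annotation(gid, contigs), ref_prot,
                             config$annotator)
      write_embl(ann, embl0)
      write_gff3(ann, file.path(gdir, "annotation.gff3"))
    })
    embl1 <- file.path(gdir, "repaired_annotation.embl")
    rep_fa <- file.path(gdir, "repaired_genes.fasta")
    fs_report <- file.path(gdir, "frameshift_report.tsv")
    ok <- ok && run_step("frameshift", gid, c(embl1, fs_report), function() {
      ann <- load_stage_annotation(embl0, rep_fa, gid)
      det <- detect_frameshift_candidates(ann, config$repair_cfg)
      if (length(det$candidates)) {
        member_seqs <- unlist(lapply(det$candidates,
                                     function(cand) cand$member_seqs))
        write_fasta(member_seqs, file.path(gdir, "candidates.fasta"))
      }
      do_repair <- isTRUE(g$repair) && length(g$reads) > 0L
      if (do_repair) {
        reads <- load_genome_reads(g)
        rep <- repair_genome(ann, det$candidates, reads, ref_nt,
                             config$repair_cfg, config$mapper)
        write_embl(rep$annotation, embl1)
        if (length(rep$annotation$repaired_genes)) {
          write_fasta(rep$annotation$repaired_genes, rep_fa)
        } else if (file.exists(rep_fa)) {
          unlink(rep_fa)
        }
        write_tsv_file(rep$repairs, fs_report)
      } else {
        # repair off: annotation passes through; candidates still counted
        write_embl(ann, embl1)
        rep_df <- if (length(det$candidates)) {
          do.call(rbind, lapply(det$candidates, function(cand) data.frame(
            genome_id = gid, contig_id = cand$contig_id,
            product = cand$product, n_members = nrow(cand$members),
            loci = paste(cand$members$locus_id, collapse = ","),
            reference = NA_character_, completeness = NA_real_,
            admitted = FALSE, stringsAsFactors = FALSE)))
        } else {
          data.frame(genome_id = character(), contig_id = character(),
                     product = character(), n_members = integer(),
                     loci = character(), reference = character(),
                     completeness = numeric(), admitted = logical())
        }
        write_tsv_file(rep_df, fs_report)
      }
    })
    genome_ok[gid] <- ok
  }
  if (!all(genome_ok)) {
    warning("comparative stages skipped: failed genome(s): ",
            paste(names(genome_ok)[!genome_ok], collapse = ", "))
    return(invisible(list(journal = jpath, output_dir = out,
                          genome_ok = genome_ok)))
  }
  gids <- vapply(config$genomes, function(g) g$genome_id, character(1))
  std_dir <- file.path(out, "standardized")
  std_files <- as.vector(vapply(gids, function(g)
    file.path(std_dir, paste0(g, c(".nuc", ".pep", ".function"))),
    character(3)))
  run_step("standardize", "all", std_files, function() {
    anns <- lapply(gids, function(gid) {
      gdir <- file.path(out, gid)
      load_stage_annotation(file.path(gdir, "repaired_annotation.embl"),
                            file.path(gdir, "repaired_genes.fasta"), gid)
    })
    names(anns) <- gids
    write_standardized(standardize_genomes(anns), std_dir)
  })
  fam_file <- file.path(out, "families.tsv")
  part_file <- file.path(out, "partition.tsv")
  uniq_file <- file.path(out, "unique_genes.tsv")
  run_step("cluster", "all", c(fam_file, part_file, uniq_file), function() {
    peps <- lapply(gids, function(g)
      read_fasta(file.path(std_dir, paste0(g, ".pep")),
                 alphabet = "protein"))
    names(peps) <- gids
    edges <- all_vs_all(peps, config$cluster)
    genes <- do.call(rbind, lapply(gids, function(g) data.frame(
      genome_id = g, locus_id = names(peps[[g]]),
      stringsAsFactors = FALSE)))
    fams <- cluster_families(edges, genes, config$cluster)
    part <- partition_families(fams, gids)
    write_tsv_file(part$families, fam_file)
    write_tsv_file(data.frame(category = names(part$counts),
                              n_families = as.integer(part$counts)),
                   part_file)
    write_tsv_file(part$unique_per_genome, uniq_file)
  })
  curve_file <- file.path(out, "pan_core_curves.tsv")
  heaps_file <- file.path(out, "heaps.tsv")
  run_step("curves", "all", c(curve_file, heaps_file), function() {
    fams <- read_tsv_file(fam_file)
    curve <- pan_core_curves(fams, gids, config$n_permutations,
                             config$seed)
    long <- do.call(rbind, lapply(seq_len(curve$permutations), function(p)
      data.frame(permutation = p, step = seq_len(curve$genome_steps),
                 pan = curve$pan_sizes[p, ], core = curve$core_sizes[p, ],
                 new = curve$new_gene_counts[p, ])))
    write_tsv_file(long, curve_file)
    fits <- lapply(c("mean", "median"), function(a) fit_heaps(curve, a))
    write_tsv_file(data.frame(
      aggregate = vapply(fits, function(f) f$aggregate, character(1)),
      kappa = vapply(fits, function(f) f$kappa, numeric(1)),
      alpha = vapply(fits, function(f) f$alpha, numeric(1)),
      open_pangenome = vapply(fits, function(f) f$open_pangenome,
                              logical(1))), heaps_file)
  })
  tree_file <- file.path(out, "tree.nwk")
  run_step("tree", "all", tree_file, function() {
    fams <- read_tsv_file(fam_file)
    writeLines(upgma_tree(fams, gids), tree_file)
  })
  charts_dir <- file.path(out, "charts")
  run_step("charts", "all",
           file.path(charts_dir, c("unique_genes.tsv",
                                   "shared_orthologs.tsv",
                                   "pan_core_boxplot.tsv", "tree.nwk")),
           function() {
    emit_chart_tables(out, charts_dir)
  })
  invisible(list(journal = jpath, output_dir = out, genome_ok = genome_ok))
}

#' Emit chart data tables
#'
#' Collects the comparative outputs into the chart tables: unique genes per
#' genome, shared-ortholog counts (families by number of genomes sharing
#' them), the pan/core boxplot long table with a Heaps annotation row, and
#' a copy of the Newick tree.
#'
#' @param out_dir pipeline output directory holding the comparative files.
#' @param charts_dir destination directory.
#' @return the charts directory, invisibly.
#' @export
emit_chart_tables <- function(out_dir, charts_dir = file.path(out_dir,
                                                              "charts")) {
  dir.create(charts_dir, showWarnings = FALSE, recursive = TRUE)
  uniq <- read_tsv_file(file.path(out_dir, "unique_genes.tsv"))
  write_tsv_file(uniq, file.path(charts_dir, "unique_genes.tsv"))
  fams <- read_tsv_file(file.path(out_dir, "families.tsv"))
  span <- tapply(fams$genome_id, fams$family_id,
                 function(g) length(unique(g)))
  span_tab <- table(factor(span, levels = seq_len(max(
    length(unique(fams$genome_id)), 1L))))
  write_tsv_file(data.frame(n_genomes_sharing = as.integer(names(span_tab)),
                            n_families = as.integer(span_tab)),
                 file.path(charts_dir, "shared_orthologs.tsv"))
  curves <- read_tsv_file(file.path(out_dir, "pan_core_curves.tsv"))
  heaps <- read_tsv_file(file.path(out_dir, "heaps.tsv"))
  boxplot_tab <- curves
  boxplot_tab$annotation <- ""
  for (i in seq_len(nrow(heaps))) {
    boxplot_tab <- rbind(boxplot_tab, data.frame(
      permutation = NA, step = NA, pan = NA, core = NA, new = NA,
      annotation = sprintf("heaps_%s kappa=%.6g alpha=%.6g %s",
                           heaps$aggregate[i], heaps$kappa[i],
                           heaps$alpha[i],
                           ifelse(heaps$open_pangenome[i], "open",
                                  "closed"))))
  }
  write_tsv_file(boxplot_tab, file.path(charts_dir, "pan_core_boxplot.tsv"))
  file.copy(file.path(out_dir, "tree.nwk"),
            file.path(charts_dir, "tree.nwk"), overwrite = TRUE)
  invisible(charts_dir)
}

#' Create a synthetic project on disk
#'
#' Simulates a pan-genome, turns all but one genome into drafts (with
#' fragmentation, contig loss and injected frameshifts), simulates reads,
#' writes the reference databases derived from the ancestral gene pool,
#' and writes a ready-to-run YAML configuration.
#'
#' @param dir project directory (created).
#' @param n_genomes number of genomes; the last one stays complete.
#' @param n_core core families.
#' @param accessory_rate accessory draw rate (see [simulate_pangenome()]).
#' @param sub_rate per-site substitution rate between genomes.
#' @param coverage read coverage per genome.
#' @param read_len read length.
#' @param n_breaks fragmentation cuts per draft.
#' @param drop_prob contig drop probability per draft.
#' @param n_frameshifts injected frameshifts per draft.
#' @param n_permutations pan/core permutations.
#' @param seed integer seed driving the whole simulation.
#' @return list: `config` (path to config.yaml), `truth` (manifest),
#'   `genomes` (the unfragmented annotations), `drafts` (draft
#'   annotations), `injections` (data frame).
#' @export
simulate_project <- function(dir, n_genomes = 4L, n_core = 20L,
                             accessory_rate = 0.3, sub_rate = 0.02,
                             coverage = 20, read_len = 100L,
                             n_breaks = 6L, drop_prob = 0.1,
                             n_frameshifts = 3L, n_permutations = 25L,
                             seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_pangenome(n_genomes, n_core, accessory_rate,
                            sub_rate = sub_rate, seed = seed)
  gids <- names(sim$genomes)
  complete_id <- gids[length(gids)]
  ref_nt <- sim$truth$family_seqs
  names(ref_nt) <- sprintf("%s %s", names(ref_nt),
                           sim$truth$family_products[names(ref_nt)])
  ref_prot <- vapply(sim$truth$family_seqs, protein_of, character(1))
  names(ref_prot) <- names(ref_nt)
  write_fasta(ref_nt, file.path(dir, "reference_genes.fasta"))
  write_fasta(ref_prot, file.path(dir, "reference_proteins.fasta"))
  drafts <- list()
  injections <- list()
  entries <- list()
  for (k in seq_along(gids)) {
    gid <- gids[k]
    complete <- gid == complete_id
    gseed <- seed + 101L * k
    if (complete) {
      ann <- sim$genomes[[gid]]
      read_source <- ann
    } else {
      # fragment first with no loss: draft breaks coincide with coverage
      # gaps, so reads are sampled per fragment and never span a junction
      frag <- make_draft(sim$genomes[[gid]], n_breaks, drop_prob = 0,
                         min_fragment = 200L, seed = gseed)
      read_source <- frag$annotation
      # drop one gene-bearing fragment so the rescue stage has work to do
      fx <- frag$annotation$features
      genes_per <- table(fx$contig_id)
      lens <- setNames(nchar(frag$annotation$contigs$seq),
                       frag$annotation$contigs$id)
      cand <- names(genes_per)[lens[names(genes_per)] >= 400 &
                                 lens[names(genes_per)] <= 3000]
      force_idx <- if (length(cand)) {
        # fragment index is encoded in the contig id suffix
        as.integer(sub("^.*_c", "", cand[which.min(lens[cand])]))
      } else integer()
      dr <- make_draft(sim$genomes[[gid]], n_breaks, drop_prob,
                       min_fragment = 200L, seed = gseed,
                       force_drop = force_idx)
      sim$truth$dropped_genes <- rbind(sim$truth$dropped_genes, dr$delta)
      ann <- dr$annotation
      if (n_frameshifts > 0L) {
        inj <- inject_random_frameshifts(ann, n_frameshifts,
                                         seed = gseed + 1L)
        ann <- inj$genome
        injections[[gid]] <- inj$injections
        sim$truth$injected_frameshifts <-
          rbind(sim$truth$injected_frameshifts,
                inj$injections[c("genome_id", "gene_id", "pos", "kind")])
      }
      drafts[[gid]] <- ann
    }
    contigs_file <- file.path(dir, paste0(gid, "_contigs.fasta"))
    write_fasta(contig_seqs(ann), contigs_file)
    write_gff3(ann, file.path(dir, paste0(gid, "_truth.gff3")))
    # reads come from the organism's true sequence (fragmented but with
    # nothing dropped and no injected indels)
    reads <- simulate_reads(read_source, read_len = read_len,
                            coverage = coverage, error_rate = 0,
                            seed = gseed + 2L)
    reads_file <- file.path(dir, paste0(gid, "_reads.fastq"))
    write_fastq(reads, reads_file)
    entries[[k]] <- list(genome_id = gid,
                         contigs = basename(contigs_file),
                         reads = list(basename(reads_file)),
                         library = "single", complete = complete,
                         repair = !complete)
  }
  cfg <- list(project = basename(dir), output_dir = "output",
              seed = as.integer(seed), n_permutations = n_permutations,
              reference_proteins = "reference_proteins.fasta",
              reference_nt = "reference_genes.fasta", genomes = entries)
  cfg_path <- file.path(dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  write_truth_manifest(sim$truth, file.path(dir, "truth"))
  list(config = cfg_path, truth = sim$truth, genomes = sim$genomes,
       drafts = drafts,
       injections = do.call(rbind, c(unname(injections),
                                     list(make.row.names = FALSE))))
}
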