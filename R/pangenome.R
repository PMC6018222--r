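# Native comparative analysis: all-vs-all protein similarity, thresholded
# gene-family clustering (connected components by default, Markov
# clustering optional), core/accessory/unique partition, permutation
# pan/core curves, Heaps-law openness fit, and a UPGMA tree on gene
# presence/absence.  Clustering thresholds follow the validated settings:
# e-value 1e-5, identity 0.7, coverage 0.8.

#' Clustering parameters
#'
#' @param evalue e-value threshold for keeping an edge (default 1e-5).
#' @param identity_min minimum identity over alignment columns (default 0.7).
#' @param coverage_min minimum coverage; applied to both sequences (the
#'   minimum of the two coverages must pass; set `one_sided = TRUE` for a
#'   single-sided gate).
#' @param method `"connected_components"` (deterministic default) or
#'   `"markov"` (Markov clustering with similarity weights).
#' @param inflation Markov-clustering inflation (> 1).
#' @param one_sided apply the coverage gate to the query side only.
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(evalue = 1e-5, identity_min = 0.7,
                           coverage_min = 0.8,
                           method = c("connected_components", "markov"),
                           inflation = 1.5, one_sided = FALSE) {
  method <- match.arg(method)
  stopifnot(evalue > 0, identity_min > 0, identity_min <= 1,
            coverage_min > 0, coverage_min <= 1, inflation > 1)
  structure(list(evalue = evalue, identity_min = identity_min,
                 coverage_min = coverage_min, method = method,
                 inflation = inflation, one_sided = one_sided),
            class = "cluster_params")
}

gene_key <- function(genome_id, locus_id) {
  paste(genome_id, locus_id, sep = "|")
}

#' Standardize annotated genomes for comparative analysis
#'
#' Produces the per-genome gene nucleotide set, protein set and
#' locus-to-product table (the .nuc/.pep/.function trio).  Genes whose
#' translation has internal stops are dropped with a warning.
#'
#' @param anns named list of [genome_annotation()] objects.
#' @return list per genome: `nuc`, `pep` (named character vectors keyed by
#'   locus), `products` (data frame `locus_id`, `product`).
#' @export
standardize_genomes <- function(anns) {
  out <- list()
  for (g in names(anns)) {
    nuc <- gene_seqs(anns[[g]])
    pep <- vapply(nuc, protein_of, character(1))
    bad <- is.na(pep)
    if (any(bad)) {
      warning(sum(bad), " untranslatable gene(s) dropped in ", g)
      nuc <- nuc[!bad]
      pep <- pep[!bad]
    }
    fx <- anns[[g]]$features
    out[[g]] <- list(
      nuc = nuc, pep = pep,
      products = data.frame(
        locus_id = names(nuc),
        product = fx$product[match(names(nuc), fx$locus_id)],
        stringsAsFactors = FALSE))
  }
  out
}

#' Write the standardized trio to disk
#' @param std output of [standardize_genomes()].
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_standardized <- function(std, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(std)) {
    write_fasta(std[[g]]$nuc, file.path(dir, paste0(g, ".nuc")))
    write_fasta(std[[g]]$pep, file.path(dir, paste0(g, ".pep")))
    write_tsv_file(std[[g]]$products, file.path(dir,
                                                paste0(g, ".function")))
  }
  invisible(dir)
}

#' All-vs-all protein similarity edges
#'
#' Every gene pair (inter- and intra-genome) sharing an amino-acid k-mer is
#' aligned by Smith-Waterman (BLOSUM62, gap open 11 / extend 1); identity
#' is matches over alignment columns, coverage is the aligned span over
#' each sequence's length, and the e-value is Karlin-Altschul with the
#' pair's m*n search space.
#'
#' @param proteins_by_genome named list: genome id -> named character
#'   vector of proteins keyed by locus.
#' @param params a [cluster_params()] (thresholds are applied later, in
#'   [cluster_families()]; every aligned pair is reported here).
#' @param prefilter_k amino-acid k-mer length for the candidate-pair
#'   prefilter.
#' @param min_shared_kmers number of distinct shared k-mers required before
#'   a pair is aligned (homologous pairs at the clustering identity
#'   threshold share dozens; unrelated pairs rarely share two).
#' @return data frame: `a`, `b` (gene keys), `identity`, `coverage_a`,
#'   `coverage_b`, `evalue`.
#' @export
all_vs_all <- function(proteins_by_genome, params = cluster_params(),
                       prefilter_k = 5L, min_shared_kmers = 2L) {
  stopifnot(length(proteins_by_genome) >= 2L)
  keys <- character()
  seqs <- character()
  for (g in names(proteins_by_genome)) {
    p <- proteins_by_genome[[g]]
    keys <- c(keys, gene_key(g, names(p)))
    seqs <- c(seqs, unname(p))
  }
  n <- length(seqs)
  kmers <- aa_kmer_sets(seqs, prefilter_k)
  inv <- split(rep(seq_len(n), lengths(kmers)), unlist(kmers))
  all_pairs <- unlist(lapply(inv, function(g) {
    if (length(g) < 2L) return(NULL)
    g <- sort(g)
    pr <- utils::combn(g, 2L)
    pr[1, ] * (n + 1L) + pr[2, ]
  }), use.names = FALSE)
  if (length(all_pairs)) {
    r <- rle(sort(all_pairs))
    pair_keys <- r$values[r$lengths >= min_shared_kmers]
  } else {
    pair_keys <- integer()
  }
  if (length(pair_keys) == 0L) {
    return(data.frame(a = character(), b = character(), identity = numeric(),
                      coverage_a = numeric(), coverage_b = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  ii <- pair_keys %/% (n + 1L)
  jj <- pair_keys %% (n + 1L)
  ord <- order(ii, jj)
  ii <- ii[ord]
  jj <- jj[ord]
  rows <- vector("list", length(ii))
  for (r in seq_along(ii)) {
    a <- aa_local_align(seqs[ii[r]], seqs[jj[r]])
    e <- ka_evalue(a$score, nchar(seqs[ii[r]]), nchar(seqs[jj[r]]), AA_KA)
    rows[[r]] <- data.frame(
      a = keys[ii[r]], b = keys[jj[r]], identity = a$identity,
      coverage_a = a$coverage_q, coverage_b = a$coverage_s, evalue = e,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Markov clustering (expansion 2, stated inflation) on a weighted adjacency
# matrix; returns an integer membership vector
markov_cluster <- function(adj, inflation, max_iter = 100L, tol = 1e-6) {
  n <- nrow(adj)
  M <- adj + diag(n)                    # self loops
  M <- sweep(M, 2L, colSums(M), "/")
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                       # expansion
    M2 <- M2^inflation                  # inflation
    M2[M2 < 1e-12] <- 0
    M2 <- sweep(M2, 2L, pmax(colSums(M2), .Machine$double.eps), "/")
    if (max(abs(M2 - M)) < tol) {
      M <- M2
      break
    }
    M <- M2
  }
  # attractor rows define clusters; overlapping row supports are unioned
  g <- igraph::graph_from_adjacency_matrix(M > 1e-6, mode = "max")
  igraph::components(g)$membership
}

#' Cluster genes into families
#'
#' Edges passing all thresholds (e-value, identity, coverage on both
#' sequences unless `one_sided`) define a graph over all genes; families
#' are its connected components (singletons included) or Markov clusters.
#' Family ids are deterministic: families are sorted by their smallest
#' member key.
#'
#' @param edges edge table from [all_vs_all()].
#' @param genes data frame with `genome_id`, `locus_id` covering every gene
#'   (also those with no edges).
#' @param params a [cluster_params()].
#' @return data frame: `family_id`, `genome_id`, `locus_id`, `gene_key`.
#' @export
cluster_families <- function(edges, genes, params = cluster_params()) {
  keys <- gene_key(genes$genome_id, genes$locus_id)
  stopifnot(!anyDuplicated(keys))
  cov_ok <- if (params$one_sided) {
    edges$coverage_a >= params$coverage_min
  } else {
    pmin(edges$coverage_a, edges$coverage_b) >= params$coverage_min
  }
  keep <- edges[edges$evalue <= params$evalue &
                  edges$identity >= params$identity_min & cov_ok, ,
                drop = FALSE]
  keep <- keep[keep$a %in% keys & keep$b %in% keys, , drop = FALSE]
  if (params$method == "connected_components") {
    g <- igraph::graph_from_data_frame(keep[c("a", "b")], directed = FALSE,
                                       vertices = keys)
    memb <- igraph::components(g)$membership[keys]
  } else {
    adj <- matrix(0, length(keys), length(keys),
                  dimnames = list(keys, keys))
    if (nrow(keep)) {
      adj[cbind(keep$a, keep$b)] <- keep$identity
      adj[cbind(keep$b, keep$a)] <- keep$identity
    }
    memb <- markov_cluster(adj, params$inflation)
    names(memb) <- keys
  }
  smallest <- tapply(keys, memb, min)
  fam_rank <- rank(smallest, ties.method = "first")
  fam_ids <- sprintf("GF%05d", fam_rank)[match(memb, names(smallest))]
  data.frame(family_id = fam_ids, genome_id = genes$genome_id,
             locus_id = genes$locus_id, gene_key = keys,
             stringsAsFactors = FALSE)
}

#' Partition families into core, accessory and unique
#'
#' Core families span all genomes (at least one member per genome; a family
#' may hold several genes of one genome), unique families span exactly one
#' genome, accessory families the rest.
#'
#' @param families family table from [cluster_families()].
#' @param genome_ids all genome ids in the analysis.
#' @return list: `families` (with `category` column), `counts` (named
#'   vector core/accessory/unique), `unique_per_genome` (data frame).
#' @export
partition_families <- function(families, genome_ids) {
  span <- tapply(families$genome_id, families$family_id,
                 function(g) length(unique(g)))
  category <- setNames(
    as.character(ifelse(span == length(genome_ids), "core",
                        ifelse(span == 1L, "unique", "accessory"))),
    names(span))
  families$category <- unname(category[families$family_id])
  counts <- c(core = sum(category == "core"),
              accessory = sum(category == "accessory"),
              unique = sum(category == "unique"))
  uniq <- families[families$category == "unique", , drop = FALSE]
  uniq_fams <- unique(uniq[c("family_id", "genome_id")])
  unique_per_genome <- data.frame(
    genome_id = genome_ids,
    n_unique_families = vapply(genome_ids, function(g)
      sum(uniq_fams$genome_id == g), integer(1)),
    stringsAsFactors = FALSE)
  list(families = families, counts = counts,
       unique_per_genome = unique_per_genome)
}

round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Similarity percentages of identical products
#'
#' The accuracy metric comparing a draft against its complete genome:
#' identical-product counts as a percentage of the total products found,
#' reported to 2 decimals (round half up).
#'
#' @param n_identical_core identical products in core families.
#' @param n_identical_accessory identical products in accessory families.
#' @param n_total_found total products found (> 0).
#' @return named vector `pct_core`, `pct_accessory`.
#' @export
similarity_percentages <- function(n_identical_core, n_identical_accessory,
                                   n_total_found) {
  stopifnot(n_identical_core >= 0, n_identical_accessory >= 0)
  if (n_total_found <= 0) stop("n_total_found must be positive",
                               call. = FALSE)
  stopifnot(n_identical_core <= n_total_found,
            n_identical_accessory <= n_total_found)
  c(pct_core = round_half_up(100 * n_identical_core / n_total_found),
    pct_accessory = round_half_up(100 * n_identical_accessory /
                                    n_total_found))
}

#' Count draft genes identical to a complete-genome family member
#'
#' A draft gene counts when some complete-genome gene in its family has an
#' identical amino-acid sequence (100% similarity means exact); tallied
#' separately for core and accessory families.
#'
#' @param draft_id,complete_id genome ids present in the clustering.
#' @param families partitioned family table (with `category`).
#' @param proteins named character vector of proteins keyed by gene key.
#' @return list: `n_identical_core`, `n_identical_accessory`,
#'   `n_total_draft`.
#' @export
count_identical_products <- function(draft_id, complete_id, families,
                                     proteins) {
  stopifnot(all(c(draft_id, complete_id) %in% families$genome_id))
  draft <- families[families$genome_id == draft_id, , drop = FALSE]
  comp <- families[families$genome_id == complete_id, , drop = FALSE]
  comp_by_fam <- split(comp$gene_key, comp$family_id)
  n_core <- 0L
  n_acc <- 0L
  for (i in seq_len(nrow(draft))) {
    mates <- comp_by_fam[[draft$family_id[i]]]
    if (is.null(mates)) next
    if (proteins[[draft$gene_key[i]]] %in% unname(proteins[mates])) {
      if (draft$category[i] == "core") n_core <- n_core + 1L
      else if (draft$category[i] == "accessory") n_acc <- n_acc + 1L
    }
  }
  list(n_identical_core = n_core, n_identical_accessory = n_acc,
       n_total_draft = nrow(draft))
}

#' Permutation pan/core curves
#'
#' For each seeded random permutation of the genomes, at step N the pan
#' size is the number of families seen in the first N genomes, the core
#' size the number of families present in all of them, and the new-gene
#' count the number of families first observed at step N.
#'
#' @param families family table.
#' @param genome_ids all genome ids.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed.
#' @return a `pan_curve`: matrices `pan_sizes`, `core_sizes`,
#'   `new_gene_counts` of shape permutations x steps.
#' @export
pan_core_curves <- function(families, genome_ids, n_permutations = 100L,
                            seed = 1L) {
  stopifnot(n_permutations >= 1L)
  fam_ids <- sort(unique(families$family_id))
  pres <- matrix(FALSE, length(fam_ids), length(genome_ids),
                 dimnames = list(fam_ids, genome_ids))
  pres[cbind(families$family_id, families$genome_id)] <- TRUE
  G <- length(genome_ids)
  withr::with_seed(seed, {
    pan <- core <- new <- matrix(0L, n_permutations, G)
    for (p in seq_len(n_permutations)) {
      ord <- sample(genome_ids)
      P <- pres[, ord, drop = FALSE]
      seen <- rep(FALSE, nrow(P))
      inall <- rep(TRUE, nrow(P))
      for (N in seq_len(G)) {
        prev <- sum(seen)
        seen <- seen | P[, N]
        inall <- inall & P[, N]
        pan[p, N] <- sum(seen)
        core[p, N] <- sum(inall)
        new[p, N] <- sum(seen) - prev
      }
    }
    structure(list(permutations = n_permutations, pan_sizes = pan,
                   core_sizes = core, new_gene_counts = new,
                   genome_steps = G), class = "pan_curve")
  })
}

#' Fit Heaps' law to the new-gene decay
#'
#' Aggregates new-gene counts across permutations at each step N >= 2 by
#' mean or median and fits `n(N) = kappa * N^(-alpha)` by nonlinear least
#' squares (log-log regression initialization, kappa bounded positive).
#'
#' @param curve a `pan_curve`.
#' @param aggregate `"median"` or `"mean"`.
#' @return a `heaps_fit`: `kappa`, `alpha`, `aggregate`, `open_pangenome`.
#'   When every aggregated count is zero, `alpha` is `NA` and the
#'   pan-genome is flagged closed.
#' @export
fit_heaps <- function(curve, aggregate = c("median", "mean")) {
  aggregate <- match.arg(aggregate)
  G <- curve$genome_steps
  stopifnot(G >= 3L)
  N <- 2:G
  y <- apply(curve$new_gene_counts[, N, drop = FALSE], 2L,
             if (aggregate == "median") stats::median else mean)
  if (all(y == 0)) {
    return(structure(list(kappa = NA_real_, alpha = NA_real_,
                          aggregate = aggregate, open_pangenome = FALSE),
                     class = "heaps_fit"))
  }
  pos <- y > 0
  init <- if (sum(pos) >= 2L) {
    cf <- stats::coef(stats::lm(log(y[pos]) ~ log(N[pos])))
    list(kappa = exp(cf[[1]]), alpha = -cf[[2]])
  } else {
    list(kappa = max(y), alpha = 0.5)
  }
  cf <- tryCatch({
    fit <- minpack.lm::nlsLM(
      y ~ kappa * N^(-alpha), start = init,
      lower = c(kappa = .Machine$double.xmin, alpha = -Inf),
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 500L))
    stats::coef(fit)
  }, error = function(e) {
    # degenerate designs (few steps, zeros): the log-log regression
    # initialization is itself the least-squares answer or close to it
    c(kappa = init$kappa, alpha = init$alpha)
  })
  out <- structure(list(kappa = unname(cf["kappa"]),
                        alpha = unname(cf["alpha"]),
                        aggregate = aggregate, open_pangenome = NA),
                   class = "heaps_fit")
  out$open_pangenome <- classify_openness(out)
  out
}

#' Classify a pan-genome as open or closed
#'
#' Open iff the fitted decay exponent satisfies `alpha <= 1` (boundary
#' inclusive); an undefined alpha classifies closed.
#'
#' @param fit a `heaps_fit` (or anything with an `alpha` element).
#' @return logical: open?
#' @export
classify_openness <- function(fit) {
  if (is.na(fit$alpha)) return(FALSE)
  fit$alpha <= 1
}

#' UPGMA tree on gene-family presence/absence
#'
#' Distance between genomes is Jaccard on family presence sets
#' (`1 - shared / either`); agglomeration is arithmetic-mean linkage with
#' ultrametric branch lengths (node height = half the merge distance).
#'
#' @param families family table.
#' @param genome_ids genome ids (>= 2); processed in sorted order so the
#'   result is independent of input order.
#' @return Newick string with branch lengths.
#' @export
upgma_tree <- function(families, genome_ids) {
  stopifnot(length(genome_ids) >= 2L)
  genome_ids <- sort(genome_ids)
  sets <- lapply(genome_ids, function(g)
    unique(families$family_id[families$genome_id == g]))
  names(sets) <- genome_ids
  G <- length(genome_ids)
  D <- matrix(0, G, G, dimnames = list(genome_ids, genome_ids))
  for (i in seq_len(G - 1L)) {
    for (j in (i + 1L):G) {
      shared <- length(intersect(sets[[i]], sets[[j]]))
      either <- length(union(sets[[i]], sets[[j]]))
      d <- if (either == 0L) 0 else 1 - shared / either
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  ape::write.tree(ape::as.phylo(hc))
}
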