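# EMBL flat-file feature tables: read of FT CDS lines with /product and
# /locus_tag qualifiers, and a matching writer.  EMBL locations are 1-based
# inclusive; they are converted to the internal 0-based half-open convention
# here and nowhere else.  join(...) locations are flattened to their
# outermost span with a warning and a `joined` flag: compound locations are
# rare in the prokaryotic scope of this package.

parse_embl_location <- function(loc, lineno) {
  raw <- loc
  strand <- "+"
  joined <- FALSE
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(.*\\)$", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(.*\\)$", loc)) {
    joined <- TRUE
    loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  }
  loc <- gsub("[<>]", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  m <- regexec("^([0-9]+)\\.\\.([0-9]+)$", parts)
  hits <- regmatches(parts, m)
  if (length(hits) == 0L || any(lengths(hits) != 3L)) {
    stop("malformed EMBL location \"", raw, "\" at line ", lineno,
         call. = FALSE)
  }
  starts <- vapply(hits, function(h) as.integer(h[2]), integer(1))
  ends <- vapply(hits, function(h) as.integer(h[3]), integer(1))
  if (any(starts > ends)) {
    stop("malformed EMBL location \"", raw, "\" at line ", lineno,
         call. = FALSE)
  }
  # outermost span, 1-based inclusive -> 0-based half-open
  list(start = min(starts) - 1L, end = max(ends), strand = strand,
       joined = joined)
}

#' Parse CDS features from an EMBL flat file
#'
#' Reads `FT   CDS` lines with their location and `/product` and
#' `/locus_tag` qualifiers (the only qualifiers honored).  A CDS without a
#' `/product` gets `"hypothetical protein"`.  Entry sequences are taken from
#' the `SQ` block when present.
#'
#' @param path path to an EMBL flat file (one or more entries).
#' @param genome_id genome id for the returned annotation; defaults to the
#'   first entry id.
#' @return a [genome_annotation()].
#' @export
parse_embl_cds <- function(path, genome_id = NULL) {
  lines <- readLines(path)
  contig_ids <- character()
  contig_seqs <- character()
  feats <- list()
  cur_id <- NA_character_
  cur_seq <- character()
  in_sq <- FALSE
  # pending CDS being accumulated
  pend <- NULL
  n_auto <- 0L
  flush_pending <- function() {
    if (is.null(pend)) return()
    loc <- parse_embl_location(pend$loc, pend$lineno)
    if (loc$joined) {
      warning("join() location flattened to outermost span at line ",
              pend$lineno, call. = FALSE)
    }
    product <- if (is.null(pend$product)) "hypothetical protein" else
      pend$product
    locus <- if (is.null(pend$locus)) {
      n_auto <<- n_auto + 1L
      sprintf("cds_%04d", n_auto)
    } else pend$locus
    feats[[length(feats) + 1L]] <<- data.frame(
      contig_id = cur_id, start = loc$start, end = loc$end,
      strand = loc$strand, product = product, locus_id = locus,
      stringsAsFactors = FALSE)
    pend <<- NULL
  }
  get_qualifier <- function(i, name) {
    # qualifier value, possibly quoted across several FT lines
    val <- sub(paste0("^FT\\s+/", name, "="), "", lines[i])
    if (!startsWith(val, "\"")) return(list(value = val, next_i = i + 1L))
    val <- substring(val, 2L)
    while (!grepl("\"\\s*$", val) && i < length(lines)) {
      i <- i + 1L
      val <- paste(val, sub("^FT\\s+", "", lines[i]))
    }
    list(value = sub("\"\\s*$", "", val), next_i = i + 1L)
  }
  i <- 1L
  while (i <= length(lines)) {
    line <- lines[i]
    if (startsWith(line, "ID   ")) {
      flush_pending()
      if (!is.na(cur_id)) {
        contig_ids <- c(contig_ids, cur_id)
        contig_seqs <- c(contig_seqs, paste(cur_seq, collapse = ""))
      }
      cur_id <- sub(";.*$", "", sub("^ID\\s+", "", line))
      cur_seq <- character()
      in_sq <- FALSE
    } else if (startsWith(line, "SQ")) {
      in_sq <- TRUE
    } else if (startsWith(line, "//")) {
      in_sq <- FALSE
    } else if (in_sq) {
      cur_seq <- c(cur_seq, gsub("[0-9 ]", "", line))
    } else if (grepl("^FT   CDS\\s", line)) {
      flush_pending()
      loc <- sub("^FT   CDS\\s+", "", line)
      lineno <- i
      # location continuation lines (no key, no qualifier)
      while (grepl(",$", loc) && i < length(lines) &&
             grepl("^FT\\s+[^/]", lines[i + 1L])) {
        i <- i + 1L
        loc <- paste0(loc, sub("^FT\\s+", "", lines[i]))
      }
      pend <- list(loc = loc, lineno = lineno, product = NULL, locus = NULL)
    } else if (!is.null(pend) && grepl("^FT\\s+/product=", line)) {
      q <- get_qualifier(i, "product")
      pend$product <- q$value
      i <- q$next_i - 1L
    } else if (!is.null(pend) && grepl("^FT\\s+/locus_tag=", line)) {
      q <- get_qualifier(i, "locus_tag")
      pend$locus <- q$value
      i <- q$next_i - 1L
    }
    i <- i + 1L
  }
  flush_pending()
  if (!is.na(cur_id)) {
    contig_ids <- c(contig_ids, cur_id)
    contig_seqs <- c(contig_seqs, paste(cur_seq, collapse = ""))
  }
  if (length(contig_ids) == 0L) stop("no EMBL entries in ", path,
                                     call. = FALSE)
  features <- if (length(feats)) do.call(rbind, feats) else empty_features()
  # entries without an SQ block: pad with N to the span the features need
  need <- vapply(contig_ids, function(cid) {
    fe <- features[features$contig_id == cid, , drop = FALSE]
    if (nrow(fe)) max(fe$end) else 1L
  }, numeric(1))
  empty <- !nzchar(contig_seqs)
  contig_seqs[empty] <- strrep("N", need[empty])
  contig_seqs <- normalize_dna(contig_seqs)
  if (is.null(genome_id)) genome_id <- contig_ids[1]
  genome_annotation(genome_id,
                    data.frame(id = contig_ids, seq = contig_seqs,
                               origin = "original", stringsAsFactors = FALSE),
                    features)
}

# qualifiers are written on one line regardless of length: products here are
# short, and an unwrapped line round-trips without continuation ambiguity
embl_wrap_qualifier <- function(name, value) {
  sprintf("FT                   /%s=\"%s\"", name, value)
}

#' Write a genome annotation as an EMBL-like flat file
#'
#' One entry per contig with `FT CDS` features (`/locus_tag`, `/product`)
#' and the sequence in an `SQ` block; the counterpart of
#' [parse_embl_cds()].
#'
#' @param ann a [genome_annotation()].
#' @param path output path.
#' @export
write_embl <- function(ann, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(ann$contigs))) {
    cid <- ann$contigs$id[i]
    seq <- ann$contigs$seq[i]
    writeLines(sprintf("ID   %s; SV 1; linear; genomic DNA; STD; PRO; %d BP.",
                       cid, nchar(seq)), con)
    writeLines("FH   Key             Location/Qualifiers", con)
    writeLines(sprintf("FT   source          1..%d", nchar(seq)), con)
    fx <- ann$features[ann$features$contig_id == cid, , drop = FALSE]
    for (j in seq_len(nrow(fx))) {
      loc <- sprintf("%d..%d", fx$start[j] + 1L, fx$end[j])
      if (fx$strand[j] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("FT   CDS             %s", loc), con)
      writeLines(embl_wrap_qualifier("locus_tag", fx$locus_id[j]), con)
      writeLines(embl_wrap_qualifier("product", fx$product[j]), con)
    }
    writeLines(sprintf("SQ   Sequence %d BP;", nchar(seq)), con)
    lo <- seq(1L, nchar(seq), by = 60L)
    writeLines(paste0("     ",
                      tolower(substring(seq, lo,
                                        pmin(lo + 59L, nchar(seq))))), con)
    writeLines("//", con)
  }
  invisible(path)
}
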