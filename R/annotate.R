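# Satellite monomer annotation: local-alignment search of a consensus
# library against a genome (both strands), identity/coverage filtering, and
# best-hit resolution of overlapping matches. The search engine is NCBI
# BLAST+ (blastn, -task blastn); the normative part of the contract is the
# post-filtering: percent identity and query (consensus) coverage thresholds,
# both defaulting to 70.

#' Satellite family
#'
#' A consensus monomer with optional named subunits. `subunits` is a data
#' frame with columns `name`, `offset` (0-based within the monomer) and
#' `length`; spans must lie within the monomer and not overlap.
#'
#' @param family_id non-empty family identifier.
#' @param consensus consensus monomer sequence (A/C/G/T).
#' @param subunits optional subunit table (see above).
#' @return An object of class `sat_family` with fields `family_id`,
#'   `consensus`, `monomer_length`, `subunits` and `at_fraction`.
#' @export
sat_family <- function(family_id, consensus, subunits = NULL) {
  stopifnot(nzchar(family_id), nzchar(consensus))
  consensus <- toupper(consensus)
  if (grepl("[^ACGT]", consensus)) {
    stop("family consensus must be over A/C/G/T: ", family_id)
  }
  L <- nchar(consensus)
  if (is.null(subunits)) {
    subunits <- data.frame(name = character(), offset = integer(),
                           length = integer(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("name", "offset", "length") %in% names(subunits)))
    if (any(subunits$offset < 0 | subunits$offset + subunits$length > L)) {
      stop("subunit span outside monomer: ", family_id)
    }
    o <- order(subunits$offset)
    subunits <- subunits[o, , drop = FALSE]
    if (nrow(subunits) > 1) {
      ends <- subunits$offset + subunits$length
      if (any(subunits$offset[-1] < ends[-nrow(subunits)])) {
        stop("overlapping subunit spans: ", family_id)
      }
    }
    rownames(subunits) <- NULL
  }
  at <- sum(strsplit(consensus, "")[[1]] %in% c("A", "T")) / L
  structure(list(family_id = family_id, consensus = consensus,
                 monomer_length = L, subunits = subunits,
                 at_fraction = at),
            class = "sat_family")
}

#' @export
print.sat_family <- function(x, ...) {
  cat(sprintf("<sat_family %s: %d bp, A+T %.1f%%, %d subunit(s)>\n",
              x$family_id, x$monomer_length, 100 * x$at_fraction,
              nrow(x$subunits)))
  invisible(x)
}

#' Read a consensus library
#'
#' Reads a FASTA file where each record id is a family id and returns a named
#' list of [sat_family()] objects.
#'
#' @param path FASTA path.
#' @export
read_family_library <- function(path) {
  seqs <- load_sequences(path)
  fams <- lapply(seq_along(seqs), function(i) {
    sat_family(names(seqs)[i], as.character(seqs[[i]]))
  })
  names(fams) <- names(seqs)
  fams
}

.family_lengths <- function(families) {
  stats::setNames(vapply(families, function(f) f$monomer_length, 0L),
                  vapply(families, function(f) f$family_id, ""))
}

.check_blast <- function() {
  for (tool in c("makeblastdb", "blastn")) {
    if (Sys.which(tool) == "") {
      stop("NCBI BLAST+ tool not found on PATH: ", tool)
    }
  }
}

.empty_hits <- function() {
  intervals(family_id = character(), percent_identity = numeric(),
            query_coverage = numeric(), score = numeric())
}

#' Search satellite monomers in a genome
#'
#' Runs a local-alignment search (blastn, word size 7, low-complexity
#' filtering off) of every family consensus against both strands of the
#' genome and keeps alignments passing the identity and consensus-coverage
#' thresholds, reported with genomic coordinates, strand relative to the
#' consensus, percent identity, query coverage (qcovhsp semantics: percent of
#' the consensus length aligned) and bit score.
#'
#' @param genome `DNAStringSet` or FASTA path.
#' @param families named list of [sat_family()] objects.
#' @param min_identity minimum percent identity, in (0, 100]. Default 70.
#' @param min_qcov minimum percent consensus coverage, in (0, 100].
#'   Default 70.
#' @return Interval data frame of hits with columns `family_id`,
#'   `percent_identity`, `query_coverage`, `score`, sorted genomically.
#' @export
search_monomers <- function(genome, families, min_identity = 70,
                            min_qcov = 70) {
  stopifnot(length(families) > 0,
            min_identity > 0, min_identity <= 100,
            min_qcov > 0, min_qcov <= 100)
  if (is.character(genome)) genome <- load_sequences(genome)
  short <- vapply(families, function(f) f$monomer_length < 20, TRUE)
  if (any(short)) {
    stop("consensus shorter than 20 bp (seeding unreliable): ",
         paste(names(families)[short], collapse = ", "))
  }
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0) {
    return(.empty_hits())
  }
  .check_blast()
  wd <- tempfile("satarch_blast_")
  dir.create(wd)
  on.exit(unlink(wd, recursive = TRUE))
  db_fa <- file.path(wd, "genome.fa")
  q_fa <- file.path(wd, "families.fa")
  write_sequences(genome, db_fa)
  write_sequences(stats::setNames(
    vapply(families, function(f) f$consensus, ""),
    vapply(families, function(f) f$family_id, "")), q_fa)
  db <- file.path(wd, "db")
  out <- system2("makeblastdb",
                 c("-in", db_fa, "-dbtype", "nucl", "-out", db),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(out, "status"))) {
    stop("makeblastdb failed:\n", paste(out, collapse = "\n"))
  }
  res <- system2("blastn",
                 c("-task", "blastn", "-word_size", "7",
                   "-reward", "1", "-penalty", "-1",
                   "-gapopen", "2", "-gapextend", "1",
                   "-dust", "no", "-soft_masking", "false",
                   "-evalue", "1e-5", "-num_threads", "1",
                   "-query", q_fa, "-db", db,
                   "-outfmt",
                   shQuote(paste("6 qseqid sseqid pident qcovhsp bitscore",
                                 "sstart send qstart qend qlen"))),
                 stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(res, "status"))) {
    stop("blastn failed:\n", paste(res, collapse = "\n"))
  }
  res <- res[nzchar(res) & !grepl("^Warning", res)]
  if (length(res) == 0) return(.empty_hits())
  f <- do.call(rbind, strsplit(res, "\t", fixed = TRUE))
  sstart <- as.integer(f[, 6])
  send <- as.integer(f[, 7])
  minus <- sstart > send
  start <- ifelse(minus, send, sstart) - 1L
  end <- ifelse(minus, sstart, send)
  # reconstruct the full monomer extent when the local alignment clipped a
  # short consensus terminus (e.g. inside a diverged boundary variant): a
  # terminus of at most `max_clip` unaligned consensus bases is
  # extrapolated onto the genome; larger truncations are genuine partial
  # copies and keep their alignment bounds
  max_clip <- 25L
  qstart <- as.integer(f[, 8])
  qend <- as.integer(f[, 9])
  qlen <- as.integer(f[, 10])
  head_miss <- qstart - 1L
  tail_miss <- qlen - qend
  left_miss <- ifelse(minus, tail_miss, head_miss)
  right_miss <- ifelse(minus, head_miss, tail_miss)
  ctg_len <- Biostrings::width(genome)[match(f[, 2], names(genome))]
  start <- ifelse(left_miss <= max_clip,
                  pmax(0L, start - left_miss), start)
  end <- ifelse(right_miss <= max_clip,
                pmin(ctg_len, end + right_miss), end)
  hits <- intervals(contig = f[, 2],
                    start = start,
                    end = end,
                    strand = ifelse(minus, "-", "+"),
                    family_id = f[, 1],
                    percent_identity = as.numeric(f[, 3]),
                    query_coverage = as.numeric(f[, 4]),
                    score = as.numeric(f[, 5]))
  hits <- hits[hits$percent_identity >= min_identity &
                 hits$query_coverage >= min_qcov, , drop = FALSE]
  sort_intervals(hits)
}

#' Resolve overlapping monomer hits
#'
#' Greedy best-hit retention: hits are visited by descending score (ties:
#' higher identity, then leftmost start, then `+` strand) and accepted iff
#' the overlap with every already-accepted hit is at most
#' `max_overlap_fraction` of the shorter of the two. This keeps the
#' best-scoring hit at a genomic location while forbidding nested and heavily
#' overlapping calls, across families.
#'
#' @param hits hit table from [search_monomers()].
#' @param max_overlap_fraction tolerated overlap as a fraction of the shorter
#'   hit. Default 0.1.
#' @return The accepted hits, sorted genomically.
#' @export
resolve_overlaps <- function(hits, max_overlap_fraction = 0.1) {
  validate_intervals(hits)
  if (nrow(hits) <= 1) return(hits)
  out <- lapply(split(seq_len(nrow(hits)), hits$contig), function(idx) {
    h <- hits[idx, , drop = FALSE]
    n <- nrow(h)
    ir <- .as_iranges(h)
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    keep_pair <- qh != sh
    nb <- split(sh[keep_pair], factor(qh[keep_pair], levels = seq_len(n)))
    w <- h$end - h$start
    ord <- order(-h$score, -h$percent_identity, h$start,
                 match(h$strand, .STRAND_LEVELS))
    accepted <- logical(n)
    for (i in ord) {
      js <- nb[[i]]
      js <- js[accepted[js]]
      ok <- TRUE
      if (length(js) > 0) {
        ov_bp <- pmin(h$end[i], h$end[js]) - pmax(h$start[i], h$start[js])
        lim <- max_overlap_fraction * pmin(w[i], w[js])
        ok <- all(ov_bp <= lim)
      }
      accepted[i] <- ok
    }
    idx[accepted]
  })
  sort_intervals(hits[sort(unlist(out, use.names = FALSE)), , drop = FALSE])
}

#' Summarize an annotation
#'
#' Per-family copy counts, annotated bp and genome fraction, plus
#' assembly-wide totals.
#'
#' @param hits resolved hit table.
#' @param genome `DNAStringSet` the hits were called on.
#' @return List of class `annotation_summary` with `per_family` (data frame:
#'   `family_id`, `copy_count`, `total_bp`, `genome_fraction` in percent),
#'   `assembly_bp`, `annotated_bp` and `annotated_fraction`.
#' @export
summarize_annotation <- function(hits, genome) {
  assembly_bp <- sum(as.numeric(Biostrings::width(genome)))
  if (nrow(hits) == 0) {
    per <- data.frame(family_id = character(), copy_count = integer(),
                      total_bp = numeric(), genome_fraction = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    w <- hits$end - hits$start
    agg <- stats::aggregate(w, by = list(family_id = hits$family_id), FUN = sum)
    cnt <- table(hits$family_id)
    per <- data.frame(family_id = agg$family_id,
                      copy_count = as.integer(cnt[agg$family_id]),
                      total_bp = as.numeric(agg$x),
                      genome_fraction = 100 * agg$x / assembly_bp,
                      stringsAsFactors = FALSE)
    per <- per[order(per$family_id), , drop = FALSE]
    rownames(per) <- NULL
  }
  structure(list(per_family = per,
                 assembly_bp = assembly_bp,
                 annotated_bp = sum(per$total_bp),
                 annotated_fraction = 100 * sum(per$total_bp) / assembly_bp),
            class = "annotation_summary")
}

#' @export
print.annotation_summary <- function(x, ...) {
  cat(sprintf("<annotation_summary: %.0f bp assembly, %.2f%% annotated>\n",
              x$assembly_bp, x$annotated_fraction))
  print(x$per_family)
  invisible(x)
}
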