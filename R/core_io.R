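# Coordinate convention used throughout: 0-based half-open [start, end) on
# the forward strand of a contig. GFF3 is written 1-based inclusive, BED
# 0-based half-open. Strand is one of "+", "-", "." and sorts "+" < "-" < ".".

.STRAND_LEVELS <- c("+", "-", ".")

#' Construct an interval table
#'
#' Creates the plain data frame representation of genomic intervals used by
#' every module: columns `contig`, `start`, `end` (0-based half-open) and
#' `strand`.
#'
#' @param contig character vector of contig ids.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand character vector over `+`, `-`, `.` (recycled).
#' @param ... further columns to attach (recycled by `data.frame`).
#' @return A data frame with at least the four interval columns.
#' @export
intervals <- function(contig = character(), start = integer(),
                      end = integer(), strand = ".", ...) {
  n <- length(start)
  df <- data.frame(contig = rep_len(as.character(contig), n),
                   start = as.integer(start),
                   end = rep_len(as.integer(end), n),
                   strand = rep_len(as.character(strand), n),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

#' @rdname intervals
#' @param iv an interval data frame.
#' @export
validate_intervals <- function(iv) {
  stopifnot(is.data.frame(iv),
            all(c("contig", "start", "end", "strand") %in% names(iv)))
  if (nrow(iv) == 0) return(invisible(iv))
  if (any(iv$start < 0)) stop("interval start must be >= 0")
  if (any(iv$end <= iv$start)) stop("interval end must be > start")
  if (!all(iv$strand %in% .STRAND_LEVELS)) stop("strand must be +, - or .")
  invisible(iv)
}

# Deterministic sort: contig, start, end, strand ("+" < "-" < ".").
sort_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  o <- order(iv$contig, iv$start, iv$end,
             match(iv$strand, .STRAND_LEVELS))
  r <- iv[o, , drop = FALSE]
  rownames(r) <- NULL
  r
}

# IRanges view of one contig's intervals (1-based closed internally).
.as_iranges <- function(iv) {
  IRanges::IRanges(start = iv$start + 1L, end = iv$end)
}

#' Load genome or consensus sequences from FASTA
#'
#' Reads a FASTA file into a [Biostrings::DNAStringSet]. Sequences are
#' uppercased; any residue outside A, C, G, T, N is replaced with N and the
#' total replacement count is reported as a warning. Record ids are the first
#' whitespace-delimited token of each header and must be unique.
#'
#' @param path path to a FASTA file.
#' @return A named `DNAStringSet`, one element per record, input order kept.
#' @export
load_sequences <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(ids == "")) stop("FASTA record with empty id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate contig ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  x <- toupper(as.character(seqs))
  n_bad <- sum(nchar(x) - nchar(gsub("[^ACGTN]", "", x)))
  if (n_bad > 0) {
    warning(n_bad, " non-ACGTN residue(s) replaced with N")
    x <- gsub("[^ACGTN]", "N", x)
  }
  out <- Biostrings::DNAStringSet(x)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a named `DNAStringSet` or named character vector.
#' @param path output path.
#' @export
write_sequences <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

# Reverse complement of plain character vectors.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Extract [start, end) from a genome (DNAStringSet); "-" returns the reverse
# complement of the region.
seq_extract <- function(genome, contig, start, end, strand = "+") {
  s <- as.character(Biostrings::subseq(genome[[contig]],
                                       start = start + 1L, end = end))
  if (strand == "-") s <- revcomp(s) else s
}

#' Merge intervals under a gap bound
#'
#' Single-linkage merge per contig, strand ignored: two intervals join iff the
#' gap between them, `max(0, later.start - earlier.end)`, is at most
#' `max_gap`. The result is sorted and pairwise separated by more than
#' `max_gap`.
#'
#' @param iv interval data frame.
#' @param max_gap non-negative integer gap bound in bp.
#' @return Interval data frame (strand `.`) with a list column `members`
#'   giving, per merged interval, the row indices of `iv` it absorbed.
#' @export
interval_merge <- function(iv, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  validate_intervals(iv)
  if (nrow(iv) == 0) {
    return(intervals())
  }
  pieces <- lapply(split(seq_len(nrow(iv)), iv$contig), function(idx) {
    ir <- .as_iranges(iv[idx, , drop = FALSE])
    red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L,
                           with.revmap = TRUE)
    data.frame(contig = iv$contig[idx[1]],
               start = IRanges::start(red) - 1L,
               end = IRanges::end(red),
               strand = ".",
               members = I(lapply(S4Vectors_mcols_revmap(red), function(m) idx[m])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# mcols(red)$revmap as a plain list (kept out of the IRanges namespace churn).
S4Vectors_mcols_revmap <- function(red) {
  as.list(S4Vectors::mcols(red)$revmap)
}

#' Subtract mask intervals from a set of intervals
#'
#' Each item is replaced by its sub-segments that do not overlap any mask
#' interval; zero-length remnants are dropped. Items are processed
#' independently, so overlapping items yield overlapping remnants.
#'
#' @param iv interval data frame (items).
#' @param mask interval data frame (mask).
#' @return Interval data frame of remnants with a column `source` giving the
#'   row index of the originating item.
#' @export
interval_subtract <- function(iv, mask) {
  validate_intervals(iv)
  validate_intervals(mask)
  if (nrow(iv) == 0) return(cbind(intervals(), source = integer()))
  if (nrow(mask) == 0) {
    out <- iv[, c("contig", "start", "end", "strand")]
    out$source <- seq_len(nrow(iv))
    return(sort_intervals(out))
  }
  res <- vector("list", nrow(iv))
  mask_by_ctg <- split(mask, mask$contig)
  for (i in seq_len(nrow(iv))) {
    ctg <- iv$contig[i]
    m <- mask_by_ctg[[ctg]]
    if (is.null(m)) {
      res[[i]] <- data.frame(contig = ctg, start = iv$start[i],
                             end = iv$end[i], strand = iv$strand[i],
                             source = i, stringsAsFactors = FALSE)
      next
    }
    keep <- IRanges::setdiff(
      IRanges::IRanges(iv$start[i] + 1L, iv$end[i]),
      IRanges::reduce(.as_iranges(m)))
    if (length(keep) == 0) {
      res[[i]] <- NULL
    } else {
      res[[i]] <- data.frame(contig = ctg,
                             start = IRanges::start(keep) - 1L,
                             end = IRanges::end(keep),
                             strand = iv$strand[i],
                             source = i, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(cbind(intervals(), source = integer()))
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Gap distance between [a_start, a_end) and [b_start, b_end): 0 when they
# overlap or abut... strictly, abutting intervals have gap 0 as well.
.gap_distance <- function(a_start, a_end, b_start, b_end) {
  pmax(0L, pmax(b_start - a_end, a_start - b_end))
}

#' Nearest target interval
#'
#' Returns the target minimizing the gap distance (0 if overlapping) on the
#' query's contig; ties are broken by leftmost target start, then smallest
#' end.
#'
#' @param query a one-row interval data frame.
#' @param targets interval data frame, non-empty.
#' @return A list with `target` (one-row data frame of `targets`, or `NULL`
#'   when no target shares the query's contig), `distance` (integer bp or
#'   `NA`), and `index` (row index into `targets`).
#' @export
interval_nearest <- function(query, targets) {
  stopifnot(nrow(query) == 1, nrow(targets) > 0)
  on_ctg <- which(targets$contig == query$contig)
  if (length(on_ctg) == 0) {
    return(list(target = NULL, distance = NA_integer_, index = NA_integer_))
  }
  d <- .gap_distance(query$start, query$end,
                     targets$start[on_ctg], targets$end[on_ctg])
  o <- order(d, targets$start[on_ctg], targets$end[on_ctg])
  best <- on_ctg[o[1]]
  list(target = targets[best, , drop = FALSE],
       distance = as.integer(d[o[1]]),
       index = best)
}

# GFF3 attribute escaping (minimal percent-encoding of reserved characters).
.gff3_escape <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub(";", "%3B", x, fixed = TRUE)
  x <- gsub("=", "%3D", x, fixed = TRUE)
  x <- gsub(",", "%2C", x, fixed = TRUE)
  gsub("\t", "%09", x, fixed = TRUE)
}

.gff3_unescape <- function(x) {
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%2C", ",", x, fixed = TRUE)
  x <- gsub("%3D", "=", x, fixed = TRUE)
  x <- gsub("%3B", ";", x, fixed = TRUE)
  gsub("%25", "%", x, fixed = TRUE)
}

#' Write features as GFF3
#'
#' `features` must carry the interval columns plus `type`; every further
#' column is emitted as a `key=value` attribute (values coerced to character,
#' reserved characters percent-encoded). Coordinates are converted to the
#' 1-based inclusive GFF3 dialect on write. Zero-length anchors (e.g.
#' inversion points) are not representable; the narrowest feature is 1 bp.
#'
#' @param features data frame with `contig`, `start`, `end`, `strand`,
#'   `type` and attribute columns.
#' @param path output path.
#' @param source value of the GFF3 source column.
#' @export
write_gff3 <- function(features, path, source = "satarch") {
  validate_intervals(features)
  stopifnot("type" %in% names(features))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features) == 0) return(invisible(path))
  attr_cols <- setdiff(names(features),
                       c("contig", "start", "end", "strand", "type"))
  attrs <- rep(".", nrow(features))
  if (length(attr_cols) > 0) {
    mat <- vapply(attr_cols, function(cn) {
      paste0(cn, "=", .gff3_escape(as.character(features[[cn]])))
    }, character(nrow(features)))
    if (nrow(features) == 1) mat <- matrix(mat, nrow = 1)
    attrs <- apply(mat, 1, paste, collapse = ";")
  }
  lines <- paste(features$contig, source, features$type,
                 features$start + 1L, features$end, ".",
                 features$strand, ".", attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path input path.
#' @return Data frame with interval columns, `type`, and one column per
#'   attribute key found in the file (character; `NA` where absent).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(cbind(intervals(), type = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  stopifnot(all(lengths(f) == 9))
  f <- do.call(rbind, f)
  out <- data.frame(contig = f[, 1],
                    start = as.integer(f[, 4]) - 1L,
                    end = as.integer(f[, 5]),
                    strand = f[, 7],
                    type = f[, 3],
                    stringsAsFactors = FALSE)
  pairs <- lapply(strsplit(f[, 9], ";", fixed = TRUE), function(kv) {
    kv <- kv[kv != "."]
    if (length(kv) == 0) return(character())
    m <- regmatches(kv, regexpr("=", kv), invert = TRUE)
    stats::setNames(.gff3_unescape(vapply(m, `[`, "", 2)),
                    vapply(m, `[`, "", 1))
  })
  keys <- unique(unlist(lapply(pairs, names)))
  for (k in keys) {
    out[[k]] <- vapply(pairs, function(p) {
      if (k %in% names(p)) p[[k]] else NA_character_
    }, character(1))
  }
  out
}

#' Write intervals as BED6
#'
#' @param iv interval data frame; optional columns `name` and `score`.
#' @param path output path.
#' @export
write_bed <- function(iv, path) {
  validate_intervals(iv)
  name <- if ("name" %in% names(iv)) as.character(iv$name) else rep(".", nrow(iv))
  score <- if ("score" %in% names(iv)) as.character(iv$score) else rep("0", nrow(iv))
  lines <- paste(iv$contig, iv$start, iv$end, name, score,
                 ifelse(iv$strand == ".", ".", iv$strand), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(cbind(intervals(), name = character(), score = character()))
  }
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  data.frame(contig = f[, 1], start = as.integer(f[, 2]),
             end = as.integer(f[, 3]), strand = f[, 6],
             name = f[, 4], score = f[, 5], stringsAsFactors = FALSE)
}

#' Tab-separated table helpers
#'
#' Thin wrappers writing/reading TSV with a header row and no quoting, the
#' dialect used for every statistics table the pipeline emits.
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  # list columns (e.g. merge member maps) are not meaningful in TSV exports
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
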