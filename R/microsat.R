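# Perfect dinucleotide microsatellite runs and their satellite linkage.
# A run is defined phase-agnostically: the maximal substring that is a
# repetition of the motif or its rotation (no mismatches); units =
# floor(length / 2), and the reported interval is trimmed to 2 * units bp
# from the run start so that interval length always equals 2 * units.

#' Find perfect dinucleotide runs
#'
#' Scans every contig for maximal exact tandem runs of a two-base motif (or
#' its rotation) with at least `min_units` motif copies and no mismatches.
#'
#' @param genome `DNAStringSet` or plain named character vector.
#' @param motif 2-mer with two distinct bases. Default `"AC"`.
#' @param min_units minimum number of motif units. Default 5.
#' @return Interval data frame with columns `motif` and `units`.
#' @export
find_dinuc_runs <- function(genome, motif = "AC", min_units = 5L) {
  motif <- toupper(motif)
  if (nchar(motif) != 2 || grepl("[^ACGT]", motif)) {
    stop("motif must be a 2-mer over A/C/G/T")
  }
  m1 <- substr(motif, 1, 1)
  m2 <- substr(motif, 2, 2)
  if (m1 == m2) stop("homopolymer motif rejected: ", motif)
  if (!is.character(genome)) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  out <- list()
  for (ctg in names(genome)) {
    ch <- strsplit(genome[[ctg]], "")[[1]]
    n <- length(ch)
    if (n < 2L * min_units) next
    # ok[i]: the pair (i, i+1) is motif or its rotation
    ok <- (ch[-n] == m1 & ch[-1] == m2) | (ch[-n] == m2 & ch[-1] == m1)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (j in runs) {
      len <- r$lengths[j] + 1L            # alternating stretch length in bp
      units <- len %/% 2L
      if (units < min_units) next
      s0 <- starts[j] - 1L                # 0-based start of the stretch
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = s0, end = s0 + 2L * units, strand = ".",
        motif = motif, units = units, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(intervals(motif = character(), units = integer()))
  }
  sort_intervals(res)
}

#' Link microsatellite runs to a satellite family
#'
#' Run intervals are first trimmed by [interval_subtract()] against the
#' family's monomer annotations (isolating microsatellite sequence
#' independent of the monomers, whose termini may themselves carry motif
#' tracts); surviving remnants within `max_gap` bp of a family monomer are
#' labeled linked, the rest unlinked.
#'
#' @param runs run table from [find_dinuc_runs()].
#' @param satellite_hits resolved monomer hit table.
#' @param family_id family whose monomers define the linkage.
#' @param max_gap maximum gap for linkage in bp. Default 100.
#' @return Interval data frame of surviving runs with `motif`, `units`
#'   (recomputed from the trimmed width), `linked_family` (family id or
#'   `NA`) and `link_distance` (bp or `NA`).
#' @export
link_runs <- function(runs, satellite_hits, family_id, max_gap = 100L) {
  validate_intervals(runs)
  mask <- satellite_hits[satellite_hits$family_id == family_id, ,
                         drop = FALSE]
  trimmed <- interval_subtract(runs, mask)
  if (nrow(trimmed) == 0) {
    return(intervals(motif = character(), units = integer(),
                     linked_family = character(),
                     link_distance = integer()))
  }
  trimmed$motif <- runs$motif[trimmed$source]
  trimmed$units <- (trimmed$end - trimmed$start) %/% 2L
  trimmed$linked_family <- NA_character_
  trimmed$link_distance <- NA_integer_
  if (nrow(mask) > 0) {
    for (i in seq_len(nrow(trimmed))) {
      nn <- interval_nearest(trimmed[i, , drop = FALSE], mask)
      if (!is.null(nn$target) && nn$distance <= max_gap) {
        trimmed$linked_family[i] <- family_id
        trimmed$link_distance[i] <- nn$distance
      }
    }
  }
  trimmed$source <- NULL
  sort_intervals(trimmed)
}

#' Linkage statistics for annotated runs
#'
#' @param runs annotated run table from [link_runs()].
#' @return List with `summary` (per class: count, total bp, median length)
#'   and `linked_bp_fraction` (percent of total microsatellite bp in the
#'   linked class).
#' @export
linkage_stats <- function(runs) {
  linked <- !is.na(runs$linked_family)
  w <- runs$end - runs$start
  cls <- function(sel) {
    data.frame(n = sum(sel), total_bp = sum(w[sel]),
               median_length = if (any(sel)) stats::median(w[sel]) else NA_real_)
  }
  summary <- cbind(class = c("linked", "unlinked"),
                   rbind(cls(linked), cls(!linked)))
  total <- sum(w)
  list(summary = summary,
       linked_bp_fraction = if (total > 0) 100 * sum(w[linked]) / total
       else NA_real_,
       linked_run_fraction = if (nrow(runs) > 0) 100 * mean(linked)
       else NA_real_)
}
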