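# Array reconstruction: resolved monomer hits of one family are grouped into
# arrays by single-linkage merging with a gap bound of one monomer length --
# the fixed point of iteratively expanding each annotation by up to one
# monomer length and absorbing newly covered monomers. Strand is ignored at
# this tier ("strand-agnostic" arrays); orientation structure is recovered
# later by the symmetry module.

#' Build satellite arrays from monomer hits
#'
#' @param hits resolved hit table ([resolve_overlaps()]); must carry
#'   `family_id`.
#' @param families named list of [sat_family()] objects covering every
#'   family in `hits`; the per-family gap bound is that family's
#'   `monomer_length`.
#' @return List of class `sat_arrays` with
#'   \describe{
#'     \item{arrays}{data frame `array_id`, `family_id`, `contig`, `start`,
#'       `end`, `strand` (`.`), `monomer_count`}
#'     \item{hits}{the input hits with an `array_id` column}
#'   }
#' @export
build_arrays <- function(hits, families) {
  validate_intervals(hits)
  fam_len <- .family_lengths(families)
  unknown <- setdiff(unique(hits$family_id), names(fam_len))
  if (length(unknown) > 0) {
    stop("hit references unknown family: ", paste(unknown, collapse = ", "))
  }
  hits <- sort_intervals(hits)
  hits$array_id <- NA_character_
  rows <- list()
  serial <- 0L
  for (fam in intersect(names(fam_len), unique(hits$family_id))) {
    idx <- which(hits$family_id == fam)
    merged <- interval_merge(hits[idx, , drop = FALSE],
                             max_gap = fam_len[[fam]])
    ids <- sprintf("%s_arr%05d", fam, serial + seq_len(nrow(merged)))
    serial <- serial + nrow(merged)
    for (j in seq_len(nrow(merged))) {
      hits$array_id[idx[merged$members[[j]]]] <- ids[j]
    }
    rows[[fam]] <- data.frame(array_id = ids,
                              family_id = fam,
                              contig = merged$contig,
                              start = merged$start,
                              end = merged$end,
                              strand = ".",
                              monomer_count = lengths(merged$members),
                              stringsAsFactors = FALSE)
  }
  arrays <- do.call(rbind, unname(rows))
  if (is.null(arrays)) {
    arrays <- data.frame(array_id = character(), family_id = character(),
                         contig = character(), start = integer(),
                         end = integer(), strand = character(),
                         monomer_count = integer(), stringsAsFactors = FALSE)
  } else {
    arrays <- sort_intervals(arrays)
  }
  structure(list(arrays = arrays, hits = hits), class = "sat_arrays")
}

#' Classify a family as a satellite
#'
#' A family qualifies as a satellite when at least one of its arrays contains
#' `min_tandem` or more tandemized monomers (default 5).
#'
#' @param family_id family to test.
#' @param arrays `sat_arrays` object or its `arrays` data frame.
#' @param min_tandem minimum tandem copy number. Default 5.
#' @return `TRUE` or `FALSE`.
#' @export
classify_satellite <- function(family_id, arrays, min_tandem = 5L) {
  a <- if (inherits(arrays, "sat_arrays")) arrays$arrays else arrays
  any(a$family_id == family_id & a$monomer_count >= min_tandem)
}

#' Array length and copy-number statistics
#'
#' Per family: the list of array lengths, their median and maximum, a
#' monomer-count histogram, and a Gaussian-kernel density estimate of the
#' length distribution (Scott's rule bandwidth; visualization only).
#'
#' @param arrays `sat_arrays` object or its `arrays` data frame.
#' @return List of class `array_stats` with `summary` (data frame
#'   `family_id`, `n_arrays`, `median_length`, `max_length`), `lengths`
#'   (named list of numeric vectors), `monomer_histogram` (named list of
#'   tables) and `kde` (named list of data frames `grid`, `density`; `NULL`
#'   for families with fewer than 2 arrays).
#' @export
array_stats <- function(arrays) {
  a <- if (inherits(arrays, "sat_arrays")) arrays$arrays else arrays
  fams <- sort(unique(a$family_id))
  lengths_by <- lapply(fams, function(f) {
    x <- a[a$family_id == f, ]
    as.numeric(x$end - x$start)
  })
  names(lengths_by) <- fams
  hist_by <- lapply(fams, function(f) table(a$monomer_count[a$family_id == f]))
  names(hist_by) <- fams
  kde_by <- lapply(lengths_by, function(x) {
    if (length(x) < 2 || stats::sd(x) == 0) return(NULL)
    d <- stats::density(x, bw = stats::bw.nrd(x))
    data.frame(grid = d$x, density = d$y)
  })
  summary <- data.frame(family_id = fams,
                        n_arrays = vapply(lengths_by, length, 0L),
                        median_length = vapply(lengths_by, stats::median, 0),
                        max_length = vapply(lengths_by, function(x)
                          if (length(x)) max(x) else NA_real_, 0),
                        stringsAsFactors = FALSE)
  rownames(summary) <- NULL
  structure(list(summary = summary, lengths = lengths_by,
                 monomer_histogram = hist_by, kde = kde_by),
            class = "array_stats")
}

#' @export
print.array_stats <- function(x, ...) {
  print(x$summary)
  invisible(x)
}
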