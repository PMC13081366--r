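# Inter-family junction grammar: adjacencies between arrays of two
# families, k-mer based array-edge refinement, junction extraction and
# clustering into transition types, chimeric breakpoint characterization
# (duplicated motif, internal deletion), the cassette census, and
# flank/proximity analyses.

#' Find adjacencies between arrays of two families
#'
#' All ordered neighbor pairs (left array, right array) of distinct
#' families on a contig with gap at most `max_gap` and no intervening array
#' of either family. Neighborship is evaluated on the combined,
#' position-sorted array list of the two families.
#'
#' @param arrays `sat_arrays` object or its `arrays` data frame.
#' @param family_a,family_b the two family ids.
#' @param max_gap maximum gap in bp. Default 1000.
#' @return Data frame `contig`, `left_array_id`, `right_array_id`,
#'   `left_family`, `right_family`, `left_end`, `right_start`, `gap`.
#' @export
find_adjacencies <- function(arrays, family_a, family_b, max_gap = 1000L) {
  a <- if (inherits(arrays, "sat_arrays")) arrays$arrays else arrays
  if (!family_a %in% a$family_id) stop("unknown family: ", family_a)
  if (!family_b %in% a$family_id) stop("unknown family: ", family_b)
  stopifnot(family_a != family_b)
  a <- a[a$family_id %in% c(family_a, family_b), , drop = FALSE]
  out <- list()
  for (ctg in unique(a$contig)) {
    x <- a[a$contig == ctg, , drop = FALSE]
    x <- x[order(x$start, x$end), , drop = FALSE]
    if (nrow(x) < 2) next
    li <- seq_len(nrow(x) - 1)
    gap <- pmax(0L, x$start[li + 1] - x$end[li])
    keep <- x$family_id[li] != x$family_id[li + 1] & gap <= max_gap
    if (!any(keep)) next
    out[[ctg]] <- data.frame(contig = ctg,
                             left_array_id = x$array_id[li][keep],
                             right_array_id = x$array_id[li + 1][keep],
                             left_family = x$family_id[li][keep],
                             right_family = x$family_id[li + 1][keep],
                             left_end = x$end[li][keep],
                             right_start = x$start[li + 1][keep],
                             gap = as.integer(gap[keep]),
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, unname(out))
  if (is.null(res)) {
    res <- data.frame(contig = character(), left_array_id = character(),
                      right_array_id = character(), left_family = character(),
                      right_family = character(), left_end = integer(),
                      right_start = integer(), gap = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Refine an array edge by k-mer composition
#'
#' Monotone outward scan from the array edge in 1-bp steps. At candidate
#' boundary `b` the trailing window of `4k` bp on the array side of `b` is
#' decomposed into k-mers; the boundary is advanced while the fraction of
#' window k-mers present in the family consensus k-mer set (both strands)
#' stays at or above `threshold`, and the last satisfying position is
#' returned. Scans are truncated at contig ends.
#'
#' @param genome `DNAStringSet`.
#' @param array one-row array data frame (or list) with `contig`, `start`,
#'   `end`.
#' @param family [sat_family()] whose consensus defines the k-mer set.
#' @param side which edge to refine: `"right"` scans toward larger
#'   coordinates from `end`, `"left"` toward smaller coordinates from
#'   `start`.
#' @param k k-mer size. Default 12.
#' @param threshold minimum in-set k-mer fraction. Default 0.5.
#' @param max_scan scan cap in bp. Default 5000.
#' @return The refined boundary position (0-based; an end-exclusive
#'   coordinate for the right edge, a start coordinate for the left edge).
#' @export
refine_edge <- function(genome, array, family, side = c("right", "left"),
                        k = 12L, threshold = 0.5, max_scan = 5000L) {
  side <- match.arg(side)
  stopifnot(array$monomer_count >= 1 || !is.null(array$start))
  ctg <- as.character(array$contig)
  clen <- Biostrings::width(genome)[match(ctg, names(genome))]
  win <- 4L * k
  # monomers occur in tandem, so the consensus is treated as circular:
  # junction-crossing k-mers belong to the family signature too
  kset <- kmerize(paste0(family$consensus,
                         substr(family$consensus, 1, k - 1L)),
                  k = k)$kmers
  s <- as.character(genome[[ctg]])
  window_kmers <- function(lo, hi) {
    # in-set flags of the k-mers in window [lo, hi), 0-based, clipped
    lo <- max(0L, lo); hi <- min(clen, hi)
    if (hi - lo < k) return(NULL)
    starts <- lo:(hi - k)
    list(starts = starts,
         inset = substring(s, starts + 1L, starts + k) %in% kset)
  }
  frac_ok <- function(lo, hi) {
    wk <- window_kmers(lo, hi)
    !is.null(wk) && mean(wk$inset) >= threshold
  }
  if (side == "right") {
    b <- as.integer(array$end)
    last_good <- b
    lim <- min(clen, array$end + max_scan)
    while (b < lim && frac_ok(b + 1L - win, b + 1L)) b <- b + 1L
    last_good <- b
    # refined edge: end of the outermost in-set k-mer of the last window
    wk <- window_kmers(last_good - win, last_good)
    if (!is.null(wk) && any(wk$inset)) {
      return(max(wk$starts[wk$inset]) + k)
    }
    last_good
  } else {
    b <- as.integer(array$start)
    lim <- max(0L, array$start - max_scan)
    while (b > lim && frac_ok(b - 1L, b - 1L + win)) b <- b - 1L
    last_good <- b
    wk <- window_kmers(last_good, last_good + win)
    if (!is.null(wk) && any(wk$inset)) {
      return(min(wk$starts[wk$inset]))
    }
    last_good
  }
}

#' Extract junction sequences for adjacencies
#'
#' For each adjacency the forward-strand sequence from `left_end - pad` to
#' `right_start + pad`. The pad is clipped to the flanking array's own
#' extent and to the contig; clipped junctions are flagged.
#'
#' @param genome `DNAStringSet`.
#' @param adjacencies data frame from [find_adjacencies()].
#' @param arrays `sat_arrays` object or its `arrays` data frame (for pad
#'   clipping).
#' @param pad bp of flanking array included on each side. Default 250.
#' @return `adjacencies` with columns `junction_start`, `junction_end`,
#'   `truncated`, `sequence` (the padded window) and `core` (the
#'   inter-array portion of the window, i.e. the transition element proper;
#'   empty for abutting arrays) appended.
#' @export
extract_junctions <- function(genome, adjacencies, arrays, pad = 250L) {
  a <- if (inherits(arrays, "sat_arrays")) arrays$arrays else arrays
  if (nrow(adjacencies) == 0) {
    adjacencies$junction_start <- integer()
    adjacencies$junction_end <- integer()
    adjacencies$truncated <- logical()
    adjacencies$sequence <- character()
    adjacencies$core <- character()
    return(adjacencies)
  }
  left <- a[match(adjacencies$left_array_id, a$array_id), ]
  right <- a[match(adjacencies$right_array_id, a$array_id), ]
  ctg_len <- Biostrings::width(genome)[match(adjacencies$contig,
                                             names(genome))]
  js <- pmax(adjacencies$left_end - pad, left$start, 0L)
  je <- pmin(adjacencies$right_start + pad, right$end, ctg_len)
  adjacencies$junction_start <- as.integer(js)
  adjacencies$junction_end <- as.integer(je)
  adjacencies$truncated <- js > adjacencies$left_end - pad |
    je < adjacencies$right_start + pad
  adjacencies$sequence <- vapply(seq_len(nrow(adjacencies)), function(i) {
    seq_extract(genome, adjacencies$contig[i], js[i], je[i])
  }, "")
  adjacencies$core <- substr(adjacencies$sequence,
                             adjacencies$left_end - js + 1L,
                             adjacencies$right_start - js)
  adjacencies
}

#' Classify junction sequences into transition types
#'
#' Single-linkage identity clustering of junction sequences (same pinned
#' alignment scheme as [cluster_sites()]), with clusters ranked by size and
#' a majority-rule consensus per cluster. Above `max_exact` sequences a
#' seeded subsample is clustered exactly and the remaining junctions are
#' assigned to the best-matching cluster consensus (their own singleton
#' cluster when below the threshold), keeping the cost linear in n.
#'
#' @param junctions character vector of junction sequences (or a data frame
#'   with a `sequence` column).
#' @param identity_threshold percent identity joining threshold. Default 90.
#' @param max_exact largest n clustered all-vs-all. Default 80.
#' @param seed seed for the subsample draw. Default 1.
#' @return List with `clusters` (data frame `cluster_label`, `n`,
#'   `prevalence` in percent, `mean_pairwise_identity`, `minor`,
#'   `consensus`) and `assignments`.
#' @export
classify_transitions <- function(junctions, identity_threshold = 90,
                                 max_exact = 80L, seed = 1L) {
  seqs <- if (is.data.frame(junctions)) junctions$sequence else junctions
  stopifnot(length(seqs) >= 1)
  n <- length(seqs)
  if (n <= max_exact) {
    res <- identity_clusters(seqs, identity_threshold, prefix = "TRANS")
    assignments <- res$assignments
    clusters <- res$clusters
  } else {
    idx <- withr_seed(seed, sample.int(n, max_exact))
    core <- identity_clusters(seqs[idx], identity_threshold,
                              prefix = "TRANS")
    cons <- core$clusters$consensus
    assignments <- character(n)
    assignments[idx] <- core$assignments
    rest <- setdiff(seq_len(n), idx)
    if (length(rest) > 0) {
      idmat <- vapply(cons, function(cc) align_identity_many(seqs[rest], cc),
                      numeric(length(rest)))
      if (length(rest) == 1) idmat <- matrix(idmat, nrow = 1)
      best <- max.col(idmat, ties.method = "first")
      best_id <- idmat[cbind(seq_along(rest), best)]
      extra <- 0L
      for (r in seq_along(rest)) {
        if (best_id[r] >= identity_threshold) {
          assignments[rest[r]] <- core$clusters$cluster_label[best[r]]
        } else {
          extra <- extra + 1L
          assignments[rest[r]] <- sprintf("TRANS_extra_%d", extra)
        }
      }
    }
    counts <- table(assignments)
    clusters <- core$clusters
    clusters$n <- as.integer(counts[clusters$cluster_label])
    singles <- setdiff(names(counts), clusters$cluster_label)
    if (length(singles) > 0) {
      clusters <- rbind(clusters, data.frame(
        cluster_label = singles,
        n = as.integer(counts[singles]),
        mean_pairwise_identity = 100,
        minor = TRUE,
        consensus = seqs[match(singles, assignments)],
        stringsAsFactors = FALSE))
    }
    clusters <- clusters[order(-clusters$n), , drop = FALSE]
    rownames(clusters) <- NULL
  }
  clusters$prevalence <- 100 * clusters$n / n
  clusters <- clusters[, c("cluster_label", "n", "prevalence",
                           "mean_pairwise_identity", "minor", "consensus")]
  list(clusters = clusters, assignments = assignments)
}

# Evaluate an expression under a local, restored RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Donor-relative deletion length of a junction segment: local anchor
# against the donor, then a second local anchor of the remainders; the
# deletion is the donor bases skipped between the two anchors (net of
# junction bases skipped). Returns 0 when no second anchor exists.
.donor_deletion <- function(seq, donor, min_anchor = 8) {
  a1 <- .align(seq, donor, type = "local")
  if (Biostrings::score(a1) < min_anchor) return(0L)
  je <- IRanges::end(Biostrings::pattern(a1))
  de <- IRanges::end(Biostrings::subject(a1))
  gap_in_a1 <- Biostrings::deletion(a1)[[1]]
  best <- if (length(gap_in_a1) == 0) 0L else max(IRanges::width(gap_in_a1))
  rest_j <- substr(seq, je + 1L, nchar(seq))
  rest_d <- substr(donor, de + 1L, nchar(donor))
  if (nchar(rest_j) >= min_anchor && nchar(rest_d) > best) {
    a2 <- .align(rest_j, rest_d, type = "local")
    if (Biostrings::score(a2) >= min_anchor) {
      dgap <- IRanges::start(Biostrings::subject(a2)) - 1L
      jgap <- IRanges::start(Biostrings::pattern(a2)) - 1L
      best <- max(best, dgap - jgap)
    }
  }
  as.integer(max(best, 0L))
}

#' Characterize a chimeric junction breakpoint
#'
#' Finds the split of the junction maximizing the summed local-alignment
#' scores of the prefix against `consensus_a` and the suffix against
#' `consensus_b`; when a duplicated motif makes the split ambiguous (the
#' score is flat across it) the rightmost maximizing split is taken, so the
#' shared material is carried by the prefix. The duplicated motif is then
#' the longest exact string (3-30 bp) that terminates the aligned prefix
#' donor segment and immediately precedes the aligned suffix donor segment
#' in its own donor -- i.e. a string present at the breakpoint in both
#' donor contexts (empty if none; shorter than 3 bp is treated as
#' alignment-end noise). The internal deletion length is the donor
#' material skipped within the prefix relative to `consensus_a` (anchor
#' chaining; 0 if none).
#'
#' @param junction junction sequence.
#' @param consensus_a donor consensus for the prefix side.
#' @param consensus_b donor consensus for the suffix side.
#' @param min_score per-side local score floor below which the junction is
#'   reported as unclassified. Default 15.
#' @return List `breakpoint_offset`, `duplicated_motif`, `deletion_length`,
#'   `classified`, `score`.
#' @export
detect_chimeric_breakpoint <- function(junction, consensus_a, consensus_b,
                                       min_score = 15) {
  n <- nchar(junction)
  stopifnot(n >= 20)
  al_a <- .align(junction, consensus_a, type = "local")
  al_b <- .align(junction, consensus_b, type = "local")
  if (Biostrings::score(al_a) < min_score ||
      Biostrings::score(al_b) < min_score) {
    return(list(breakpoint_offset = NA_integer_, duplicated_motif = "",
                deletion_length = NA_integer_, classified = FALSE,
                score = Biostrings::score(al_a) + Biostrings::score(al_b)))
  }
  side_align <- function(s) {
    a <- .align(substr(junction, 1, s), consensus_a, type = "local")
    b <- .align(substr(junction, s + 1, n), consensus_b, type = "local")
    list(a = a, b = b,
         total = Biostrings::score(a) + Biostrings::score(b))
  }
  grid <- unique(pmin(pmax(seq(10L, n - 10L, by = 5L), 10L), n - 10L))
  sc <- vapply(grid, function(s) side_align(s)$total, 0)
  best <- grid[which.max(sc)]
  lo <- max(10L, best - 8L)
  hi <- min(n - 10L, best + 8L)
  fine <- lo:hi
  sc2 <- vapply(fine, function(s) side_align(s)$total, 0)
  # rightmost split of the plateau: shared material goes to the prefix
  s <- max(fine[sc2 >= max(sc2) - 1e-9])
  res <- side_align(s)
  qa2 <- IRanges::end(Biostrings::subject(res$a))
  qb1 <- IRanges::start(Biostrings::subject(res$b))
  # the motif terminating the prefix donor segment either begins the suffix
  # donor segment (motif present twice in the junction) or immediately
  # precedes it in its donor (one shared copy consumed by the prefix)
  dup <- ""
  for (m in 3:30) {
    if (qa2 - m + 1L < 1L) break
    tail_a <- substr(consensus_a, qa2 - m + 1L, qa2)
    hit <- (qb1 + m - 1L <= nchar(consensus_b) &&
              tail_a == substr(consensus_b, qb1, qb1 + m - 1L)) ||
      (qb1 - m >= 1L && tail_a == substr(consensus_b, qb1 - m, qb1 - 1L))
    if (hit) dup <- tail_a
  }
  deletion_length <- .donor_deletion(substr(junction, 1, s), consensus_a)
  list(breakpoint_offset = as.integer(s), duplicated_motif = dup,
       deletion_length = deletion_length, classified = TRUE,
       score = res$total)
}

#' Cassette census over minor-family arrays
#'
#' For each minor-family array: whether a junction of the first prevalent
#' transition type flanks it, whether one of the second type does, and
#' whether it contains at least one internal inversion point; plus the Venn
#' counts of the three booleans. The two prevalent types are the two largest
#' junction clusters (junctions labeled `TRANS_none`, i.e. abutting arrays
#' with no transition element, are excluded from the ranking), ordered by
#' decreasing median junction gap (the longer transition element first),
#' which makes the labels reproducible without reference sequences.
#'
#' @param minor_arrays data frame of the minor family's arrays.
#' @param junctions junction table from [extract_junctions()] with the
#'   cluster assignment appended as column `type_label`.
#' @param inversions inversion table from [decompose_subarrays()].
#' @return List of class `cassette_report`: `per_array` (booleans per
#'   array), `venn` (named counts `none`, `t1`, `t2`, `inv`, `t1_t2`,
#'   `t1_inv`, `t2_inv`, `t1_t2_inv`), `n_arrays`, `type_labels`.
#' @export
cassette_census <- function(minor_arrays, junctions, inversions) {
  stopifnot("type_label" %in% names(junctions))
  typed <- junctions$type_label != "TRANS_none"
  sizes <- sort(table(junctions$type_label[typed]), decreasing = TRUE)
  top <- names(sizes)[seq_len(min(2L, length(sizes)))]
  if (length(top) == 2) {
    med_gap <- vapply(top, function(lb) {
      stats::median(junctions$gap[junctions$type_label == lb])
    }, 0)
    top <- top[order(-med_gap)]
  }
  t1 <- top[1]
  t2 <- if (length(top) > 1) top[2] else NA_character_
  per <- data.frame(array_id = minor_arrays$array_id,
                    has_type1 = FALSE, has_type2 = FALSE,
                    has_inversion = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(per))) {
    aid <- per$array_id[i]
    j <- junctions[junctions$left_array_id == aid |
                     junctions$right_array_id == aid, , drop = FALSE]
    per$has_type1[i] <- any(j$type_label == t1)
    per$has_type2[i] <- !is.na(t2) && any(j$type_label == t2)
    per$has_inversion[i] <- any(inversions$array_id == aid)
  }
  venn <- c(
    none = sum(!per$has_type1 & !per$has_type2 & !per$has_inversion),
    t1 = sum(per$has_type1 & !per$has_type2 & !per$has_inversion),
    t2 = sum(!per$has_type1 & per$has_type2 & !per$has_inversion),
    inv = sum(!per$has_type1 & !per$has_type2 & per$has_inversion),
    t1_t2 = sum(per$has_type1 & per$has_type2 & !per$has_inversion),
    t1_inv = sum(per$has_type1 & !per$has_type2 & per$has_inversion),
    t2_inv = sum(!per$has_type1 & per$has_type2 & per$has_inversion),
    t1_t2_inv = sum(per$has_type1 & per$has_type2 & per$has_inversion))
  structure(list(per_array = per, venn = venn, n_arrays = nrow(per),
                 type_labels = c(type1 = t1, type2 = t2)),
            class = "cassette_report")
}

#' @export
print.cassette_report <- function(x, ...) {
  cat(sprintf("<cassette_report: %d arrays; triple rate %.1f%%>\n",
              x$n_arrays,
              100 * x$venn[["t1_t2_inv"]] / max(1L, x$n_arrays)))
  print(x$venn)
  invisible(x)
}

#' Pairwise similarity of array flanking regions
#'
#' Extracts `flank` bp upstream and downstream of each array (forward
#' strand) and computes the all-vs-all percent-identity matrix of the
#' extracted flanks under the pinned global alignment scheme.
#'
#' @param arrays data frame of arrays.
#' @param genome `DNAStringSet`.
#' @param flank flank length in bp. Default 2000.
#' @return List with `flanks` (data frame `label`, `array_id`, `side`,
#'   `start`, `end`, `truncated`, `sequence`) and `identity` (matrix with
#'   `label` dimnames).
#' @export
flank_similarity <- function(arrays, genome, flank = 2000L) {
  stopifnot(nrow(arrays) > 0)
  ctg_len <- Biostrings::width(genome)[match(arrays$contig, names(genome))]
  rows <- list()
  for (i in seq_len(nrow(arrays))) {
    us <- max(0L, arrays$start[i] - flank)
    de <- min(ctg_len[i], arrays$end[i] + flank)
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0(arrays$array_id[i], "_up"),
      array_id = arrays$array_id[i], side = "up",
      start = us, end = arrays$start[i],
      truncated = us > arrays$start[i] - flank,
      sequence = seq_extract(genome, arrays$contig[i], us, arrays$start[i]),
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      label = paste0(arrays$array_id[i], "_down"),
      array_id = arrays$array_id[i], side = "down",
      start = arrays$end[i], end = de,
      truncated = de < arrays$end[i] + flank,
      sequence = seq_extract(genome, arrays$contig[i], arrays$end[i], de),
      stringsAsFactors = FALSE)
  }
  flanks <- do.call(rbind, rows)
  keep <- nchar(flanks$sequence) > 0
  flanks <- flanks[keep, , drop = FALSE]
  m <- pairwise_identity_matrix(flanks$sequence)
  dimnames(m) <- list(flanks$label, flanks$label)
  list(flanks = flanks, identity = m)
}

#' Distance from each array of one family to the nearest array of another
#'
#' @param arrays_x,arrays_y array data frames (query and target families).
#' @return List with `table` (per x-array: nearest y `array_id`, gap
#'   `distance`; `NA` on contigs without y-arrays) and `median_distance`
#'   over the defined rows.
#' @export
nearest_family_distance <- function(arrays_x, arrays_y) {
  stopifnot(nrow(arrays_x) > 0, nrow(arrays_y) > 0)
  res <- data.frame(array_id = arrays_x$array_id,
                    nearest_id = NA_character_,
                    distance = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(arrays_x))) {
    nn <- interval_nearest(arrays_x[i, , drop = FALSE], arrays_y)
    if (!is.null(nn$target)) {
      res$nearest_id[i] <- nn$target$array_id
      res$distance[i] <- nn$distance
    }
  }
  list(table = res,
       median_distance = stats::median(res$distance, na.rm = TRUE))
}
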