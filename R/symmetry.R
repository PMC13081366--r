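# Oriented subarray decomposition and macro-dyad symmetry. Arrays built
# strand-agnostically are re-examined per strand: member monomers of each
# strand are merged with the same family gap rule, the resulting stranded
# blocks are intersected with the array span and ordered, giving an
# alternating-orientation block list. Each boundary between opposite-strand
# blocks is an inversion point (position = midpoint of the inter-block gap).

#' Decompose arrays into oriented subarrays and inversion points
#'
#' @param arrays a `sat_arrays` object from [build_arrays()].
#' @param families named list of [sat_family()] objects.
#' @return List with
#'   \describe{
#'     \item{subarrays}{data frame `array_id`, `family_id`, `contig`,
#'       `start`, `end`, `strand`, `monomer_count`, `block_index`}
#'     \item{inversions}{data frame `array_id`, `family_id`, `contig`,
#'       `position`, `left_strand`, `right_strand`}
#'   }
#' @export
decompose_subarrays <- function(arrays, families) {
  stopifnot(inherits(arrays, "sat_arrays"))
  fam_len <- .family_lengths(families)
  hits <- arrays$hits
  sub_rows <- list()
  inv_rows <- list()
  for (aid in arrays$arrays$array_id) {
    h <- hits[hits$array_id == aid, , drop = FALSE]
    if (nrow(h) == 0) stop("array with zero monomers: ", aid)
    fam <- h$family_id[1]
    arr <- arrays$arrays[arrays$arrays$array_id == aid, ]
    blocks <- list()
    for (st in c("+", "-")) {
      hs <- h[h$strand == st, , drop = FALSE]
      if (nrow(hs) == 0) next
      m <- interval_merge(hs, max_gap = fam_len[[fam]])
      m$strand <- st
      m$monomer_count <- lengths(m$members)
      blocks[[st]] <- m[, c("contig", "start", "end", "strand",
                            "monomer_count")]
    }
    b <- do.call(rbind, unname(blocks))
    b <- b[order(b$start), , drop = FALSE]
    # clip to the array span (tier 3)
    b$start <- pmax(b$start, arr$start)
    b$end <- pmin(b$end, arr$end)
    # defensive: merge adjacent same-strand blocks (possible when a short
    # opposite-strand block interrupts a within-gap run)
    if (nrow(b) > 1) {
      same <- c(FALSE, b$strand[-1] == b$strand[-nrow(b)])
      grp <- cumsum(!same)
      if (any(same)) {
        b <- do.call(rbind, lapply(split(b, grp), function(g) {
          data.frame(contig = g$contig[1], start = min(g$start),
                     end = max(g$end), strand = g$strand[1],
                     monomer_count = sum(g$monomer_count),
                     stringsAsFactors = FALSE)
        }))
      }
    }
    rownames(b) <- NULL
    b <- data.frame(array_id = aid, family_id = fam, b,
                    block_index = seq_len(nrow(b)),
                    stringsAsFactors = FALSE)
    sub_rows[[aid]] <- b
    if (nrow(b) > 1) {
      li <- seq_len(nrow(b) - 1)
      inv_rows[[aid]] <- data.frame(
        array_id = aid, family_id = fam, contig = b$contig[1],
        position = as.integer(floor((b$end[li] + b$start[li + 1]) / 2)),
        left_strand = b$strand[li],
        right_strand = b$strand[li + 1],
        stringsAsFactors = FALSE)
    }
  }
  subarrays <- do.call(rbind, unname(sub_rows))
  inversions <- do.call(rbind, unname(inv_rows))
  if (is.null(inversions)) {
    inversions <- data.frame(array_id = character(), family_id = character(),
                             contig = character(), position = integer(),
                             left_strand = character(),
                             right_strand = character(),
                             stringsAsFactors = FALSE)
  }
  rownames(subarrays) <- NULL
  rownames(inversions) <- NULL
  list(subarrays = subarrays, inversions = inversions)
}

#' Macro-dyad symmetry metrics per array
#'
#' For every array: the number of oriented subarrays; for every inversion
#' point, the signed length difference (left block bp minus right block bp)
#' of the two flanking subarrays; and the symmetry span, the maximum over
#' inversion points of the summed flanking block lengths. One-directional
#' arrays are reported with `n_subarrays = 1` and no difference entries.
#'
#' @param decomposition result of [decompose_subarrays()].
#' @return List with `per_array` (data frame `array_id`, `family_id`,
#'   `n_subarrays`, `symmetry_span`) and `per_inversion` (data frame
#'   `array_id`, `position`, `direct_inverted_diff`, `flank_span`).
#' @export
macrodyad_metrics <- function(decomposition) {
  sub <- decomposition$subarrays
  ids <- unique(sub$array_id)
  per_inv <- list()
  per_arr <- data.frame(array_id = ids,
                        family_id = sub$family_id[match(ids, sub$array_id)],
                        n_subarrays = NA_integer_,
                        symmetry_span = NA_real_,
                        stringsAsFactors = FALSE)
  for (r in seq_along(ids)) {
    b <- sub[sub$array_id == ids[r], , drop = FALSE]
    b <- b[order(b$block_index), , drop = FALSE]
    per_arr$n_subarrays[r] <- nrow(b)
    if (nrow(b) > 1) {
      li <- seq_len(nrow(b) - 1)
      lw <- b$end[li] - b$start[li]
      rw <- b$end[li + 1] - b$start[li + 1]
      per_inv[[ids[r]]] <- data.frame(
        array_id = ids[r],
        position = as.integer(floor((b$end[li] + b$start[li + 1]) / 2)),
        direct_inverted_diff = lw - rw,
        flank_span = lw + rw,
        stringsAsFactors = FALSE)
      per_arr$symmetry_span[r] <- max(lw + rw)
    }
  }
  per_inversion <- do.call(rbind, unname(per_inv))
  if (is.null(per_inversion)) {
    per_inversion <- data.frame(array_id = character(), position = integer(),
                                direct_inverted_diff = numeric(),
                                flank_span = numeric(),
                                stringsAsFactors = FALSE)
  }
  rownames(per_inversion) <- NULL
  list(per_array = per_arr, per_inversion = per_inversion)
}

#' Extract sequence windows around inversion points
#'
#' Windows `[position - radius, position + radius)` on the forward genome
#' strand; windows clipped at contig ends are flagged as truncated.
#'
#' @param points inversion table from [decompose_subarrays()].
#' @param genome `DNAStringSet`.
#' @param window_radius half-window in bp. Default 200.
#' @return Data frame `site_id`, `array_id`, `contig`, `position`, `start`,
#'   `end`, `truncated`, `sequence`.
#' @export
extract_inversion_sites <- function(points, genome, window_radius = 200L) {
  if (nrow(points) == 0) {
    return(data.frame(site_id = character(), array_id = character(),
                      contig = character(), position = integer(),
                      start = integer(), end = integer(),
                      truncated = logical(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  ctg_len <- stats::setNames(Biostrings::width(genome), names(genome))
  if (any(!points$contig %in% names(ctg_len))) {
    stop("inversion point on unknown contig")
  }
  if (any(points$position < 0 | points$position > ctg_len[points$contig])) {
    stop("inversion position outside contig")
  }
  start <- pmax(0L, points$position - window_radius)
  end <- pmin(as.integer(ctg_len[points$contig]),
              points$position + window_radius)
  seqs <- vapply(seq_len(nrow(points)), function(i) {
    seq_extract(genome, points$contig[i], start[i], end[i])
  }, "")
  data.frame(site_id = sprintf("site_%04d", seq_len(nrow(points))),
             array_id = points$array_id,
             contig = points$contig,
             position = points$position,
             start = start, end = end,
             truncated = (end - start) < 2L * window_radius,
             sequence = seqs,
             stringsAsFactors = FALSE)
}

#' Cluster inversion-site windows by sequence identity
#'
#' Single-linkage clustering on pairwise global-alignment identity
#' (match +1, mismatch -1, gap open -5, gap extend -1; identity =
#' matches / alignment columns). Per cluster a majority-rule consensus and
#' the mean pairwise identity are reported; clusters with fewer than 3
#' members are labeled minor.
#'
#' @param sites data frame from [extract_inversion_sites()] (needs a
#'   `sequence` column), or a character vector of windows.
#' @param identity_threshold percent identity joining threshold. Default 90.
#' @return List with `clusters` (data frame `cluster_label`, `n`,
#'   `mean_pairwise_identity`, `minor`, `consensus`) and `assignments`
#'   (cluster label per input site).
#' @export
cluster_sites <- function(sites, identity_threshold = 90) {
  seqs <- if (is.data.frame(sites)) sites$sequence else sites
  stopifnot(length(seqs) >= 1)
  res <- identity_clusters(seqs, identity_threshold, prefix = "INV")
  list(clusters = res$clusters, assignments = res$assignments)
}

#' Divergence of a cluster consensus from a canonical subunit
#'
#' 100 minus the percent identity of the pinned global pairwise alignment;
#' gap columns count as differences.
#'
#' @param cluster_consensus,canonical non-empty sequences.
#' @return Percent divergence.
#' @export
site_divergence <- function(cluster_consensus, canonical) {
  stopifnot(nzchar(cluster_consensus), nzchar(canonical))
  100 - align_identity(cluster_consensus, canonical)
}
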