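# Cross-genome comparison: exact and approximate k-mer scanning with a
# bounded Levenshtein distance (pigeonhole seeding, provably complete for
# the distance bound), mapping of matched regions back onto a consensus,
# and sequence-population geometry: F81 distances on a common coordinate
# frame, PCA embeddings of distance-matrix rows, and k-nearest-neighbor
# sequence graphs.

#' k-mer set of a consensus
#'
#' All overlapping k-mers of the sequence and of its reverse complement,
#' duplicates collapsed.
#'
#' @param consensus sequence of length >= k.
#' @param k k-mer size. Default 16.
#' @return List of class `kmer_set` with fields `k` and `kmers`.
#' @export
kmerize <- function(consensus, k = 16L) {
  consensus <- toupper(consensus)
  L <- nchar(consensus)
  if (L < k) stop("sequence shorter than k = ", k)
  fwd <- substring(consensus, 1:(L - k + 1L), k:L)
  rev <- substring(revcomp(consensus), 1:(L - k + 1L), k:L)
  structure(list(k = as.integer(k), kmers = unique(c(fwd, rev))),
            class = "kmer_set")
}

#' Levenshtein edit distance
#'
#' Standard unit-cost edit distance (insertions, deletions, substitutions).
#'
#' @param a,b strings.
#' @return Integer distance.
#' @export
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Minimum edit distance of `kmer` against windows of the contig string `s`
# starting at each 0-based position in `starts`, over window lengths
# k-d .. k+d. Ties between lengths prefer the length closest to k, then the
# shorter one. Returns data.frame(start, dist, len).
.best_window <- function(s, n, kmer, starts, d) {
  k <- nchar(kmer)
  lens <- (k - d):(k + d)
  lens <- lens[lens >= 1]
  # order lengths by |len - k| then len so the first minimum wins ties
  lens <- lens[order(abs(lens - k), lens)]
  best_d <- rep(Inf, length(starts))
  best_l <- rep(NA_integer_, length(starts))
  for (l in lens) {
    valid <- which(starts + l <= n)
    if (length(valid) == 0) next
    w <- substring(s, starts[valid] + 1L, starts[valid] + l)
    dd <- as.integer(utils::adist(kmer, w))
    better <- dd < best_d[valid]
    best_d[valid[better]] <- dd[better]
    best_l[valid[better]] <- l
  }
  data.frame(start = starts, dist = best_d, len = best_l)
}

#' Approximate k-mer scan of a genome
#'
#' Reports every genomic locus where some k-mer of the set matches within
#' edit distance `max_distance`, with the minimal distance found. The scan
#' uses pigeonhole seeding: each k-mer is split into `max_distance + 1`
#' exact seed parts, seed matches are located exactly, and candidate loci
#' are verified with full edit distance over window lengths `k - d .. k +
#' d`. Any window within the distance bound contains at least one exact
#' seed part, so the scan is complete for the bound. Exact matches are
#' always found. With `collapse = TRUE` (default), loci within
#' `max_distance` bp reporting the same k-mer are collapsed to the best
#' (minimal distance, then leftmost).
#'
#' @param genome `DNAStringSet` or named character vector.
#' @param kmers a [kmerize()] result.
#' @param max_distance Levenshtein bound. Default 3.
#' @param collapse collapse near-duplicate loci of one k-mer. Default TRUE.
#' @return Interval data frame of hits with `min_edit_distance` and
#'   `source_kmer`.
#' @export
approx_scan <- function(genome, kmers, max_distance = 3L, collapse = TRUE) {
  stopifnot(inherits(kmers, "kmer_set"), length(kmers$kmers) > 0,
            max_distance >= 0)
  k <- kmers$k
  d <- as.integer(max_distance)
  if (k < d + 1L) stop("k must be at least max_distance + 1")
  if (!is.character(genome)) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  # seed parts: d + 1 pieces of the k-mer, as equal as possible
  nparts <- d + 1L
  cuts <- floor(seq(0, k, length.out = nparts + 1L))
  out <- list()
  for (ctg in names(genome)) {
    s <- genome[[ctg]]
    n <- nchar(s)
    subj <- Biostrings::DNAString(s)
    rows <- list()
    for (km in sort(kmers$kmers)) {
      cand <- integer()
      for (p in seq_len(nparts)) {
        part <- substr(km, cuts[p] + 1L, cuts[p + 1L])
        if (nchar(part) == 0) next
        mp <- Biostrings::matchPattern(part, subj)
        if (length(mp) == 0) next
        seed0 <- Biostrings::start(mp) - 1L       # 0-based seed positions
        anchor <- seed0 - cuts[p]                 # implied window start
        cand <- c(cand, outer(anchor, (-d):d, "+"))
      }
      cand <- unique(cand)
      cand <- cand[cand >= 0 & cand < n]
      if (length(cand) == 0) next
      bw <- .best_window(s, n, km, sort(cand), d)
      bw <- bw[bw$dist <= d, , drop = FALSE]
      if (nrow(bw) == 0) next
      rows[[km]] <- data.frame(contig = ctg, start = bw$start,
                               end = bw$start + bw$len, strand = ".",
                               min_edit_distance = as.integer(bw$dist),
                               source_kmer = km, stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, rows)
    if (is.null(res)) next
    # one record per locus: the minimal distance over k-mers, ties broken
    # by lexicographically smallest k-mer (rows are already in k-mer order)
    res <- res[order(res$start, res$min_edit_distance, res$source_kmer), ,
               drop = FALSE]
    res <- res[!duplicated(res$start), , drop = FALSE]
    if (collapse && nrow(res) > 1) {
      keep <- logical(nrow(res))
      grp <- cumsum(c(TRUE, diff(res$start) > d |
                        res$source_kmer[-1] != res$source_kmer[-nrow(res)]))
      for (g in split(seq_len(nrow(res)), grp)) {
        keep[g[order(res$min_edit_distance[g], res$start[g])[1]]] <- TRUE
      }
      res <- res[keep, , drop = FALSE]
    }
    out[[ctg]] <- res
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(intervals(min_edit_distance = integer(),
                     source_kmer = character()))
  }
  rownames(res) <- NULL
  sort_intervals(res)
}

#' Merge scan hits into regions
#'
#' [interval_merge()] with `max_gap`; each merged region carries the number
#' of constituent hits and their minimal edit distance.
#'
#' @param hits hit table from [approx_scan()].
#' @param max_gap merge gap in bp. Default 16.
#' @return Interval data frame with `n_hits` and `min_edit_distance`.
#' @export
merge_hits <- function(hits, max_gap = 16L) {
  merged <- interval_merge(hits, max_gap = max_gap)
  if (nrow(merged) == 0) {
    return(intervals(n_hits = integer(), min_edit_distance = integer()))
  }
  merged$n_hits <- lengths(merged$members)
  merged$min_edit_distance <- vapply(merged$members, function(m) {
    min(hits$min_edit_distance[m])
  }, 0L)
  merged$members <- NULL
  merged
}

#' Map region sequences back onto a consensus
#'
#' Each region sequence is locally aligned to the consensus on both strands
#' (pinned scoring scheme); the better orientation contributes +1 coverage
#' on the consensus positions it spans. Regions scoring below `min_score`
#' in both orientations are counted as unmapped. The profile shows whether
#' cross-genome similarity is confined to short consensus segments.
#'
#' @param regions character vector of region sequences.
#' @param consensus consensus sequence.
#' @param min_score local alignment score floor. Default 10.
#' @return List with `profile` (integer coverage per consensus position)
#'   and `n_unmapped`.
#' @export
map_back <- function(regions, consensus, min_score = 10) {
  L <- nchar(consensus)
  profile <- integer(L)
  n_unmapped <- 0L
  for (r in regions) {
    af <- .align(r, consensus, type = "local")
    ar <- .align(revcomp(r), consensus, type = "local")
    best <- if (Biostrings::score(af) >= Biostrings::score(ar)) af else ar
    if (Biostrings::score(best) < min_score) {
      n_unmapped <- n_unmapped + 1L
      next
    }
    rng <- seq(IRanges::start(Biostrings::subject(best)),
               IRanges::end(Biostrings::subject(best)))
    profile[rng] <- profile[rng] + 1L
  }
  list(profile = profile, n_unmapped = n_unmapped)
}

#' F81 genetic distance between two aligned sequences
#'
#' Felsenstein (1981) model distance `d = -E * ln(1 - p / E)` with
#' `E = 1 - sum(pi_i^2)`, where `p` is the mismatch proportion over columns
#' where both sequences carry A/C/G/T (pairwise deletion). Saturated pairs
#' (`p >= E`) are returned as `Inf`.
#'
#' @param aligned_a,aligned_b equal-length aligned sequences (gaps `-`).
#' @param base_freqs length-4 frequency vector (A, C, G, T) summing to 1.
#' @return Distance in substitutions/site (`Inf` when saturated).
#' @export
f81_distance <- function(aligned_a, aligned_b, base_freqs) {
  stopifnot(nchar(aligned_a) == nchar(aligned_b),
            length(base_freqs) == 4,
            abs(sum(base_freqs) - 1) < 1e-8)
  a <- strsplit(toupper(aligned_a), "")[[1]]
  b <- strsplit(toupper(aligned_b), "")[[1]]
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop("no comparable columns")
  p <- mean(a[ok] != b[ok])
  E <- 1 - sum(base_freqs^2)
  if (p >= E) return(Inf)
  -E * log(1 - p / E)
}

#' F81 distance matrix over a sequence population
#'
#' Sequences are first put into a common coordinate frame by pairwise
#' anchoring to the longest sequence (every sequence globally aligned to
#' the anchor and projected onto its columns), so that all pairs are scored
#' on the same column set. Base frequencies are estimated once from the
#' whole anchored alignment. Saturated pairs are flagged.
#'
#' @param seqs named character vector of sequences.
#' @return List of class `distance_matrix` with `labels`, `values` (n x n
#'   matrix, `Inf` where saturated), `saturated` (logical matrix),
#'   `base_freqs`, and the anchored `alignment` character matrix.
#' @export
build_distance_matrix <- function(seqs) {
  stopifnot(length(seqs) >= 2)
  if (is.null(names(seqs))) {
    names(seqs) <- sprintf("seq_%04d", seq_along(seqs))
  }
  aln <- anchor_align(seqs)
  tab <- table(factor(aln[aln %in% c("A", "C", "G", "T")],
                      levels = c("A", "C", "G", "T")))
  base_freqs <- as.numeric(tab) / sum(tab)
  n <- length(seqs)
  E <- 1 - sum(base_freqs^2)
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  base <- matrix(aln %in% c("A", "C", "G", "T"), n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- base[i, ] & base[j, ]
      if (!any(ok)) stop("no comparable columns for pair ",
                         names(seqs)[i], " / ", names(seqs)[j])
      p <- mean(aln[i, ok] != aln[j, ok])
      D[i, j] <- D[j, i] <- if (p >= E) Inf else -E * log(1 - p / E)
    }
  }
  structure(list(labels = names(seqs), values = D,
                 saturated = is.infinite(D), base_freqs = base_freqs,
                 alignment = aln),
            class = "distance_matrix")
}

#' PCA embedding of a distance matrix
#'
#' Rows of the distance matrix are treated as feature vectors,
#' column-centered, and projected onto the top two principal axes.
#' Saturated entries are imputed with 1.5 times the largest finite
#' distance before embedding.
#'
#' @param matrix a `distance_matrix` or a plain numeric matrix.
#' @return List of class `embedding` with `coordinates` (n x 2, PC1/PC2)
#'   and `variance_fractions` (length 2).
#' @export
pca_embed <- function(matrix) {
  D <- if (inherits(matrix, "distance_matrix")) matrix$values else matrix
  n <- nrow(D)
  if (n < 3) stop("need at least 3 sequences for PCA")
  if (any(is.infinite(D))) {
    mx <- max(D[is.finite(D)])
    D[is.infinite(D)] <- 1.5 * mx
  }
  if (all(D == 0)) {
    coords <- matrix(0, n, 2, dimnames = list(rownames(D), c("PC1", "PC2")))
    return(structure(list(coordinates = coords,
                          variance_fractions = c(0, 0)),
                     class = "embedding"))
  }
  pc <- stats::prcomp(D, center = TRUE, scale. = FALSE)
  coords <- pc$x[, 1:2, drop = FALSE]
  colnames(coords) <- c("PC1", "PC2")
  vf <- pc$sdev[1:2]^2 / sum(pc$sdev^2)
  structure(list(coordinates = coords, variance_fractions = vf),
            class = "embedding")
}

#' k-nearest-neighbor sequence graph
#'
#' Undirected edges from each node to its `k` nearest neighbors by distance
#' (ties broken by label order); mutual selections are deduplicated.
#'
#' @param matrix a `distance_matrix` or plain numeric matrix.
#' @param k neighbors per node. Default 5.
#' @return List of class `seq_graph` with `nodes` and `edges` (data frame
#'   `from`, `to`, `distance`).
#' @export
knn_graph <- function(matrix, k = 5L) {
  D <- if (inherits(matrix, "distance_matrix")) matrix$values else matrix
  n <- nrow(D)
  if (n <= k) stop("need more than k = ", k, " sequences")
  labels <- rownames(D)
  if (is.null(labels)) labels <- sprintf("seq_%04d", seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    others <- setdiff(seq_len(n), i)
    nb <- others[order(D[i, others], others)][seq_len(k)]
    edges[[i]] <- data.frame(from = labels[pmin(i, nb)],
                             to = labels[pmax(i, nb)],
                             distance = D[i, nb],
                             stringsAsFactors = FALSE)
  }
  e <- do.call(rbind, edges)
  e <- e[!duplicated(e[, c("from", "to")]), , drop = FALSE]
  e <- e[order(e$from, e$to), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = labels, edges = e), class = "seq_graph")
}

#' Write a sequence graph as an edge list
#'
#' Tab-separated `from`, `to`, `distance` (an open edge-list format readable
#' by igraph and friends).
#'
#' @param graph a `seq_graph`.
#' @param path output path.
#' @export
write_edgelist <- function(graph, path) {
  write_tsv(graph$edges, path)
}
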