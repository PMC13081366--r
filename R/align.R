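# Pairwise alignment helpers shared by the symmetry, junction and
# comparative modules. The scoring scheme is pinned for reproducibility:
# match +1, mismatch -1, gap open -5, gap extend -1. Identity is
# matches / alignment columns, so gap columns count as differences, and N
# never counts as a match.

.nuc_matrix <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- c("A", "C", "G", "T", "N")
      m <- matrix(-1, 5, 5, dimnames = list(letters, letters))
      diag(m) <- 1
      m["N", "N"] <- -1
      mat <<- m
    }
    mat
  }
})

.align <- function(a, b, type = "global") {
  Biostrings::pairwiseAlignment(a, b, type = type,
                                substitutionMatrix = .nuc_matrix(),
                                gapOpening = 5, gapExtension = 1)
}

# Percent identities of the pinned global alignment of many queries
# against one reference (vectorized over the C alignment loop).
align_identity_many <- function(queries, ref) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(queries), ref, type = "global",
    substitutionMatrix = .nuc_matrix(), gapOpening = 5, gapExtension = 1)
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  vapply(seq_along(pa), function(k) {
    p <- strsplit(pa[k], "")[[1]]
    s <- strsplit(sa[k], "")[[1]]
    100 * sum(p == s & p != "-" & p != "N") / length(p)
  }, 0)
}

# Percent identity of the pinned global alignment of two sequences.
align_identity <- function(a, b) {
  align_identity_many(a, b)
}

# Symmetric percent-identity matrix over a character vector of sequences.
pairwise_identity_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(100, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ids <- align_identity_many(seqs[(i + 1):n], seqs[i])
      m[i, (i + 1):n] <- m[(i + 1):n, i] <- ids
    }
  }
  m
}

# Connected components of an undirected adjacency defined by a logical
# matrix (union-find). Returns an integer component label per element,
# renumbered in order of first appearance.
.components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(n)) {
    for (j in which(adj[i, ])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  match(roots, unique(roots))
}

# Put sequences into a common coordinate frame by pairwise anchoring to the
# longest sequence: every sequence is globally aligned to the anchor and
# projected onto the anchor's columns (insertions relative to the anchor are
# dropped, deletions become "-"). Returns a character matrix, one row per
# sequence, ncol = anchor length.
anchor_align <- function(seqs) {
  stopifnot(length(seqs) >= 1)
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[ref_i]
  L <- nchar(ref)
  out <- matrix("-", length(seqs), L)
  for (i in seq_along(seqs)) {
    if (i == ref_i) {
      out[i, ] <- strsplit(ref, "")[[1]]
      next
    }
    aln <- .align(seqs[i], ref)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
    keep <- sa != "-"
    # global alignment covers the full anchor, so keep sums to L
    out[i, ] <- pa[keep]
  }
  rownames(out) <- names(seqs)
  out
}

# Majority-rule consensus of an anchored alignment matrix: per column the
# most frequent base among A/C/G/T (ties alphabetical); columns where gaps
# hold the strict majority are dropped.
majority_consensus <- function(alnmat) {
  n <- nrow(alnmat)
  cols <- apply(alnmat, 2, function(col) {
    gaps <- sum(col == "-")
    if (gaps > n / 2) return(NA_character_)
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) == 0) return(NA_character_)
    tab <- table(col)
    names(tab)[which.max(tab)]  # which.max breaks ties alphabetically
  })
  paste(cols[!is.na(cols)], collapse = "")
}

# Single-linkage clustering of sequences on pairwise global identity.
# Returns list(assignments, clusters df). Cluster labels are ranked by size
# (ties: first appearance).
identity_clusters <- function(seqs, identity_threshold, prefix = "cluster") {
  stopifnot(length(seqs) >= 1)
  idm <- pairwise_identity_matrix(seqs)
  comp <- .components(idm >= identity_threshold & !diag(TRUE, length(seqs)))
  sizes <- table(comp)
  rank <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(rank), names(sizes)[rank])
  lab <- relabel[as.character(comp)]
  clusters <- lapply(seq_along(rank), function(k) {
    members <- which(lab == k)
    mi <- if (length(members) > 1) {
      mean(idm[members, members][upper.tri(idm[members, members])])
    } else 100
    list(label = sprintf("%s_%d", prefix, k),
         members = members,
         n = length(members),
         mean_identity = mi,
         minor = length(members) < 3,
         consensus = if (length(members) == 1) seqs[members] else
           majority_consensus(anchor_align(seqs[members])))
  })
  df <- data.frame(
    cluster_label = vapply(clusters, `[[`, "", "label"),
    n = vapply(clusters, `[[`, 0L, "n"),
    mean_pairwise_identity = vapply(clusters, `[[`, 0, "mean_identity"),
    minor = vapply(clusters, `[[`, TRUE, "minor"),
    consensus = vapply(clusters, `[[`, "", "consensus"),
    stringsAsFactors = FALSE)
  list(assignments = sprintf("%s_%d", prefix, lab),
       clusters = df,
       members = lapply(clusters, `[[`, "members"))
}
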