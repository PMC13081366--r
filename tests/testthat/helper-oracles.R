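# Independent oracles and shared fixtures. Oracles are deliberately naive
# (brute force / closed form) and never share code with the implementation
# paths they check.

# --- brute-force interval oracles -------------------------------------------

random_intervals <- function(n, contigs = c("c1", "c2"), span = 1000L,
                             max_len = 60L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  intervals(contig = sample(contigs, n, replace = TRUE),
            start = start, end = start + len,
            strand = sample(c("+", "-", "."), n, replace = TRUE))
}

# transitive closure merge by pairwise gap checks, O(n^2)
oracle_merge <- function(iv, max_gap) {
  out <- list()
  for (ctg in unique(iv$contig)) {
    x <- iv[iv$contig == ctg, , drop = FALSE]
    n <- nrow(x)
    grp <- seq_len(n)
    repeat {
      changed <- FALSE
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          if (grp[i] != grp[j]) {
            gap <- max(0L, max(x$start[j] - x$end[i],
                               x$start[i] - x$end[j]))
            if (gap <= max_gap) {
              grp[grp == grp[j]] <- grp[i]
              changed <- TRUE
            }
          }
        }
      }
      if (!changed) break
    }
    for (g in unique(grp)) {
      out[[length(out) + 1L]] <- data.frame(
        contig = ctg, start = min(x$start[grp == g]),
        end = max(x$end[grp == g]), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$end), , drop = FALSE]
}

# per-base boolean-array subtraction
oracle_subtract <- function(iv, mask, span = 2000L) {
  out <- list()
  for (i in seq_len(nrow(iv))) {
    covered <- rep(FALSE, span)
    m <- mask[mask$contig == iv$contig[i], , drop = FALSE]
    for (j in seq_len(nrow(m))) {
      if (m$end[j] > m$start[j]) covered[(m$start[j] + 1):m$end[j]] <- TRUE
    }
    keep <- rep(FALSE, span)
    keep[(iv$start[i] + 1):iv$end[i]] <- TRUE
    keep <- keep & !covered
    r <- rle(keep)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    sel <- which(r$values)
    for (k in sel) {
      out[[length(out) + 1L]] <- data.frame(
        contig = iv$contig[i], start = starts[k], end = ends[k],
        source = i, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res[order(res$contig, res$start, res$end), , drop = FALSE]
}

# full dynamic-programming Levenshtein table
oracle_edit_distance <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
    }
  }
  d[n + 1, m + 1]
}

# windowed brute-force approximate scan: every k-mer against every window
# of length k-d .. k+d, same length tie rule as the implementation
oracle_approx_scan <- function(s, kmers, k, d) {
  n <- nchar(s)
  lens <- (k - d):(k + d)
  lens <- lens[order(abs(lens - k), lens)]
  rows <- list()
  for (km in sort(kmers)) {
    best_d <- rep(Inf, n)
    best_l <- rep(NA_integer_, n)
    for (l in lens) {
      starts0 <- 0:(n - l)
      w <- substring(s, starts0 + 1L, starts0 + l)
      dd <- as.integer(utils::adist(km, w))
      upd <- which(dd < best_d[starts0 + 1L])
      best_d[upd] <- dd[upd]
      best_l[upd] <- l
    }
    hit <- which(best_d <= d)
    if (length(hit)) {
      rows[[km]] <- data.frame(start = hit - 1L,
                               end = hit - 1L + best_l[hit],
                               dist = best_d[hit], kmer = km,
                               stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) return(res)
  # per locus: min distance, ties by lexicographically smallest k-mer
  res <- res[order(res$start, res$dist, res$kmer), , drop = FALSE]
  res <- res[!duplicated(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# --- shared small simulation (built once per test run) ----------------------

.fixture_env <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_env$sim)) {
    spec <- default_architecture(seed = 202, genome_length = 9e5,
                                 n_cassettes = 4, n_major_plain = 3,
                                 n_minor_plain = 2, n_spacer_arrays = 2,
                                 n_decoys = 6)
    .fixture_env$sim <- plant_architecture(spec)
  }
  .fixture_env$sim
}

small_annotation <- function() {
  if (is.null(.fixture_env$ann)) {
    sim <- small_sim()
    hits <- resolve_overlaps(search_monomers(sim$genome, sim$families))
    arrays <- build_arrays(hits, sim$families)
    decomposition <- decompose_subarrays(arrays, sim$families)
    .fixture_env$ann <- list(hits = hits, arrays = arrays,
                             decomposition = decomposition)
  }
  .fixture_env$ann
}

# deterministic toy genome with one planted family, used by annotate tests
toy_plant <- function(seed = 77, n_copies = 1, divergence = 0,
                      bg = 10000L, consensus_length = 110L) {
  set.seed(seed)
  cons <- random_dna(consensus_length)
  copies <- vapply(seq_len(n_copies), function(i)
    mutate_copy(cons, divergence), "")
  left <- random_dna(bg %/% 2)
  g <- paste0(left, paste(copies, collapse = ""), random_dna(bg %/% 2))
  planted <- intervals(
    contig = "chr1",
    start = nchar(left) + (seq_len(n_copies) - 1L) * consensus_length,
    end = nchar(left) + seq_len(n_copies) * consensus_length,
    strand = "+")
  list(genome = Biostrings::DNAStringSet(c(chr1 = g)),
       family = list(fam1 = sat_family("fam1", cons)),
       consensus = cons, planted = planted)
}
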