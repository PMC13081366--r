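test_that("kmerize enumerates both-strand k-mers", {
  set.seed(71)
  s16 <- random_dna(16)
  ks <- kmerize(s16, 16)
  expect_true(length(ks$kmers) %in% c(1L, 2L))
  expect_true(s16 %in% ks$kmers)
  s20 <- random_dna(20)
  fwd <- substring(s20, 1:5, 16:20)
  ks20 <- kmerize(s20, 16)
  expect_true(all(fwd %in% ks20$kmers))
  expect_error(kmerize(random_dna(10), 16), "shorter than k")
  # enumeration oracle
  for (i in 1:5) {
    s <- random_dna(sample(30:60, 1))
    k <- 12L
    ks2 <- kmerize(s, k)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    expect_setequal(ks2$kmers,
                    unique(c(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)),
                             substring(rc, 1:(nchar(s) - k + 1), k:nchar(s)))))
  }
})

test_that("edit distance equals the DP oracle and behaves as a metric", {
  expect_equal(edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(edit_distance("ACGT", "ACGA"), 1L)
  set.seed(72)
  for (i in 1:40) {
    a <- random_dna(sample(5:25, 1))
    b <- random_dna(sample(5:25, 1))
    expect_equal(edit_distance(a, b), oracle_edit_distance(a, b))
    expect_equal(edit_distance(a, b), edit_distance(b, a))
  }
  for (i in 1:20) {
    x <- random_dna(12); y <- random_dna(12); z <- random_dna(12)
    expect_lte(edit_distance(x, z),
               edit_distance(x, y) + edit_distance(y, z))
  }
})

test_that("approximate scan finds exact and bounded-distance matches", {
  set.seed(73)
  km <- random_dna(16)
  bg1 <- random_dna(3000)
  bg2 <- random_dna(3000)
  g <- stats::setNames(paste0(bg1, km, bg2), "c1")
  ks <- structure(list(k = 16L, kmers = km), class = "kmer_set")
  hits <- approx_scan(g, ks, max_distance = 3)
  exact <- hits[hits$min_edit_distance == 0, ]
  expect_equal(exact$start, 3000L)
  expect_equal(exact$end, 3016L)

  # three substitutions still found at distance 3; four missed
  mut_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  }
  km3 <- mut_at(km, c(2, 8, 14))
  g3 <- stats::setNames(paste0(bg1, km3, bg2), "c1")
  h3 <- approx_scan(g3, ks, max_distance = 3)
  near <- h3[abs(h3$start - 3000L) <= 3, ]
  expect_true(any(near$min_edit_distance <= 3))
  km4 <- mut_at(km, c(2, 5, 8, 14))
  g4 <- stats::setNames(paste0("GGGGCCCC", km4, "GGGGCCCC"), "c1")
  h4 <- approx_scan(g4, ks, max_distance = 3)
  expect_false(any(abs(h4$start - 8L) <= 3))

  # distance 0 equals exact string search
  g0 <- stats::setNames(paste0(bg1, km, bg2, km), "c1")
  h0 <- approx_scan(g0, ks, max_distance = 0)
  naive <- gregexpr(km, g0[["c1"]], fixed = TRUE)[[1]]
  expect_equal(h0$start, as.integer(naive) - 1L)
})

test_that("approximate scan equals the windowed brute-force oracle", {
  set.seed(74)
  s <- random_dna(10000)
  cons <- random_dna(60)
  # plant diverged fragments of the consensus so non-trivial hits exist
  for (p in c(2000, 5000, 8000)) {
    frag <- mutate_copy(substr(cons, 10, 35), 0.08)
    substr(s, p, p + nchar(frag) - 1) <- frag
  }
  ks <- kmerize(cons, 16)
  ks$kmers <- sort(ks$kmers)[1:30]
  got <- approx_scan(stats::setNames(s, "c1"), ks, max_distance = 3,
                     collapse = FALSE)
  exp <- oracle_approx_scan(s, ks$kmers, 16L, 3L)
  expect_equal(got$start, exp$start)
  expect_equal(got$min_edit_distance, exp$dist)
  expect_equal(got$end, exp$end)
  expect_equal(got$source_kmer, exp$kmer)
})

test_that("merged hit regions carry counts and minimal distances", {
  hits <- intervals(contig = "c1", start = c(0L, 10L, 100L),
                    end = c(16L, 26L, 116L),
                    min_edit_distance = c(2L, 0L, 3L),
                    source_kmer = "X")
  m <- merge_hits(hits, max_gap = 16L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$n_hits, c(2L, 1L))
  expect_equal(m$min_edit_distance, c(0L, 3L))
})

test_that("map_back accumulates coverage on the consensus", {
  set.seed(75)
  cons <- random_dna(120)
  region <- substr(cons, 41, 80)
  mb <- map_back(c(region, region), cons)
  expect_equal(mb$profile[41:80], rep(2L, 40))
  expect_equal(sum(mb$profile), 80L)
  expect_equal(mb$n_unmapped, 0L)
  # reverse-complement regions map to the same positions
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(region)))
  mb2 <- map_back(rc, cons)
  expect_equal(mb2$profile[41:80], rep(1L, 40))
  # unrelated decoys are counted unmapped
  mb3 <- map_back(c(region, random_dna(40), random_dna(40)), cons,
                  min_score = 15)
  expect_equal(mb3$n_unmapped, 2L)
})

test_that("F81 distance follows the closed form", {
  expect_equal(f81_distance("ACGTACGT", "ACGTACGT", rep(0.25, 4)), 0)
  # equal frequencies, p = 0.1
  a <- strrep("ACGT", 10)
  b <- paste0("CCGT", strrep("ACGT", 9))  # 1 mismatch in 40 -> p = 0.025
  expect_equal(f81_distance(a, b, rep(0.25, 4)),
               -0.75 * log(1 - 0.025 / 0.75))
  for (p in c(0.05, 0.1, 0.3, 0.6)) {
    n <- 1000L
    k <- round(p * n)
    x <- strrep("A", n)
    y <- paste0(strrep("C", k), strrep("A", n - k))
    expect_equal(f81_distance(x, y, rep(0.25, 4)),
                 -0.75 * log(1 - (k / n) / 0.75))
  }
  # monotone in p
  E <- 0.75
  ps <- seq(0.01, 0.7, by = 0.01)
  ds <- -E * log(1 - ps / E)
  expect_true(all(diff(ds) > 0))
  # saturation flagged as infinite
  expect_equal(f81_distance(strrep("A", 10), strrep("C", 10),
                            rep(0.25, 4)), Inf)
  expect_error(f81_distance("----", "AAAA", rep(0.25, 4)),
               "no comparable columns")
})

test_that("distance matrices agree with the reference F81 implementation", {
  set.seed(76)
  base <- random_dna(300)
  seqs <- c(a = base, b = mutate_copy(base, 0.05),
            c = mutate_copy(base, 0.15), d = mutate_copy(base, 0.3))
  dm <- build_distance_matrix(seqs)
  expect_true(isSymmetric(dm$values))
  expect_equal(diag(dm$values), setNames(rep(0, 4), names(seqs)))
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  rownames(m) <- names(seqs)
  ref <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "F81",
                                 pairwise.deletion = TRUE))
  expect_equal(dm$values, ref, tolerance = 1e-8)
})

test_that("PCA embeddings separate planted families", {
  set.seed(77)
  base <- random_dna(250)
  fam_cons <- c(base, mutate_copy(base, 0.3), mutate_copy(base, 0.3))
  seqs <- unlist(lapply(1:3, function(f) {
    vapply(1:10, function(i) mutate_copy(fam_cons[f], 0.03), "")
  }))
  names(seqs) <- sprintf("f%d_%02d", rep(1:3, each = 10), rep(1:10, 3))
  emb <- pca_embed(build_distance_matrix(seqs))
  expect_true(all(emb$variance_fractions >= 0 &
                    emb$variance_fractions <= 1))
  expect_lte(sum(emb$variance_fractions), 1)
  expect_gte(emb$variance_fractions[1], emb$variance_fractions[2])
  lab <- rep(1:3, each = 10)
  co <- emb$coordinates
  d2 <- as.matrix(stats::dist(co))
  within_max <- max(vapply(1:3, function(f) max(d2[lab == f, lab == f]), 0))
  between_min <- min(vapply(1:2, function(f) {
    min(d2[lab == f, lab > f])
  }, 0))
  expect_lt(within_max, between_min)

  D0 <- matrix(0, 5, 5)
  e0 <- pca_embed(D0)
  expect_true(all(e0$coordinates == 0))
  expect_equal(e0$variance_fractions, c(0, 0))
  expect_error(pca_embed(matrix(0, 2, 2)), "at least 3")
})

test_that("k-nearest-neighbor graphs match exhaustive neighbor lists", {
  set.seed(78)
  n <- 6
  D <- matrix(runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(letters[1:n], letters[1:n])
  g6 <- knn_graph(D, k = 5)
  expect_equal(nrow(g6$edges), 15L)  # forced complete graph

  n <- 12
  D <- matrix(runif(n * n), n, n)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(sprintf("s%02d", 1:n), sprintf("s%02d", 1:n))
  gr <- knn_graph(D, k = 4)
  for (i in 1:n) {
    nb_exp <- order(D[i, -i])[1:4]
    nb_lab <- rownames(D)[setdiff(1:n, i)][nb_exp]
    me <- rownames(D)[i]
    has_edge <- vapply(nb_lab, function(x) {
      any((gr$edges$from == me & gr$edges$to == x) |
            (gr$edges$from == x & gr$edges$to == me))
    }, TRUE)
    expect_true(all(has_edge))
  }
  expect_error(knn_graph(D, k = 12), "more than k")

  # two well-separated families give two graph components
  set.seed(79)
  base <- random_dna(200)
  base2 <- mutate_copy(base, 0.4)
  seqs <- c(vapply(1:6, function(i) mutate_copy(base, 0.02), ""),
            vapply(1:6, function(i) mutate_copy(base2, 0.02), ""))
  names(seqs) <- sprintf("s%02d", 1:12)
  gr2 <- knn_graph(build_distance_matrix(seqs), k = 3)
  ig <- igraph::graph_from_data_frame(gr2$edges, directed = FALSE,
                                      vertices = gr2$nodes)
  comp <- igraph::components(ig)$membership
  expect_equal(length(unique(comp)), 2L)
  expect_equal(length(unique(comp[1:6])), 1L)
  expect_equal(length(unique(comp[7:12])), 1L)
})
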