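adj_arrays <- function(df) {
  df$strand <- "."
  df$monomer_count <- 10L
  df
}

test_that("adjacencies respect the gap bound and interposition", {
  arr <- adj_arrays(data.frame(
    array_id = c("a1", "b1", "a2", "b2"),
    family_id = c("A", "B", "A", "B"),
    contig = "c1",
    start = c(0L, 10100L, 12500L, 30000L),
    end = c(10000L, 12000L, 20000L, 32000L),
    stringsAsFactors = FALSE))
  adj <- find_adjacencies(arr, "A", "B", max_gap = 1000L)
  expect_equal(nrow(adj), 2L)
  expect_equal(adj$gap, c(100L, 500L))
  expect_equal(adj$left_array_id, c("a1", "b1"))
  none <- find_adjacencies(arr, "A", "B", max_gap = 50L)
  expect_equal(nrow(none), 0L)
  expect_error(find_adjacencies(arr, "A", "Z"), "unknown family")

  # planted alternating pattern: adjacency count equals planted junctions
  sim <- small_sim()
  ann <- small_annotation()
  adj2 <- find_adjacencies(ann$arrays, "satMaj", "satMin", 1000L)
  n_cassette_junctions <- 2L * nrow(sim$truth$cassettes)
  expect_equal(nrow(adj2), n_cassette_junctions)
})

test_that("k-mer edge refinement finds planted array edges", {
  set.seed(55)
  cons <- random_dna(225)
  fam <- sat_family("famE", cons)
  g <- Biostrings::DNAStringSet(c(c1 = paste0(
    random_dna(3000), strrep(cons, 3), random_dna(3000))))
  arr <- list(contig = "c1", start = 3000L, end = 3000L + 675L,
              monomer_count = 3L)
  right <- refine_edge(g, arr, fam, side = "right", threshold = 1.0)
  expect_equal(right, 3675L)
  expect_equal(refine_edge(g, arr, fam, side = "left", threshold = 1.0),
               3000L)
  expect_lte(abs(refine_edge(g, arr, fam, side = "right") - 3675L), 12L)
  expect_lte(abs(refine_edge(g, arr, fam, side = "left") - 3000L), 12L)
  # embedded in more copies of its own consensus: edge pushed outward
  g2 <- Biostrings::DNAStringSet(c(c1 = paste0(
    random_dna(3000), strrep(cons, 5), random_dna(3000))))
  expect_equal(refine_edge(g2, arr, fam, side = "right", threshold = 1.0),
               3000L + 5L * 225L)
})

test_that("junction windows are extracted with pad clipping", {
  set.seed(56)
  g <- Biostrings::DNAStringSet(c(c1 = random_dna(40000)))
  arr <- adj_arrays(data.frame(
    array_id = c("a1", "b1"), family_id = c("A", "B"), contig = "c1",
    start = c(1000L, 10150L), end = c(10000L, 20000L),
    stringsAsFactors = FALSE))
  adj <- find_adjacencies(arr, "A", "B")
  junc <- extract_junctions(g, adj, arr, pad = 250L)
  expect_equal(junc$junction_start, 9750L)
  expect_equal(junc$junction_end, 10400L)
  expect_false(junc$truncated)
  expect_equal(nchar(junc$sequence), 650L)
  expect_equal(junc$core,
               as.character(Biostrings::subseq(g[[1]], 10001, 10150)))
  # pad larger than the flanking array is clipped and flagged
  arr2 <- adj_arrays(data.frame(
    array_id = c("a1", "b1"), family_id = c("A", "B"), contig = "c1",
    start = c(9900L, 10150L), end = c(10000L, 20000L),
    stringsAsFactors = FALSE))
  junc2 <- extract_junctions(g, find_adjacencies(arr2, "A", "B"), arr2,
                             pad = 250L)
  expect_true(junc2$truncated)
  expect_equal(junc2$junction_start, 9900L)
})

test_that("transition clustering recovers planted type prevalences", {
  set.seed(57)
  t1 <- random_dna(400)
  t2 <- random_dna(380)
  juncs <- c(vapply(1:12, function(i) mutate_copy(t1, 0.02), ""),
             vapply(1:8, function(i) mutate_copy(t2, 0.02), ""))
  cls <- classify_transitions(juncs, identity_threshold = 90)
  expect_equal(cls$clusters$n[1:2], c(12L, 8L))
  expect_equal(cls$clusters$prevalence[1:2], c(60, 40))
  expect_equal(length(unique(cls$assignments[1:12])), 1L)
  expect_equal(length(unique(cls$assignments[13:20])), 1L)

  same <- classify_transitions(rep(t1, 5))
  expect_equal(nrow(same$clusters), 1L)
  expect_equal(same$clusters$prevalence, 100)

  # the subsampled path assigns the same partition on a larger population
  many <- c(vapply(1:60, function(i) mutate_copy(t1, 0.02), ""),
            vapply(1:40, function(i) mutate_copy(t2, 0.02), ""))
  big <- classify_transitions(many, identity_threshold = 90,
                              max_exact = 30L, seed = 3L)
  expect_equal(sort(big$clusters$n[1:2], decreasing = TRUE), c(60L, 40L))
  expect_equal(length(unique(big$assignments[1:60])), 1L)
  expect_equal(length(unique(big$assignments[61:100])), 1L)
})

test_that("chimeric breakpoints report split, duplicated motif and deletion", {
  set.seed(58)
  # donors engineered so the shared 6-mer is flanked by disagreeing bases
  a <- paste0(random_dna(80), "GTTCAATA", random_dna(60))
  b <- paste0(random_dna(50), "CTTCAATG", random_dna(90))
  # junction: a's prefix through its TTCAAT + b following its own TTCAAT
  jx <- paste0(substr(a, 1, 87), substr(b, 58, 148))
  r <- detect_chimeric_breakpoint(jx, a, b)
  expect_true(r$classified)
  expect_equal(r$duplicated_motif, "TTCAAT")
  expect_lte(abs(r$breakpoint_offset - 87L), 2L)

  # clean splice: no duplicated motif, breakpoint at the concatenation
  a2 <- random_dna(120)
  b2 <- random_dna(150)
  r2 <- detect_chimeric_breakpoint(paste0(a2, b2), a2, b2)
  expect_equal(r2$duplicated_motif, "")
  expect_lte(abs(r2$breakpoint_offset - 120L), 2L)
  expect_equal(r2$deletion_length, 0L)

  # prefix donor copy with a planted 60 bp internal deletion
  a3 <- random_dna(225)
  del_copy <- paste0(substr(mutate_copy(a3, 0.05), 1, 135),
                     substr(mutate_copy(a3, 0.05), 196, 225))
  r3 <- detect_chimeric_breakpoint(paste0(del_copy, b2), a3, b2)
  expect_lte(abs(r3$deletion_length - 60L), 2L)

  # junction unrelated to both donors is unclassified, not an error
  r4 <- detect_chimeric_breakpoint(random_dna(100), random_dna(200),
                                   random_dna(200))
  expect_false(r4$classified)
})

test_that("the cassette census partitions arrays into Venn cells", {
  minors <- data.frame(array_id = c("m1", "m2", "m3", "m4"),
                       stringsAsFactors = FALSE)
  junctions <- data.frame(
    left_array_id = c("x", "m1", "x", "m2", "x", "m4"),
    right_array_id = c("m1", "x", "m2", "x", "m3", "x"),
    gap = c(160L, 120L, 160L, 120L, 0L, 120L),
    type_label = c("TRANS_1", "TRANS_2", "TRANS_1", "TRANS_2",
                   "TRANS_none", "TRANS_2"),
    stringsAsFactors = FALSE)
  inversions <- data.frame(array_id = c("m1", "m3"),
                           stringsAsFactors = FALSE)
  census <- cassette_census(minors, junctions, inversions)
  expect_equal(census$n_arrays, 4L)
  expect_equal(sum(census$venn), 4L)
  expect_equal(unname(census$venn["t1_t2_inv"]), 1L)  # m1
  expect_equal(unname(census$venn["t1_t2"]), 1L)      # m2
  expect_equal(unname(census$venn["inv"]), 1L)        # m3
  expect_equal(unname(census$venn["t2"]), 1L)         # m4
  # the longer-gap cluster is type 1
  expect_equal(unname(census$type_labels["type1"]), "TRANS_1")
})

test_that("flank similarity is symmetric with identical planted flanks", {
  set.seed(59)
  flank <- random_dna(500)
  core1 <- random_dna(2000)
  core2 <- random_dna(1500)
  g <- Biostrings::DNAStringSet(c(c1 = paste0(
    flank, core1, flank, random_dna(3000), flank, core2, flank)))
  s1 <- 500L
  s2 <- 500L + 2000L + 500L + 3000L + 500L
  arr <- data.frame(array_id = c("a1", "a2"), family_id = "A",
                    contig = "c1",
                    start = c(s1, s2), end = c(s1 + 2000L, s2 + 1500L),
                    stringsAsFactors = FALSE)
  fs <- flank_similarity(arr, g, flank = 500L)
  expect_equal(dim(fs$identity), c(4L, 4L))
  expect_true(all(diag(fs$identity) == 100))
  expect_equal(fs$identity, t(fs$identity))
  expect_true(all(fs$identity[c("a1_up", "a1_down"),
                              c("a2_up", "a2_down")] == 100))
})

test_that("nearest-family distances match the exhaustive scan", {
  x <- data.frame(array_id = c("x1", "x2"), contig = "c1", strand = ".",
                  start = c(0L, 5000L), end = c(100L, 5100L),
                  stringsAsFactors = FALSE)
  y <- data.frame(array_id = c("y1", "y2"), contig = "c1", strand = ".",
                  start = c(200L, 4000L), end = c(300L, 4100L),
                  stringsAsFactors = FALSE)
  nd <- nearest_family_distance(x, y)
  expect_equal(nd$table$distance, c(100L, 900L))
  expect_equal(nd$median_distance, 500)

  set.seed(60)
  xs <- random_intervals(30)
  xs$array_id <- sprintf("x%02d", seq_len(nrow(xs)))
  ys <- random_intervals(30)
  ys$array_id <- sprintf("y%02d", seq_len(nrow(ys)))
  nd2 <- nearest_family_distance(xs, ys)
  for (i in seq_len(nrow(xs))) {
    on <- which(ys$contig == xs$contig[i])
    if (length(on) == 0) {
      expect_true(is.na(nd2$table$distance[i]))
    } else {
      d <- vapply(on, function(j) max(0L, max(ys$start[j] - xs$end[i],
                                              xs$start[i] - ys$end[j])), 0L)
      expect_equal(nd2$table$distance[i], min(d))
    }
  }
})
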