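mk_stranded <- function(starts, strands, L = 110L, fam = "f1") {
  intervals(contig = "c1", start = as.integer(starts),
            end = as.integer(starts + L), strand = strands,
            family_id = fam, percent_identity = 95,
            query_coverage = 100, score = 100)
}

sym_families <- function(L = 110L) {
  set.seed(321)
  list(f1 = sat_family("f1", random_dna(L)))
}

test_that("subarray decomposition reports alternating blocks and midpoints", {
  fams <- sym_families()
  all_plus <- build_arrays(mk_stranded(seq(0, by = 110, length.out = 4),
                                       "+"), fams)
  d1 <- decompose_subarrays(all_plus, fams)
  expect_equal(nrow(d1$subarrays), 1L)
  expect_equal(d1$subarrays$strand, "+")
  expect_equal(nrow(d1$inversions), 0L)

  ppmm <- build_arrays(mk_stranded(seq(0, by = 110, length.out = 4),
                                   c("+", "+", "-", "-")), fams)
  d2 <- decompose_subarrays(ppmm, fams)
  expect_equal(d2$subarrays$strand, c("+", "-"))
  expect_equal(d2$subarrays$monomer_count, c(2L, 2L))
  expect_equal(nrow(d2$inversions), 1L)
  expect_equal(d2$inversions$position, 220L)
  expect_equal(d2$inversions$left_strand, "+")
  expect_equal(d2$inversions$right_strand, "-")

  # conservation and alternation across a mixed pattern
  mixed <- build_arrays(mk_stranded(seq(0, by = 110, length.out = 7),
                                    c("+", "+", "-", "-", "-", "+", "+")),
                        fams)
  d3 <- decompose_subarrays(mixed, fams)
  expect_equal(sum(d3$subarrays$monomer_count), 7L)
  expect_true(all(d3$subarrays$strand[-1] !=
                    d3$subarrays$strand[-nrow(d3$subarrays)]))
})

test_that("planted subarray structure is recovered from the simulation", {
  sim <- small_sim()
  ann <- small_annotation()
  dec <- ann$decomposition
  truth_inv <- sim$truth$inversions
  expect_equal(nrow(dec$inversions), nrow(truth_inv))
  err <- vapply(seq_len(nrow(truth_inv)), function(i) {
    min(abs(dec$inversions$position - truth_inv$position[i]))
  }, 0)
  expect_true(all(err <= 5))
  # block counts per truth array match
  truth_blocks <- table(sim$truth$subarrays$array_id)
  arr_match <- truth_compare(ann$arrays$arrays, sim$truth$arrays)
  for (r in seq_len(nrow(arr_match$matches))) {
    taid <- sim$truth$arrays$array_id[arr_match$matches$truth_row[r]]
    paid <- ann$arrays$arrays$array_id[arr_match$matches$predicted_row[r]]
    if (taid %in% names(truth_blocks)) {
      expect_equal(sum(dec$subarrays$array_id == paid),
                   unname(truth_blocks[taid]))
    }
  }
})

test_that("reverse-complementing the genome mirrors the decomposition", {
  tp <- toy_plant(seed = 90, n_copies = 1, divergence = 0)
  # build +- array: consensus tandem then its reverse complement
  cons <- tp$consensus
  set.seed(90)
  left <- random_dna(3000)
  arrseq <- paste0(strrep(cons, 3),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(strrep(cons, 2)))))
  g <- Biostrings::DNAStringSet(c(chr1 = paste0(left, arrseq,
                                                random_dna(3000))))
  fams <- list(fam1 = sat_family("fam1", cons))
  run <- function(genome) {
    arrays <- build_arrays(
      resolve_overlaps(search_monomers(genome, fams)), fams)
    decompose_subarrays(arrays, fams)
  }
  d_fwd <- run(g)
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  d_rev <- run(rc)
  L <- Biostrings::width(g)[1]
  expect_equal(nrow(d_rev$inversions), nrow(d_fwd$inversions))
  expect_equal(d_rev$subarrays$strand,
               rev(ifelse(d_fwd$subarrays$strand == "+", "-", "+")))
  expect_true(all(abs(sort(L - d_rev$inversions$position) -
                        sort(d_fwd$inversions$position)) <= 1))
})

test_that("macro-dyad metrics quantify flanking block symmetry", {
  sub <- data.frame(array_id = "a1", family_id = "f1", contig = "c1",
                    start = c(0L, 10000L), end = c(10000L, 20000L),
                    strand = c("+", "-"), monomer_count = c(90L, 90L),
                    block_index = 1:2, stringsAsFactors = FALSE)
  m <- macrodyad_metrics(list(subarrays = sub))
  expect_equal(m$per_array$n_subarrays, 2L)
  expect_equal(m$per_inversion$direct_inverted_diff, 0)
  expect_equal(m$per_array$symmetry_span, 20000)

  sub$end <- c(8000L, 20000L); sub$start <- c(0L, 8000L)
  m2 <- macrodyad_metrics(list(subarrays = sub))
  expect_equal(m2$per_inversion$direct_inverted_diff, 8000 - 12000)
  expect_equal(m2$per_array$symmetry_span, 20000)

  # symmetric length law: signed differences centered at zero
  set.seed(44)
  diffs <- replicate(300, {
    lw <- round(rlnorm(1, log(5000), 0.4))
    rw <- round(rlnorm(1, log(5000), 0.4))
    s <- data.frame(array_id = "a", family_id = "f", contig = "c",
                    start = c(0L, lw), end = c(lw, lw + rw),
                    strand = c("+", "-"), monomer_count = 1L,
                    block_index = 1:2, stringsAsFactors = FALSE)
    macrodyad_metrics(list(subarrays = s))$per_inversion$direct_inverted_diff
  })
  expect_lt(abs(mean(diffs)), 0.1 * sd(diffs))
})

test_that("inversion-site windows are extracted and truncations flagged", {
  set.seed(6)
  g <- Biostrings::DNAStringSet(c(c1 = random_dna(2000)))
  pts <- data.frame(array_id = c("a", "b"), family_id = "f",
                    contig = "c1", position = c(1000L, 50L),
                    left_strand = "+", right_strand = "-",
                    stringsAsFactors = FALSE)
  sites <- extract_inversion_sites(pts, g, window_radius = 200L)
  expect_equal(sites$start, c(800L, 0L))
  expect_equal(sites$end, c(1200L, 250L))
  expect_equal(sites$truncated, c(FALSE, TRUE))
  expect_equal(sites$sequence[1],
               as.character(Biostrings::subseq(g[[1]], 801, 1200)))
  bad <- pts; bad$position <- 5000L
  expect_error(extract_inversion_sites(bad, g), "outside contig")
})

test_that("site clustering separates planted variants and matches components", {
  set.seed(14)
  canon <- random_dna(170)
  variant <- local({
    ch <- strsplit(canon, "")[[1]]
    pos <- sample(170, 12)
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    paste(ch, collapse = "")
  })
  sites <- c(vapply(1:12, function(i) mutate_copy(canon, 0.02), ""),
             vapply(1:9, function(i) mutate_copy(variant, 0.02), ""))
  truth_lab <- rep(c(1, 2), c(12, 9))
  cl <- cluster_sites(sites, identity_threshold = 95)
  expect_equal(nrow(cl$clusters[!cl$clusters$minor, ]), 2L)
  expect_equal(length(unique(cl$assignments[truth_lab == 1])), 1L)
  expect_equal(length(unique(cl$assignments[truth_lab == 2])), 1L)
  expect_false(any(cl$assignments[truth_lab == 1] %in%
                     cl$assignments[truth_lab == 2]))

  ident <- cluster_sites(rep(canon, 10))
  expect_equal(nrow(ident$clusters), 1L)
  expect_equal(ident$clusters$mean_pairwise_identity, 100)

  # partition equals connected components of the identity graph
  idm <- satarch:::pairwise_identity_matrix(sites)
  gr <- igraph::graph_from_adjacency_matrix(idm >= 95, mode = "undirected",
                                            diag = FALSE)
  comp <- igraph::components(gr)$membership
  expect_equal(length(unique(cl$assignments)), max(comp))
  for (k in unique(comp)) {
    expect_equal(length(unique(cl$assignments[comp == k])), 1L)
  }
})

test_that("site divergence is the complement of global identity", {
  set.seed(8)
  s <- random_dna(100)
  expect_equal(site_divergence(s, s), 0)
  ch <- strsplit(s, "")[[1]]
  pos <- sample(100, 10)
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  expect_equal(site_divergence(paste(ch, collapse = ""), s), 10)
  # scripted edits on a longer sequence recover the implied divergence
  long <- random_dna(400)
  mut <- mutate_copy(long, 0.08, seed = 5)
  implied <- 100 * mean(strsplit(long, "")[[1]] != strsplit(mut, "")[[1]])
  expect_lt(abs(site_divergence(mut, long) - implied), 0.5)
})
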