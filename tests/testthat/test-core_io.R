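test_that("FASTA loading folds case, maps ambiguity to N, validates ids", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">ctgA desc", "acgtACGT", ">ctgB", "ACGRT"), fa)
  expect_warning(seqs <- load_sequences(fa), "1 non-ACGTN")
  expect_equal(names(seqs), c("ctgA", "ctgB"))
  expect_equal(as.character(seqs[["ctgA"]]), "ACGTACGT")
  expect_equal(as.character(seqs[["ctgB"]]), "ACGNT")
  expect_equal(unname(Biostrings::width(seqs)), c(8L, 5L))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "ACGT", ">x", "AAAA"), dup)
  expect_error(load_sequences(dup), "duplicate contig ids")
  expect_error(load_sequences(file.path(tempdir(), "nope.fa")), "not found")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(load_sequences(empty), "no records")
})

test_that("GFF3 and BED round-trip features exactly", {
  feats <- intervals(contig = c("c1", "c1", "c2"),
                     start = c(0L, 99L, 5L), end = c(50L, 200L, 6L),
                     strand = c("+", "-", "."),
                     type = "satellite_monomer",
                     family_id = c("fam1", "fam2", "fam;odd=1"),
                     score_val = c("1.5", "2", "3"))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(feats, gff)
  back <- read_gff3(gff)
  expect_equal(back[, names(feats)], feats)

  bed <- withr::local_tempfile(fileext = ".bed")
  iv <- intervals(contig = "c1", start = c(0L, 10L), end = c(5L, 20L),
                  strand = c("+", "."), name = c("a", "b"),
                  score = c("0", "7"))
  write_bed(iv, bed)
  expect_equal(read_bed(bed)[, names(iv)], iv)
})

test_that("interval_merge handles abutting and distant intervals", {
  m <- interval_merge(intervals(contig = "c", start = c(0L, 10L),
                                end = c(10L, 20L)), max_gap = 0L)
  expect_equal(m$start, 0L)
  expect_equal(m$end, 20L)
  m2 <- interval_merge(intervals(contig = "c", start = c(0L, 25L),
                                 end = c(10L, 30L)), max_gap = 10L)
  expect_equal(nrow(m2), 2L)
  expect_equal(nrow(interval_merge(intervals(), 5L)), 0L)
})

test_that("interval_merge equals brute-force transitive closure and is idempotent", {
  set.seed(42)
  for (rep in 1:5) {
    iv <- random_intervals(200)
    for (g in c(0L, 3L, 25L)) {
      got <- interval_merge(iv, g)
      exp <- oracle_merge(iv, g)
      expect_equal(got[, c("contig", "start", "end")], exp,
                   ignore_attr = TRUE)
      again <- interval_merge(got[, c("contig", "start", "end", "strand")], g)
      expect_equal(again[, c("contig", "start", "end")],
                   got[, c("contig", "start", "end")])
    }
  }
})

test_that("interval_subtract splits, removes and conserves bases", {
  r <- interval_subtract(intervals(contig = "c", start = 0L, end = 100L),
                         intervals(contig = "c", start = 40L, end = 60L))
  expect_equal(r$start, c(0L, 60L))
  expect_equal(r$end, c(40L, 100L))
  gone <- interval_subtract(intervals(contig = "c", start = 10L, end = 20L),
                            intervals(contig = "c", start = 0L, end = 50L))
  expect_equal(nrow(gone), 0L)

  set.seed(7)
  for (rep in 1:5) {
    iv <- random_intervals(80, span = 1500L)
    mask <- random_intervals(40, span = 1500L)
    got <- interval_subtract(iv, mask)
    exp <- oracle_subtract(iv, mask)
    expect_equal(got[, c("contig", "start", "end", "source")],
                 exp, ignore_attr = TRUE)
    # conservation: bp(items) = bp(result) + bp(items intersect mask)
    masked_bp <- sum(vapply(seq_len(nrow(iv)), function(i) {
      m <- mask[mask$contig == iv$contig[i], , drop = FALSE]
      if (nrow(m) == 0) return(0L)
      mr <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
      sum(IRanges::width(IRanges::intersect(
        IRanges::IRanges(iv$start[i] + 1L, iv$end[i]), mr)))
    }, 0L))
    expect_equal(sum(iv$end - iv$start),
                 sum(got$end - got$start) + masked_bp)
  }
})

test_that("interval_nearest matches an exhaustive scan", {
  r <- interval_nearest(intervals(contig = "c", start = 100L, end = 200L),
                        intervals(contig = "c", start = 300L, end = 400L))
  expect_equal(r$distance, 100L)
  ov <- interval_nearest(intervals(contig = "c", start = 100L, end = 200L),
                         intervals(contig = "c", start = 150L, end = 400L))
  expect_equal(ov$distance, 0L)
  none <- interval_nearest(intervals(contig = "cX", start = 0L, end = 5L),
                           intervals(contig = "c", start = 0L, end = 5L))
  expect_null(none$target)
  expect_true(is.na(none$distance))

  set.seed(11)
  targets <- random_intervals(60)
  for (i in 1:100) {
    q <- random_intervals(1)
    got <- interval_nearest(q, targets)
    on_ctg <- which(targets$contig == q$contig)
    if (length(on_ctg) == 0) {
      expect_true(is.na(got$distance))
    } else {
      d <- vapply(on_ctg, function(j) {
        max(0L, max(targets$start[j] - q$end, q$start - targets$end[j]))
      }, 0L)
      expect_equal(got$distance, min(d))
      # tie-break: leftmost target start among minimizers
      mins <- on_ctg[d == min(d)]
      expect_equal(got$target$start,
                   min(targets$start[mins]))
    }
  }
})
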