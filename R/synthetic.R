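# Synthetic genomes with planted satellite architecture and complete ground
# truth. The generator emulates the study conditions the pipeline is built
# for: an A+T-rich background (70%), a two-subunit major satellite and a
# seven-subunit minor satellite sharing a diverged ancestral ~110 bp unit,
# multi-kilobase arrays decomposed into oriented subarrays with conserved
# diverged variants at inversion points, conserved transition elements
# between the two intermingled families (one carrying an internal 60 bp
# deletion, one a 124 bp chimeric element with a duplicated 6-mer at the
# breakpoint), variable-copy minor-family "cassettes" embedded in the major
# satellite, and a third family whose monomers alternate with (AC)n
# microsatellite spacers. Per-copy substitution divergence defaults to 5%.

#' Random background sequence
#'
#' i.i.d. bases at a stated A+T fraction (A and T equiprobable, likewise
#' G and C). Uses the current RNG state.
#'
#' @param n length in bp.
#' @param at_fraction target A+T fraction. Default 0.7.
#' @return A character string.
#' @export
random_dna <- function(n, at_fraction = 0.7) {
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c(at_fraction / 2, at_fraction / 2,
                        (1 - at_fraction) / 2, (1 - at_fraction) / 2)),
        collapse = "")
}

#' Mutate a sequence copy
#'
#' Independent per-site substitution with the given probability, uniform
#' over the three alternative bases; no indels. With `seed` the draw is
#' made under a local RNG state (restored afterwards), otherwise the
#' current RNG stream is used.
#'
#' @param consensus template sequence.
#' @param divergence per-site substitution probability in [0, 0.5].
#' @param seed optional integer seed.
#' @return The mutated copy (same length).
#' @export
mutate_copy <- function(consensus, divergence, seed = NULL) {
  stopifnot(divergence >= 0, divergence <= 0.5)
  if (!is.null(seed)) return(withr_seed(seed, mutate_copy(consensus, divergence)))
  if (divergence == 0) return(consensus)
  ch <- strsplit(consensus, "")[[1]]
  hit <- which(stats::runif(length(ch)) < divergence)
  if (length(hit) > 0) {
    alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(b) sample(alts[[b]], 1), "")
  }
  paste(ch, collapse = "")
}

# Truncate or extend a sequence to length L (extension with fresh random
# background at the given A+T fraction).
.resize_seq <- function(s, L, at_fraction = 0.7) {
  n <- nchar(s)
  if (n >= L) return(substr(s, 1, L))
  paste0(s, random_dna(L - n, at_fraction))
}

.splice_in <- function(s, offset, insert) {
  # overwrite s at 0-based offset with insert
  paste0(substr(s, 1, offset), insert,
         substr(s, offset + nchar(insert) + 1L, nchar(s)))
}

#' Generate a satellite family from a specification
#'
#' Builds a base subunit (or takes one), derives sibling subunits at stated
#' divergences, optionally replaces a designated subunit with the verbatim
#' reverse complement of another (the intra-monomer inverted block), plants
#' literal motifs, and assembles the monomer with optional head/tail
#' sequences (e.g. terminal microsatellite tracts).
#'
#' @param spec list with fields `family_id`, `subunit_lengths` (integer
#'   vector, optionally named), `subunit_divergence` (same length),
#'   optional `base_seq`, `base_length`, `at_fraction` (default 0.7),
#'   `inverted_block` (list `source`, `target`: subunit indices),
#'   `motif_plant` (list of lists `subunit`, `offset`, `seq`), `head`,
#'   `tail` (literal sequences).
#' @param seed optional integer seed (local RNG state).
#' @return A [sat_family()] with the realized subunit table.
#' @export
make_family <- function(spec, seed = NULL) {
  if (!is.null(seed)) return(withr_seed(seed, make_family(spec)))
  lens <- as.integer(spec$subunit_lengths)
  divs <- spec$subunit_divergence
  stopifnot(length(lens) == length(divs), all(lens > 0))
  at <- spec$at_fraction %||% 0.7
  base <- spec$base_seq %||% random_dna(spec$base_length %||% lens[1], at)
  subs <- vapply(seq_along(lens), function(i) {
    mutate_copy(.resize_seq(base, lens[i], at), divs[i])
  }, "")
  if (!is.null(spec$inverted_block)) {
    src <- spec$inverted_block$source
    tgt <- spec$inverted_block$target
    subs[tgt] <- .resize_seq(revcomp(subs[src]), lens[tgt], at)
  }
  for (mp in spec$motif_plant %||% list()) {
    subs[mp$subunit] <- .splice_in(subs[mp$subunit], mp$offset, mp$seq)
  }
  head <- spec$head %||% ""
  tail <- spec$tail %||% ""
  consensus <- paste0(head, paste(subs, collapse = ""), tail)
  names <- names(spec$subunit_lengths) %||%
    sprintf("sub_%s", LETTERS[seq_along(lens)])
  offsets <- nchar(head) + cumsum(c(0L, lens[-length(lens)]))
  sat_family(spec$family_id, consensus,
             subunits = data.frame(name = names, offset = offsets,
                                   length = lens, stringsAsFactors = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default synthetic architecture
#'
#' The study conditions the package is validated under: a 5 Mb background
#' at 70% A+T carrying 40 planted major/minor loci -- 20 cassettes (minor
#' array embedded in the major satellite between two conserved transition
#' elements, with an internal inversion; each element independently present
#' at the stated triple rate), 12 plain major arrays (subarray counts 1-3),
#' 8 standalone minor arrays -- plus 6 arrays of a third family whose
#' monomers alternate with (AC)n spacers, and 30 decoy (AC)n runs in the
#' background. Per-copy divergence 5%; transition and inversion-site
#' variants conserved at 1%.
#'
#' @param seed integer seed driving every draw.
#' @param genome_length genome size in bp. Default 5e6.
#' @param n_cassettes,n_major_plain,n_minor_plain,n_spacer_arrays,n_decoys
#'   locus counts.
#' @param divergence per-copy substitution divergence. Default 0.05.
#' @param triple_rate probability that a cassette carries all three
#'   conserved elements. Default 0.59.
#' @param background_at background A+T fraction. Default 0.70.
#' @return List of class `architecture_spec`.
#' @export
default_architecture <- function(seed = 42L, genome_length = 5e6,
                                 n_cassettes = 20L, n_major_plain = 12L,
                                 n_minor_plain = 8L, n_spacer_arrays = 6L,
                                 n_decoys = 30L, divergence = 0.05,
                                 triple_rate = 0.59,
                                 background_at = 0.70) {
  structure(list(
    seed = as.integer(seed),
    genome_length = genome_length,
    background_at = background_at,
    divergence = divergence,
    element_noise = 0.01,
    n_cassettes = n_cassettes,
    n_major_plain = n_major_plain,
    n_minor_plain = n_minor_plain,
    n_spacer_arrays = n_spacer_arrays,
    n_decoys = n_decoys,
    triple_rate = triple_rate,
    # copy-number laws
    major_copies_meanlog = log(30), major_copies_sdlog = 0.4,
    cassette_flank_meanlog = log(15), cassette_flank_sdlog = 0.35,
    minor_copies_min = 2L, minor_copies_p = 0.35,
    spacer_monomers_min = 5L, spacer_monomers_p = 0.3,
    # subarray count law for plain major arrays (1, 2 or 3 blocks)
    subarray_probs = c(0.3, 0.55, 0.15),
    # microsatellite unit-count laws (units = min + geometric)
    spacer_units_min = 5L, spacer_units_p = 0.04,
    decoy_units_min = 5L, decoy_units_p = 0.45,
    min_locus_gap = 2000L,
    min_units = 5L, link_gap = 100L),
    class = "architecture_spec")
}

# The three default families plus fixed variant/transition elements.
# Consumes the current RNG stream.
.default_elements <- function(spec) {
  base <- random_dna(110, spec$background_at)
  major <- make_family(list(
    family_id = "satMaj",
    subunit_lengths = c(maj_1 = 110L, maj_2 = 115L),
    subunit_divergence = c(0.05, 0.15),
    base_seq = base,
    motif_plant = list(list(subunit = 2L, offset = 20L, seq = "TTCAAT"))))
  minor <- make_family(list(
    family_id = "satMin",
    subunit_lengths = c(sub_A = 100L, sub_B = 96L, sub_C = 110L,
                        sub_D = 110L, sub_E = 59L, sub_F = 116L,
                        sub_G = 113L),
    subunit_divergence = c(0.30, 0.34, 0.32, 0.32, 0.38, 0.33, 0.36),
    base_seq = mutate_copy(base, 0.20),
    inverted_block = list(source = 3L, target = 4L),
    motif_plant = list(list(subunit = 2L, offset = 40L, seq = "TTCAAT"))))
  spacer <- make_family(list(
    family_id = "satSpc",
    subunit_lengths = c(body = 676L),
    subunit_divergence = 0,
    base_length = 676L,
    head = "ACACACACAC", tail = "ACACAC"))
  maj_cons <- major$consensus
  min_cons <- minor$consensus
  # inversion-site variants: degenerate copies of the boundary-adjacent
  # subunit span, conserved across sites
  u2 <- substr(maj_cons, 111, 225)
  inv_1a <- mutate_copy(u2, 0.235)
  inv_1b <- mutate_copy(u2, 0.107)
  fg_span <- substr(min_cons, 704 - 229 + 1, 704)    # sub_F + sub_G
  pos12 <- sort(sample(nchar(fg_span), 12))
  ch <- strsplit(fg_span, "")[[1]]
  alts <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
               G = c("A", "C", "T"), T = c("A", "C", "G"))
  ch[pos12] <- vapply(ch[pos12], function(b) sample(alts[[b]], 1), "")
  inv_2 <- paste(ch, collapse = "")
  # transition elements
  trans1_m1 <- mutate_copy(maj_cons, 0.178)        # annotated, ~82% id
  m2 <- mutate_copy(maj_cons, 0.33)                # below threshold
  trans1_m2 <- paste0(substr(m2, 1, 135), substr(m2, 196, 225))  # 60 bp del
  # chimeric element: minor donor segment ending TTCAAT + major donor
  # segment starting TTCAAT (duplicated 6-mer at the breakpoint)
  min_cut <- 100L + 40L + 6L                       # end of planted motif in sub_B
  maj_cut <- 110L + 20L                            # motif start in maj_2
  trans2 <- paste0(substr(min_cons, min_cut - 59L, min_cut),
                   substr(maj_cons, maj_cut + 1L, maj_cut + 64L))
  list(families = list(satMaj = major, satMin = minor, satSpc = spacer),
       variants = list(inv_1a = inv_1a, inv_1b = inv_1b, inv_2 = inv_2),
       trans1_m2 = trans1_m2, trans1_m1 = trans1_m1, trans2 = trans2,
       variant_span = list(satMaj = c(110L, 115L), satMin = c(475L, 229L)))
}

# One oriented block of monomer copies. Returns list(seq, monomers) with
# local 0-based monomer intervals. head_variant (if given) replaces the
# span (0-based offset, length) in the genomically-first copy before
# orientation, emulating the degenerate subunit at an inversion point.
.build_block <- function(family, n, strand, divergence,
                         head_variant = NULL, variant_span = NULL) {
  L <- family$monomer_length
  copies <- vapply(seq_len(n), function(i) {
    mutate_copy(family$consensus, divergence)
  }, "")
  if (!is.null(head_variant)) {
    copies[1] <- .splice_in(copies[1], variant_span[1], head_variant)
  }
  if (strand == "-") copies <- revcomp(copies)
  list(seq = paste(copies, collapse = ""),
       monomers = data.frame(start = (seq_len(n) - 1L) * L,
                             end = seq_len(n) * L,
                             strand = strand,
                             family_id = family$family_id,
                             stringsAsFactors = FALSE))
}

# Multi-block array with alternating orientations starting "+". Variants
# are planted at every +- boundary in the minus block's boundary-adjacent
# subunit. Returns list(seq, monomers, blocks, inversions).
.build_array <- function(family, copy_counts, elements, spec,
                         variant_names = NULL) {
  strands <- rep(c("+", "-"), length.out = length(copy_counts))
  vs <- elements$variant_span[[family$family_id]]
  pieces <- list()
  offset <- 0L
  monomers <- list()
  blocks <- list()
  inversions <- list()
  for (b in seq_along(copy_counts)) {
    hv <- NULL
    vname <- NA_character_
    if (strands[b] == "-" && b > 1) {
      vname <- if (is.null(variant_names)) NA_character_ else
        variant_names[[min(b - 1, length(variant_names))]]
      if (!is.na(vname)) {
        hv <- mutate_copy(elements$variants[[vname]], spec$element_noise)
      }
    }
    blk <- .build_block(family, copy_counts[b], strands[b],
                        spec$divergence, head_variant = hv,
                        variant_span = vs)
    m <- blk$monomers
    m$start <- m$start + offset
    m$end <- m$end + offset
    monomers[[b]] <- m
    blocks[[b]] <- data.frame(start = offset,
                              end = offset + nchar(blk$seq),
                              strand = strands[b],
                              monomer_count = copy_counts[b],
                              stringsAsFactors = FALSE)
    if (b > 1) {
      inversions[[b]] <- data.frame(position = offset,
                                    variant = vname,
                                    stringsAsFactors = FALSE)
    }
    pieces[[b]] <- blk$seq
    offset <- offset + nchar(blk$seq)
  }
  list(seq = paste(unlist(pieces), collapse = ""),
       monomers = do.call(rbind, monomers),
       blocks = do.call(rbind, blocks),
       inversions = if (length(inversions)) do.call(rbind, inversions) else
         data.frame(position = integer(), variant = character(),
                    stringsAsFactors = FALSE))
}

.draw_lognormal_count <- function(meanlog, sdlog, min = 2L, max = 120L) {
  as.integer(pmin(max, pmax(min, round(stats::rlnorm(1, meanlog, sdlog)))))
}

# A cassette locus: [major block][TRANS_2][minor array][TRANS_1][major
# block]. Each of the three conserved elements (TRANS_2, internal
# inversion, TRANS_1) is present in all-or-part per the triple-rate draw.
# Returns list(seq, parts) where parts carries local truth features.
.build_cassette <- function(elements, spec) {
  maj <- elements$families$satMaj
  mnr <- elements$families$satMin
  triple <- stats::runif(1) < spec$triple_rate
  present <- c(trans2 = TRUE, inv = TRUE, trans1 = TRUE)
  if (!triple) present[sample(3, 1)] <- FALSE
  nL <- .draw_lognormal_count(spec$cassette_flank_meanlog,
                              spec$cassette_flank_sdlog, min = 3L)
  nR <- .draw_lognormal_count(spec$cassette_flank_meanlog,
                              spec$cassette_flank_sdlog, min = 3L)
  n_min <- spec$minor_copies_min + stats::rgeom(1, spec$minor_copies_p)
  parts <- list()
  seqs <- character()
  offset <- 0L
  add <- function(seq, what, meta = list()) {
    parts[[length(parts) + 1L]] <<- c(list(start = offset,
                                           end = offset + nchar(seq),
                                           what = what), meta)
    seqs[length(seqs) + 1L] <<- seq
    offset <<- offset + nchar(seq)
  }
  majL <- .build_block(maj, nL, "+", spec$divergence)
  add(majL$seq, "major_block", list(monomers = majL$monomers))
  if (present["trans2"]) {
    add(mutate_copy(elements$trans2, spec$element_noise), "trans2")
  }
  if (present["inv"] && n_min >= 2) {
    k <- max(1L, n_min %/% 2L)
    arr <- .build_array(mnr, c(k, n_min - k), elements, spec,
                        variant_names = "inv_2")
  } else {
    present["inv"] <- FALSE
    arr <- .build_array(mnr, n_min, elements, spec)
  }
  add(arr$seq, "minor_array",
      list(monomers = arr$monomers, blocks = arr$blocks,
           inversions = arr$inversions))
  if (present["trans1"]) {
    add(mutate_copy(elements$trans1_m2, spec$element_noise), "trans1_m2")
    majR_head <- mutate_copy(elements$trans1_m1, spec$element_noise)
  } else {
    majR_head <- NULL
  }
  majR <- .build_block(maj, nR, "+", spec$divergence)
  if (!is.null(majR_head)) {
    # the conserved diverged monomer is the first monomer of the right
    # major array (annotatable at ~82% identity)
    majR$seq <- paste0(majR_head, majR$seq)
    majR$monomers$start <- majR$monomers$start + nchar(majR_head)
    majR$monomers$end <- majR$monomers$end + nchar(majR_head)
    majR$monomers <- rbind(
      data.frame(start = 0L, end = nchar(majR_head), strand = "+",
                 family_id = maj$family_id, stringsAsFactors = FALSE),
      majR$monomers)
  }
  add(majR$seq, "major_block", list(monomers = majR$monomers))
  list(seq = paste(seqs, collapse = ""), parts = parts,
       present = present, n_minor = n_min)
}

# A spacer-family locus: monomers alternating with (AC)n spacers.
.build_spacer_array <- function(elements, spec) {
  fam <- elements$families$satSpc
  n <- spec$spacer_monomers_min + stats::rgeom(1, spec$spacer_monomers_p)
  n <- min(n, 15L)
  seqs <- character()
  monomers <- list()
  spacers <- list()
  offset <- 0L
  for (i in seq_len(n)) {
    m <- mutate_copy(fam$consensus, spec$divergence)
    monomers[[i]] <- data.frame(start = offset, end = offset + nchar(m),
                                strand = "+", family_id = fam$family_id,
                                stringsAsFactors = FALSE)
    seqs[length(seqs) + 1L] <- m
    offset <- offset + nchar(m)
    if (i < n) {
      u <- min(spec$spacer_units_min + stats::rgeom(1, spec$spacer_units_p),
               200L)
      run <- strrep("AC", u)
      spacers[[i]] <- data.frame(start = offset, end = offset + 2L * u,
                                 units = u, stringsAsFactors = FALSE)
      seqs[length(seqs) + 1L] <- run
      offset <- offset + 2L * u
    }
  }
  list(seq = paste(seqs, collapse = ""),
       monomers = do.call(rbind, monomers),
       spacers = do.call(rbind, spacers))
}

#' Plant a synthetic satellite architecture
#'
#' Realizes an [default_architecture()] specification: generates the three
#' families and their conserved elements, builds every locus, interleaves
#' loci with background gaps of at least `min_locus_gap` bp, and emits the
#' assembled genome together with complete ground truth. Identical spec and
#' seed give byte-identical output.
#'
#' @param spec an `architecture_spec`.
#' @return List of class `sat_simulation` with `genome` (single-contig
#'   `DNAStringSet`, contig `ctg_sim`), `families` (named [sat_family()]
#'   list), `elements` (variant and transition sequences) and `truth`
#'   (list of data frames: `monomers`, `arrays`, `subarrays`, `inversions`,
#'   `transitions`, `cassettes`, `microsat`).
#' @export
plant_architecture <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(spec$seed)
  elements <- .default_elements(spec)
  ctg <- "ctg_sim"
  loci <- list()
  add_locus <- function(kind, built) {
    loci[[length(loci) + 1L]] <<- list(kind = kind, built = built)
  }
  for (i in seq_len(spec$n_cassettes)) {
    add_locus("cassette", .build_cassette(elements, spec))
  }
  for (i in seq_len(spec$n_major_plain)) {
    nb <- sample(1:3, 1, prob = spec$subarray_probs)
    total <- .draw_lognormal_count(spec$major_copies_meanlog,
                                   spec$major_copies_sdlog, min = nb + 2L)
    cuts <- sort(sample(seq_len(total - 1L), nb - 1L))
    counts <- diff(c(0L, cuts, total))
    vn <- as.list(rep(c("inv_1a", "inv_1b"), length.out = max(1, nb - 1)))
    # variants are planted only at +- boundaries (odd boundary indices)
    if (nb == 3) vn[[2]] <- NA_character_
    arr <- .build_array(elements$families$satMaj, counts, elements, spec,
                        variant_names = vn)
    add_locus("major_plain", arr)
  }
  for (i in seq_len(spec$n_minor_plain)) {
    n <- spec$minor_copies_min + stats::rgeom(1, spec$minor_copies_p)
    if (i %% 2 == 0 && n >= 2) {
      k <- max(1L, n %/% 2L)
      arr <- .build_array(elements$families$satMin, c(k, n - k), elements,
                          spec, variant_names = "inv_2")
    } else {
      arr <- .build_array(elements$families$satMin, n, elements, spec)
    }
    add_locus("minor_plain", arr)
  }
  for (i in seq_len(spec$n_spacer_arrays)) {
    add_locus("spacer_array", .build_spacer_array(elements, spec))
  }
  for (i in seq_len(spec$n_decoys)) {
    u <- min(spec$decoy_units_min + stats::rgeom(1, spec$decoy_units_p), 50L)
    add_locus("decoy", list(seq = strrep("AC", u), units = u))
  }
  loci <- loci[sample(length(loci))]
  locus_len <- vapply(loci, function(l) nchar(l$built$seq), 0)
  n_gaps <- length(loci) + 1L
  total_bg <- spec$genome_length - sum(locus_len)
  if (total_bg < n_gaps * spec$min_locus_gap) {
    stop("infeasible packing: planted ", sum(locus_len),
         " bp exceeds genome_length minus minimum gaps")
  }
  extra <- as.vector(stats::rmultinom(1, total_bg - n_gaps * spec$min_locus_gap,
                                      rep(1, n_gaps)))
  gaps <- spec$min_locus_gap + extra
  # assemble and lift truth to genome coordinates
  truth <- .assemble_truth(loci, gaps, spec, elements, ctg)
  genome <- Biostrings::DNAStringSet(stats::setNames(truth$genome_seq, ctg))
  truth$genome_seq <- NULL
  # microsatellite ground truth from the final sequence (includes
  # background-emergent runs), labeled from planted spacer monomers
  runs <- find_dinuc_runs(genome, "AC", spec$min_units)
  spc_mono <- truth$monomers[truth$monomers$family_id == "satSpc", ,
                             drop = FALSE]
  trimmed <- interval_subtract(runs, spc_mono)
  if (nrow(trimmed) > 0) {
    trimmed$units <- (trimmed$end - trimmed$start) %/% 2L
    trimmed$linked <- FALSE
    if (nrow(spc_mono) > 0) {
      for (i in seq_len(nrow(trimmed))) {
        nn <- interval_nearest(trimmed[i, , drop = FALSE], spc_mono)
        trimmed$linked[i] <- !is.null(nn$target) &&
          nn$distance <= spec$link_gap
      }
    }
    trimmed$source <- NULL
  } else {
    trimmed$units <- integer(); trimmed$linked <- logical()
    trimmed$source <- NULL
  }
  truth$microsat <- trimmed
  structure(list(genome = genome,
                 families = elements$families,
                 elements = elements[c("variants", "trans1_m1", "trans1_m2",
                                       "trans2")],
                 truth = truth,
                 spec = spec),
            class = "sat_simulation")
}

# Lift local locus features to genome coordinates and build the truth
# tables. Arrays of one family separated by foreign material (transition
# elements, minor cassettes) are recorded as separate arrays, matching the
# single-family gap-merge definition used by the pipeline.
.assemble_truth <- function(loci, gaps, spec, elements, ctg) {
  seqs <- character(2L * length(loci) + 1L)
  monomers <- list(); arrays <- list(); subarrays <- list()
  inversions <- list(); transitions <- list(); cassettes <- list()
  pos <- 0L
  arr_serial <- 0L
  new_arr_id <- function(fam) {
    arr_serial <<- arr_serial + 1L
    sprintf("truth_%s_%04d", fam, arr_serial)
  }
  shift_df <- function(df, off, cols = c("start", "end")) {
    for (cn in intersect(cols, names(df))) df[[cn]] <- df[[cn]] + off
    if ("position" %in% names(df)) df$position <- df$position + off
    df
  }
  reg_array <- function(fam, off, mono, blocks = NULL, invs = NULL,
                        role = "plain") {
    aid <- new_arr_id(fam)
    mono <- shift_df(mono, off)
    mono$array_id <- aid
    monomers[[length(monomers) + 1L]] <<- mono
    arrays[[length(arrays) + 1L]] <<- data.frame(
      array_id = aid, family_id = fam, contig = ctg,
      start = min(mono$start), end = max(mono$end), strand = ".",
      monomer_count = nrow(mono), role = role, stringsAsFactors = FALSE)
    if (!is.null(blocks) && nrow(blocks) > 0) {
      b <- shift_df(blocks, off)
      b$array_id <- aid
      subarrays[[length(subarrays) + 1L]] <<- b
    }
    if (!is.null(invs) && nrow(invs) > 0) {
      iv <- shift_df(invs, off)
      iv$array_id <- aid
      iv$contig <- ctg
      inversions[[length(inversions) + 1L]] <<- iv
    }
    aid
  }
  si <- 0L
  for (li in seq_along(loci)) {
    si <- si + 1L
    seqs[si] <- random_dna(gaps[li], spec$background_at)
    pos <- pos + gaps[li]
    l <- loci[[li]]
    b <- l$built
    si <- si + 1L
    seqs[si] <- b$seq
    if (l$kind %in% c("major_plain", "minor_plain")) {
      fam <- b$monomers$family_id[1]
      reg_array(fam, pos, b$monomers, b$blocks, b$inversions)
    } else if (l$kind == "spacer_array") {
      reg_array("satSpc", pos, b$monomers, role = "spacer")
    } else if (l$kind == "cassette") {
      cass_id <- sprintf("cassette_%03d", length(cassettes) + 1L)
      minor_aid <- NA_character_
      for (p in b$parts) {
        off <- pos + p$start
        if (p$what == "major_block") {
          reg_array("satMaj", pos + 0L, shift_df(p$monomers, p$start),
                    role = "cassette_flank")
        } else if (p$what == "minor_array") {
          minor_aid <- reg_array("satMin", pos + 0L,
                                 shift_df(p$monomers, p$start),
                                 shift_df(p$blocks, p$start),
                                 shift_df(p$inversions, p$start),
                                 role = "cassette_minor")
        } else {
          transitions[[length(transitions) + 1L]] <- data.frame(
            cassette_id = cass_id, contig = ctg, start = off,
            end = pos + p$end, strand = ".",
            type = if (p$what == "trans2") "trans_short" else "trans_long",
            stringsAsFactors = FALSE)
        }
      }
      cassettes[[length(cassettes) + 1L]] <- data.frame(
        cassette_id = cass_id, minor_array_id = minor_aid,
        has_trans_long = unname(b$present["trans1"]),
        has_trans_short = unname(b$present["trans2"]),
        has_inversion = unname(b$present["inv"]),
        stringsAsFactors = FALSE)
    }
    # decoys carry no features here; microsat truth is rebuilt post hoc
    pos <- pos + nchar(b$seq)
  }
  si <- si + 1L
  seqs[si] <- random_dna(gaps[length(gaps)], spec$background_at)
  mono <- do.call(rbind, monomers)
  if (is.null(mono)) {
    mono <- data.frame(contig = character(), start = integer(),
                       end = integer(), strand = character(),
                       family_id = character(), array_id = character(),
                       stringsAsFactors = FALSE)
  } else {
    mono$contig <- ctg
    mono <- sort_intervals(mono)
  }
  arr <- do.call(rbind, arrays)
  arr <- if (is.null(arr)) {
    data.frame(array_id = character(), family_id = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), monomer_count = integer(),
               role = character(), stringsAsFactors = FALSE)
  } else sort_intervals(arr)
  sub <- do.call(rbind, subarrays)
  if (!is.null(sub)) { sub$contig <- ctg; sub <- sort_intervals(sub) }
  inv <- do.call(rbind, inversions)
  trans <- do.call(rbind, transitions)
  list(genome_seq = paste(seqs, collapse = ""),
       monomers = mono, arrays = arr,
       subarrays = sub %||% data.frame(),
       inversions = inv %||% data.frame(position = integer(),
                                        variant = character(),
                                        array_id = character(),
                                        contig = character()),
       transitions = trans %||% data.frame(),
       cassettes = do.call(rbind, cassettes) %||% data.frame())
}

#' Compare predicted features against ground truth
#'
#' Matches predicted to truth intervals by reciprocal overlap (both sides
#' at least `reciprocal_overlap` of their own length), greedily by
#' descending overlap, one-to-one. When both tables carry `family_id`,
#' matches are restricted to equal families.
#'
#' @param predicted,truth interval data frames.
#' @param reciprocal_overlap minimum reciprocal overlap fraction.
#'   Default 0.5.
#' @return List `recall`, `precision`, `n_truth`, `n_predicted`, `matches`
#'   (data frame `truth_row`, `predicted_row`, `start_error`, `end_error`).
#' @export
truth_compare <- function(predicted, truth, reciprocal_overlap = 0.5) {
  n_t <- nrow(truth); n_p <- nrow(predicted)
  empty <- data.frame(truth_row = integer(), predicted_row = integer(),
                      start_error = integer(), end_error = integer())
  if (n_t == 0 || n_p == 0) {
    return(list(recall = if (n_t == 0) NA_real_ else 0,
                precision = if (n_p == 0) NA_real_ else 0,
                n_truth = n_t, n_predicted = n_p, matches = empty))
  }
  cand <- list()
  same_fam <- "family_id" %in% names(predicted) &&
    "family_id" %in% names(truth)
  for (ctg in intersect(unique(truth$contig), unique(predicted$contig))) {
    ti <- which(truth$contig == ctg)
    pi <- which(predicted$contig == ctg)
    ov <- IRanges::findOverlaps(.as_iranges(truth[ti, , drop = FALSE]),
                                .as_iranges(predicted[pi, , drop = FALSE]))
    if (length(ov) == 0) next
    t_idx <- ti[S4Vectors::queryHits(ov)]
    p_idx <- pi[S4Vectors::subjectHits(ov)]
    ov_bp <- pmin(truth$end[t_idx], predicted$end[p_idx]) -
      pmax(truth$start[t_idx], predicted$start[p_idx])
    keep <- ov_bp >= reciprocal_overlap * (truth$end[t_idx] - truth$start[t_idx]) &
      ov_bp >= reciprocal_overlap * (predicted$end[p_idx] - predicted$start[p_idx])
    if (same_fam) {
      keep <- keep & truth$family_id[t_idx] == predicted$family_id[p_idx]
    }
    if (any(keep)) {
      cand[[ctg]] <- data.frame(t = t_idx[keep], p = p_idx[keep],
                                ov = ov_bp[keep])
    }
  }
  cand <- do.call(rbind, cand)
  if (is.null(cand) || nrow(cand) == 0) {
    return(list(recall = 0, precision = 0, n_truth = n_t,
                n_predicted = n_p, matches = empty))
  }
  cand <- cand[order(-cand$ov, cand$t, cand$p), , drop = FALSE]
  t_used <- logical(n_t); p_used <- logical(n_p)
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    ti <- cand$t[r]; pi <- cand$p[r]
    if (t_used[ti] || p_used[pi]) next
    t_used[ti] <- TRUE; p_used[pi] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      truth_row = ti, predicted_row = pi,
      start_error = predicted$start[pi] - truth$start[ti],
      end_error = predicted$end[pi] - truth$end[ti])
  }
  matches <- do.call(rbind, rows)
  list(recall = sum(t_used) / n_t,
       precision = sum(p_used) / n_p,
       n_truth = n_t, n_predicted = n_p, matches = matches)
}

#' Write simulation ground truth to disk
#'
#' FASTA genome, GFF3 of planted features and a JSON dump of the truth
#' tables.
#'
#' @param sim a `sat_simulation`.
#' @param dir output directory (created if needed).
#' @export
write_truth <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sequences(sim$genome, file.path(dir, "genome.fa"))
  t <- sim$truth
  feats <- rbind(
    cbind(t$monomers[, c("contig", "start", "end", "strand")],
          type = "satellite_monomer",
          family_id = t$monomers$family_id,
          array_id = t$monomers$array_id),
    cbind(t$arrays[, c("contig", "start", "end", "strand")],
          type = "satellite_array",
          family_id = t$arrays$family_id,
          array_id = t$arrays$array_id))
  write_gff3(sort_intervals(feats), file.path(dir, "truth.gff3"),
             source = "satarch_sim")
  dump <- lapply(t, function(df) df)
  jsonlite::write_json(dump, file.path(dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
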