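---
title: "Dissecting satellite DNA long-range architecture with satarch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting satellite DNA long-range architecture with satarch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satarch)
```

## The problem

Satellite DNAs (satDNAs) are tandemly repeated sequences that can occupy a
third or more of an insect genome, concentrated in (peri)centromeric
heterochromatin. Long-read assemblies finally represent these regions well
enough to ask how satellite arrays are organized over tens of kilobases:
whether monomer orientation flips inside arrays (creating array-scale
palindromes, "macro-dyad symmetries"), whether the boundaries between
intermingled families are conserved sequence elements, and whether
satellites co-occur with microsatellites in regular higher-order patterns.

satarch implements that analysis as a reusable pipeline: consensus-library
monomer annotation, gap-bounded array reconstruction, oriented subarray
decomposition, inversion-site and transition-zone characterization, a
"cassette" census, microsatellite conjunction analysis, and cross-genome
comparison via approximate k-mer scanning and F81-based sequence geometry.
A synthetic-genome generator with complete ground truth makes every stage
testable without any external data.

## Annotation model

Monomers are found by local alignment of each family consensus against both
strands of the genome (NCBI BLAST+ `blastn`, word size 7, match/mismatch
+1/−1, gap open/extend 2/1, low-complexity filtering off). Two filters are
normative, both defaulting to 70%:

* **percent identity** of the alignment, and
* **query coverage** (`qcovhsp` semantics): the fraction of the consensus
  length that is aligned.

The engine behind the contract is replaceable; the filters are not. Because
local alignments trim divergent termini, a hit whose unaligned consensus
terminus is at most 25 bp is extrapolated to the full monomer extent on the
genome (a diverged subunit at a monomer edge is still part of the copy);
longer truncations are treated as genuine partial copies and keep their
alignment bounds. Overlapping hits are resolved greedily by descending
score (ties: identity, then leftmost, then `+` strand); an accepted hit may
overlap previously accepted ones by at most 10% of the shorter hit, which
tolerates alignment fuzz while forbidding nested or duplicated calls.

Coordinates are 0-based half-open internally; GFF3 is written 1-based
inclusive and BED 0-based half-open. Ambiguity characters are collapsed to
N on input and never count as matches in any identity computation.

## Arrays, subarrays, inversion points

An **array** is the single-linkage closure of same-family monomer hits
under a gap bound of one monomer length — the fixed point of iteratively
expanding every annotation by up to one monomer length and absorbing newly
reached monomers. The boundary case (gap exactly one monomer length) merges.
Strand is ignored at this tier. A family is classified as a satellite when
some array contains at least five tandem monomers.

**Subarrays** re-introduce orientation with a three-tier strategy: member
monomers of each strand are merged with the same gap rule, the resulting
stranded blocks are clipped to the array span, and the ordered block list
alternates in orientation. Each boundary between opposite-strand blocks is
an **inversion point**, placed at the midpoint of the inter-block gap; the
midpoint is the only choice that is symmetric under reverse complement,
which the decomposition must respect (mirroring the genome mirrors the
blocks, flips strands, and preserves the number of inversion points).

Macro-dyad symmetry is quantified per inversion point by the signed length
difference of the two flanking blocks (direct minus inverted) and per array
by the symmetry span, the largest flanking pair sum. One-directional arrays
are reported with a single subarray and excluded from difference
statistics.

Windows of ±200 bp around inversion points (the default `window_radius`)
are extracted for sequence analysis. 200 bp is large enough to span the
degenerate subunit variants observed at inversion points (roughly
110–230 bp) and small enough to stay inside the flanking monomers. Windows
are clustered by single-linkage on pairwise global-alignment identity. The
alignment scheme is pinned everywhere in the package: match +1, mismatch
−1, gap open −5, gap extend −1, identity = matches / alignment columns (gap
columns therefore count as differences). Cluster consensus sequences are
majority-rule over an alignment anchored to the longest member; clusters
with fewer than three members are labeled minor and excluded from consensus
statistics.

## Junctions, transition elements, cassettes

Adjacencies between arrays of two families are neighbor pairs on a contig
with a gap of at most 1 kb and no intervening array of either family. The
junction window spans 250 bp into each flanking array plus the whole gap;
the **core** — the inter-array portion of the window — is the transition
element proper.

For transition typing the package clusters the cores, not the full
windows. The padded flanks belong to array interiors whose orientation
varies from junction to junction (an array ending in an inverted block
contributes reverse-complemented monomer sequence), so full-window
clustering fragments along orientation rather than element type; the cores
are orientation-free and conserved. Junctions whose core is shorter than
20 bp (abutting arrays) carry no element and are labeled `TRANS_none`.
Above 80 junctions a seeded subsample is clustered exactly and the
remainder assigned to the nearest cluster consensus, keeping the cost
linear.

The **cassette census** asks, for every minor-family array, whether a
junction of the first prevalent transition type flanks it, whether one of
the second type does, and whether the array contains an internal inversion
point, and reports the Venn counts of the three booleans. The two
prevalent types are the two largest core clusters, ordered by decreasing
median junction gap (the longer transition element first) so that the
labels are reproducible without reference sequences.

Chimeric junction elements are characterized by splitting the junction to
maximize the summed local-alignment scores of the prefix against one donor
consensus and the suffix against the other. When a motif duplicated at the
breakpoint makes the split ambiguous, the rightmost maximizing split is
taken and the duplicated motif recovered by comparing the donor contexts
(it must terminate the prefix donor segment and either begin or
immediately precede the suffix donor segment); overlaps shorter than 3 bp
are treated as alignment-end noise. Internal deletions relative to a donor
are measured by anchor chaining — two local anchors and the donor bases
skipped between them — because under the pinned gap costs an alignment
will not bridge a deletion whose distal anchor is short.

Array edges can be refined independently of the aligner with a k-mer rule:
k = 12, a trailing window of 4k bp, and a threshold of 0.5 on the fraction
of window k-mers present in the family consensus k-mer set (both strands,
consensus treated as circular so tandem-junction k-mers count). The scan
walks outward while the window passes and reports the end of the outermost
in-set k-mer of the last passing window, which makes the refined edge exact
on undiverged copies.

## Microsatellite conjunction

Perfect dinucleotide runs are maximal exact repetitions of the motif or
its rotation with at least five units and no mismatches; the reported
interval is trimmed to `2 × units` from the run start so that run length
and unit count always agree. Runs are first shortened by subtracting the
linked family's monomer annotations — the family consensus itself may
begin and end with motif tracts, so spacer runs fuse with monomer termini
and must be cut back to the inter-monomer material — and surviving runs
within 100 bp of a family monomer are labeled linked. The 100 bp bound is
a documented configuration knob: the linkage in the emulated architecture
is physical adjacency (spacers abut monomers, distance 0), so results are
insensitive to it over a wide range, but it should be reported alongside
any analysis.

## Cross-genome comparison

Orthology scanning uses k = 16 k-mer sets (both strands) from a consensus
and reports every genomic locus matching some k-mer within Levenshtein
distance 3. The scan is pigeonhole-seeded: each k-mer is split into four
exact seed parts, seed matches anchor candidate windows (±3 bp), and
candidates are verified with full edit distance over window lengths
13–19. Any window within distance 3 must contain one exact part, so the
scan is provably complete for the bound; a windowed brute force over a
50 kb sequence is the test oracle. Overlapping matched regions are merged
(gap ≤ 16 bp) and mapped back onto the consensus by local alignment to
build a per-position coverage profile — the check that distinguishes
genuine orthology from short low-complexity similarity (e.g. A+T
homopolymer stretches matching an A+T-rich consensus segment).

Population geometry uses the F81 model distance
`d = −E · ln(1 − p/E)`, `E = 1 − Σπᵢ²`, with `p` the mismatch proportion
over pairwise-complete A/C/G/T columns. Sequences are placed into a common
coordinate frame by pairwise anchoring to the longest sequence (global
alignment, projection onto anchor columns); base frequencies are estimated
once from the whole anchored alignment, matching common `dist.dna`
behavior, and the package's distances are cross-checked against the ape
implementation in the test suite. Saturated pairs (`p ≥ E`, where the
formula is undefined) are flagged, excluded from similarity summaries, and
imputed at 1.5 × the largest finite distance before embedding. PCA embeds
the rows of the distance matrix (column-centered) rather than a one-hot
sequence encoding; the choice is isolated in `pca_embed()` so it can be
swapped. Sequence graphs connect each sequence to its five nearest
neighbors, ties broken by label order, mutual selections deduplicated.

## The synthetic architecture

`default_architecture()` states the validation conditions:

* 5 Mb single-contig genome, background i.i.d. at 70% A+T (a realistic
  value for satellite-rich beetle genomes);
* a two-subunit major family (225 bp monomer) and a seven-subunit minor
  family (704 bp monomer, subunit lengths 59–116 bp, one subunit the
  verbatim reverse complement of another, emulating the intra-monomer
  inverted block), both derived from a shared ~110 bp ancestral unit at
  divergences that keep cross-family identity safely below the 70%
  annotation threshold;
* 40 planted major/minor loci: 20 cassettes, 12 plain major arrays
  (subarray counts 1–3, log-normal copy numbers, median 30 copies), 8
  standalone minor arrays; plus 6 arrays of a third 692 bp family whose
  monomers alternate with (AC)n spacers, and 30 decoy (AC)n runs;
* per-copy substitution divergence 5% (high enough to exercise clustering,
  far from the 30% annotation limit); conserved elements (transition
  elements, inversion-site variants) at 1%;
* inversion-site variants: two major-family variants at 23.5% and 10.7%
  divergence from the boundary subunit, and a minor-family variant
  differing at 12 fixed positions of the terminal two-subunit span;
* cassettes structured as major block – 124 bp chimeric element (with a
  duplicated TTCAAT at the breakpoint) – minor array with internal
  inversion – diverged transition element (a ~33% diverged monomer copy
  carrying a 60 bp internal deletion, followed by an annotatable ~18%
  diverged monomer) – major block; each cassette independently carries all
  three conserved elements with probability 0.59, otherwise one element,
  drawn uniformly, is omitted;
* (AC)n unit counts: spacers 5 + Geometric(0.04) (median length ≈ 42 bp),
  decoys 5 + Geometric(0.45) (median ≈ 12 bp), a length contrast typical
  of satellite-linked spacers versus background microsatellites.

Loci are placed in shuffled order with at least 2 kb of background between
them, so planted arrays are unambiguous under the gap-merge rule. Ground
truth is emitted for every feature class; microsatellite truth is rebuilt
from the final sequence (the background occasionally contains spontaneous
(AC)≥5 runs, which are real unlinked runs and must be part of the truth)
and labeled from the planted spacer-monomer coordinates.

The generator emulates array grammar, not everything in real data: there
are no transposable elements, no assembly artifacts, no indel
mutations by default, and background is i.i.d. rather than
isochore-structured. Passing the recovery tests therefore demonstrates the
pipeline's correctness on the stated architecture, not annotation accuracy
on arbitrary genomes.

Because the default population includes standalone minor arrays, the
all-array triple rate reported by the census sits below the per-cassette
rate of 0.59; the dedicated rate-recovery validation uses a population of
200 cassettes and no standalone arrays, where the two coincide.

## Numerical choices and degenerate inputs

* Sorting and tie-breaks are fixed everywhere (contig, start, end, strand
  with `+` < `−` < `.`), so identical inputs give byte-identical outputs.
* Consensi shorter than 20 bp are rejected (alignment seeding is
  unreliable); homopolymer microsatellite motifs are rejected.
* Empty inputs return empty tables rather than errors wherever the empty
  case is meaningful (no hits, no adjacencies, no runs).
* `classify_transitions` subsampling and any other internal draw are
  seeded through function arguments; the generator consumes a single seed
  and identical spec + seed is byte-reproducible.
* KDE of array lengths uses Scott's rule bandwidth and is visualization
  output only.
* Validation problem sizes (5 Mb default genome, 200-cassette census
  population, 50 kb scan oracle) were chosen as the smallest scales at
  which every architectural feature occurs in numbers that make the
  recovery statistics meaningful.

## Known limitations

* The annotation engine is an external dependency (BLAST+ on the PATH);
  the package pins its filtering semantics but not its seeding internals,
  which is why all accuracy claims are validated against planted truth
  rather than assumed.
* Monomer-extent extrapolation (≤ 25 bp termini) assumes copies are full
  monomers; genuinely truncated copies shorter than the consensus by a few
  bases may be extended past their true edge by up to that much.
* Single-linkage identity clustering can chain through intermediates near
  the threshold; transition typing uses junction cores specifically to
  keep within-type identity far from the threshold.
* The F81 common-coordinate frame comes from pairwise anchoring, not a
  full MSA; columns inserted relative to the anchor are invisible to the
  distance, which slightly compresses distances between sequences sharing
  an insertion.
* Approximate k-mer scanning is exhaustive and intended for consensus-size
  k-mer sets against regions or small genomes, not for genome-vs-genome
  comparison.
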