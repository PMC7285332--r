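---
title: "Targeted seed-and-extend assembly of circular organelle genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted seed-and-extend assembly of circular organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant mitochondrial genomes often exist not as one "master circle" but as
several independent circular chromosomes. General-purpose assemblers tend
to collapse or merge such structures, so a multipartite assembly is hard
to trust without an independent check. `circleseed` implements that
check: a targeted seed-and-extend assembler for low-error long reads
(PacBio CCS/HiFi-class). Starting from a seed sequence - a contig from
another assembler or a single read - it repeatedly:

1. maps reads to the 3' edge of the growing contig,
2. keeps reads that are anchored well enough and overhang the contig end,
3. collapses the overhanging read parts into a consensus,
4. appends the consensus to the contig,

until one of four things happens:

* **circularized** - the contig's two ends have become identical: the
  molecule is a circle, the duplicated junction is trimmed;
* **dead_end** - no extension has enough read support (a linear molecule
  end, or a coverage gap);
* **fork** - two alternative extensions are each backed by a substantial
  share of the reads: the contig end sits in a repeat shared by two
  different molecules, and the user must choose a branch;
* **max_iterations** - the iteration cap was reached.

A genuinely circular chromosome therefore produces a specific, checkable
signature: extension to circularity with no forks along the way.

The package also provides the surrounding workflow pieces: a median
k-mer copy-number read filter that enriches for high-copy organellar
reads before assembly, an intra-genome repeat scanner, a detector of
mitochondrial inserts of plastid origin (MIPT), a variant mask that
excludes calls inside plastid-derived regions, and a truth-tracked
simulator used throughout the test suite.

## The extension model and its parameters

All parameters live in one object:

```r
library(circleseed)
extender_config()
```

* `min_mapped_part` (default **8000** bp): a read must align to the
  contig over at least this length before its overhang may vote. Long
  anchors are what lets the assembler walk across repeats shorter than
  `read length - min_mapped_part`.
* `min_read_similarity` (default **99** %): minimum percent identity of
  the read-to-edge alignment, counted as matches over all alignment
  columns, gap columns included. 99 suits reads with error rates well
  below 1%; for a run that must be conservative (e.g. a plastome from
  deeply covered data) 100 can be used, and for reads with ~1% error a
  threshold of 97-98 is appropriate - at 99 exactly half of 1%-error
  reads fail the filter, since the per-read error count is Binomial
  with its median at the cutoff.
* `edge_size` (default **15000** bp): reads are mapped against only the
  terminal window of the contig, which bounds per-iteration cost and is
  ample for anchors of 8-12 kb reads.
* `min_support` (default **3** reads): the number of reads that must
  cover every consensus column kept; the extension stops where coverage
  falls below it. See "Why the default support floor is 3" below.
* `fork_fraction` (default **0.2**): an alternative extension must hold
  at least this fraction of the overhanging reads to be reported as a
  branch.
* `circular_min_overlap` (default **1000** bp): minimal length of the
  terminal suffix/prefix duplication that declares circularity.
* `end_slack` (default **10** bp): how close to the edge terminus an
  alignment must reach to count as reaching the contig end; absorbs
  terminal indel wobble.
* `cluster_similarity` (default derived as
  `100 - 2*(100 - min_read_similarity)`): identity at which two *reads*
  are considered to agree. Read-vs-read comparisons accumulate the
  errors of both reads - twice the read-vs-contig rate - so deriving
  this threshold from `min_read_similarity` keeps the two criteria
  consistent. A fixed read-vs-read threshold equal to
  `min_read_similarity` would reject agreeing 1%-error read pairs
  (pairwise identity ~98%) and shatter the consensus.

### Alignment engine

Read-to-edge alignment is seeded (exact 15-mers against a hash of the
edge window, modal diagonal) and finished with a banded
dynamic-programming alignment (band half-width 150 bp) that consumes
the edge up to its 3' terminus with a free end on the read; the
unaligned read suffix is the overhang. Scores are match +2, mismatch
-2, gap -3 (linear); identity is matches over columns including gaps.
The same kernel, in different end-freedom modes, powers the consensus
star alignment and the circularity check. The kernels are compiled
(Rcpp); on small inputs they are checked in the test suite against
exact full-matrix dynamic programming from Biostrings.

### Consensus and fork detection

All accepted overhangs start at the same contig position, so they are
star-aligned against the longest one and collapsed column by column:
each column takes the plurality base (ties broken A < C < G < T); a
gap wins a column only when more than half of the covering reads have
one, in which case the column is omitted; an insertion relative to the
anchor is emitted only when a majority of covering reads carry it. The
consensus is truncated at the first column covered by fewer than
`min_support` reads, so the contig is extended exactly as far as the
evidence is deep enough - there is no fixed step size.

A **branch** is flagged at the first column where the second most
common base is backed by at least `max(2, fork_fraction * coverage)`
reads. The reads covering that column are split by their base,
refined by one reassignment round (a read can share the minority base
by coincidence; each read joins the alternative its sequence matches
better), and each group's consensus is rebuilt on its own anchor. For
*reporting*, a group's coverage floor is capped at its size - an
alternative backed by fewer than `min_support` reads must still show
its diverging sequence, it just cannot extend the contig.

Two candidate alternatives are reported as a **fork** only when they
genuinely disagree: their tails beyond the shared prefix are compared
ungapped, position by position (they share an anchor point, and gapped
alignment of random DNA inflates identity to ~50-60%), and the verdict
requires a window of at least 8 columns with at least 3 mismatches at
a density of 40% or more. Unrelated continuations mismatch at ~75% of
positions; tails that differ only by scattered sequencing errors
mismatch at a few percent; the rule sits between the two regimes with
a wide margin. A group created by coincident read errors - one
mismatching column, then agreement - is absorbed into the majority,
and extension proceeds. When a real branch is too close to the current
contig end to pass the window test, the minority group cannot sustain
`min_support` coverage either, so the extension stops essentially at
the divergence point and the next iteration, looking at overhangs that
diverge from their first base, sees the branch at full strength. This
"creep to the junction" behaviour is what makes fork detection
independent of the (variable) per-iteration step size.

Status precedence per iteration is circularized > fork > dead_end >
extended: a completed circle is a stronger, directly checkable claim
than a branch point.

### Circularity

The contig is circular when a terminal suffix of at least
`circular_min_overlap` bp aligns to the contig prefix at
`min_read_similarity` identity with both termini anchored. The
candidate overlap length is located by shared 15-mers between the
first and last `edge_size` window and verified by a banded global
alignment; the duplicated suffix is then trimmed so the junction
appears exactly once. Because circular molecules have no natural
origin or strand, `same_circle()` and `circular_identity()` compare
assemblies to a reference up to rotation and reverse complement.

## Why the default support floor is 3

With reads of length $L$ and an anchor requirement $m$, only reads
whose anchor ends within $(L - m)$ bp of a position can both reach and
overhang it, so the number of reads able to support a junction at
position $p$ is Poisson with mean

$$\lambda = \frac{\text{coverage}}{\bar L}\, \mathbb{E}[(L - m)^+],$$

about 10 for 50x coverage of 8-12 kb reads with $m = 8000$ - an order
of magnitude below the nominal coverage. Extension can never jump a
position whose support is below `min_support` (every consensus column
past $p$ needs that many anchored reads spanning $p$), so what matters
is the *minimum* of this Poisson field over the whole molecule: over a
30 kb circle at 50x it falls below 5 for most simulated genomes and
below 3 for roughly one in ten. A floor of 5 would make the tool's own
default conditions self-defeating; 3 keeps a reliable plurality vote
for sub-1%-error reads (three concordant reads misvote a column with
probability ~$10^{-5}$) while tolerating normal coverage fluctuation.
For deeply covered data (hundreds-fold, as targeted organelle
sequencing typically yields) a higher floor is appropriate, and the
fork-scenario tests use `min_support = 8` at 150x for exactly that
reason: inside a repeat shared by two chromosomes the effective
coverage doubles, and resolving the exit requires several
discriminating reads on each side.

The same arithmetic explains two experimental-design choices in the
test suite and acceptance script. The noisy round trip uses the same
sampled read set as the error-free one with 1% substitutions layered
on top (`add_read_errors()`), isolating error robustness from sampling
variance, with `min_read_similarity = 98` (matched to the error level,
as the threshold is a per-dataset user parameter) and an accurate
10 kb starter slice - the "contig from another assembly" starter the
tool is designed around, since a raw 1%-error starter read would
permanently contribute its ~100 errors to the final sequence (the
algorithm never revisits assembled sequence, and polishing is out of
scope). The fork scenario runs at 150x per circle because at 50x the
number of branch-discriminating reads per side at the repeat exit is
Poisson(~2-3), and a 5:1 draw makes following the majority the
statistically correct - fork-free - decision.

## The k-mer copy-number filter

`filter_reads_by_copy()` builds a canonical k-mer occurrence table
over the read set itself (k-mer and reverse complement counted
together; overlapping occurrences all count; k-mers containing N are
skipped) and discards reads whose **median** k-mer copy number is
below `min_copy` (default 5; a read whose median is exactly at the
threshold is retained - "less than" removes). Reads from a high-copy
organellar genome have k-mer medians near their genome's coverage,
single-copy nuclear reads sit at ~1, so the filter enriches strongly.
The median of an even-sized multiset is the mean of the central pair;
reads shorter than k are discarded with a warning and counted
separately. The classic variant - discard when at least 80% of k-mers
are below the threshold - is available as `mode = "fraction"`; the
median rule is the `fraction = 0.5` special case and the default. The
default `k = 15` balances specificity and table size at desk scale;
the filter's behaviour is insensitive to k in the 15-25 range for
reads of a few kilobases.

## Repeats, plastid inserts, and variant masking

`find_repeats()` (defaults 500 bp, 95%) and `find_plastid_inserts()`
(defaults 100 bp, 90%) share one engine: exact 11-mer seeds, gapless
X-drop extension trimmed back to the maximum-score endpoints, and a
pure length-and-identity filter with no e-value statistics. The engine
resolves substitution-diverged homology exactly (boundary error a few
bp) but splits alignments at indels - a documented limitation; it is
not claimed to reproduce any particular external aligner's output.
Trivial full-length self-alignments are suppressed, each unordered
pair of copies is reported once, and strand records direct versus
inverted orientation. MIPT hits whose mitochondrial interval overlaps
a supplied gene annotation by at least one base are suppressed,
because rRNA, *atp* and plastid-like tRNA genes are similar between
the two genomes for ancestral reasons rather than by insertion.

`mask_variants()` partitions variant records by overlap of their
reference span `[pos, pos + nchar(ref))` with a set of intervals, in
0-based half-open coordinates throughout (a variant exactly at an
interval's `end` is kept). Its purpose: plastid-derived regions of the
mitogenome attract reads from the (often ten-fold deeper-covered)
plastid itself, and the resulting false calls must be excluded from
diversity analyses.

## The simulator: what it emulates, and what it does not

`simulate_genome()` builds chromosomes of i.i.d.-uniform random DNA
with planted features (repeats copied within or across chromosomes,
optionally inverted; inserts copied from a simulated plastid), each
diverged to a stated identity by an exact count of substitutions and
recorded with true coordinates. `simulate_reads()` draws
truncated-normal read lengths (default 8-12 kb, mean 10 kb), uniform
start positions - wrapping the origin on circles, truncating at the
termini of linear molecules, as real fragments do - uniform strands,
and i.i.d. per-base substitution/insertion/deletion errors (default
0.5% total, CCS-like). Everything is deterministic given a seed.

What passing tests on this simulator do **not** show: behaviour under
homopolymer-biased or bursty error profiles, chimeric reads,
heteroplasmic structural variation, GC-skewed composition, or
indel-diverged homology. Random background also understates the
repeat content of real intergenic mitochondrial DNA. The simulator's
role is to give exact, truth-tracked ground truth for the algorithmic
contracts, not to model an instrument.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere (BED convention).
* IUPAC ambiguity codes other than N are converted to N on input with
  a warning; consensus and k-mer logic only distinguish {A,C,G,T,N};
  N never matches anything in alignment or k-mer counting.
* All ties are broken deterministically (bases A < C < G < T;
  insertion strings lexicographically; clusters by support, then
  consensus length, then sequence), and the assembly loop contains no
  randomness, so identical inputs and configuration give identical
  outputs byte for byte.
* Reads without a credible seed diagonal (fewer than 3 co-diagonal
  15-mer matches) are rejected as unalignable; reads contained in the
  contig are `internal_only`; rejection tallies appear per iteration
  in the assembly log.
* An empty overhang set is a dead end, not an error; an empty VCF
  round-trips with its header preserved.

## Problem sizes used in the tests

The acceptance-style tests and `scripts/acceptance.R` run the full
stated conditions: a 30 kb circle at 50x (error-free and with 1%
substitutions), a two-circle 20 kb shared-repeat construction at 150x,
a linear 30 kb molecule at 50x, a 200-read filter comparison against a
brute-force oracle, and planted-feature homology scans on 30 kb
chromosomes. Unit tests use a 12 kb circle with 3-5 kb reads and
proportionally scaled thresholds, which exercises the identical code
paths in a few seconds each.

## Known limitations

* Extension is 3'-only; assembling leftward from a starter means
  reverse-complementing it (and the result).
* A dead end caused by a local coverage pocket is reported exactly like
  a true molecule end; distinguishing them needs a restart from another
  starter or more coverage.
* Fork alternatives are reported, not auto-resolved; restarting from a
  chosen branch is the user's call (append the alternative's consensus
  to the contig and re-run).
* The homology scanner splits indel-diverged alignments; its
  recovery guarantees hold for substitution divergence.
* Consensus quality relies on plurality voting, so systematic
  (correlated) read errors would pass through; the error model the
  tool targets is the low, unbiased error of circular consensus
  sequencing.
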