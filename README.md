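# circleseed

Targeted seed-and-extend assembly of small circular genomes — plant
mitochondria and plastids — from low-error long reads (PacBio CCS/HiFi
class), with the companion utilities such assemblies need: median k-mer
copy-number read filtering, repeat and plastid-insert (MIPT) scanning,
masking of variants in plastid-derived regions, and a truth-tracked
simulator of multipartite circular genomes.

## Who it is for, and why

Plant mitogenomes frequently exist as several independent circular
chromosomes rather than one "master circle". When a general-purpose
assembler reports such a multipartite structure, the result needs an
independent check: does each contig really extend, read by read, back
into itself? `circleseed` performs that check (and can assemble small
circles outright). Starting from a seed sequence *S* — a contig from
another assembler or a single read — it iterates:

1. map reads to the 3′ edge (last `edge_size` = 15,000 bp) of the
   contig;
2. accept reads aligned over ≥ `min_mapped_part` = 8,000 bp at
   ≥ `min_read_similarity` = 99% identity that overhang the contig end;
3. collapse the overhanging parts into a column-plurality consensus,
   truncated where read coverage drops below `min_support`;
4. append the consensus and repeat,

until the contig **circularizes** (its two ends become identical, the
junction is trimmed), **dead-ends** (no sufficiently supported
extension), or **forks** — two alternative extensions each carried by at
least a `fork_fraction` = 0.2 share of the overhanging reads, the
signature of a repeat shared between two molecules. A circle recovered
with no forks along the way is strong evidence for an independent
chromosome. Support at a junction is far below nominal coverage — only
reads whose anchor fits in the `read length − min_mapped_part` window
can vote, roughly Poisson with mean 10 at 50× for 8–12 kb reads — which
is why the default support floor is 3 and why deep (hundreds-fold)
organellar coverage is the intended regime; the methods vignette
(`vignettes/targeted-assembly.Rmd`) derives this and every other
default.

## A worked example

Simulate a 30 kb circular chromosome, sample error-free 8–12 kb reads
at 50×, and assemble starting from a single read:

```r
library(circleseed)

genome <- simulate_genome(lengths = 30000, seed = 101)
reads  <- simulate_reads(genome, coverage = 50, error_rate = c(0, 0, 0), seed = 102)
reads
#> simulated read set: 150 reads, 1507646 bp total | seed: 102

contig <- assemble(reads$reads[1], reads$reads, extender_config(), verbose = TRUE)
#> iteration 1: extended | contig 11969 bp | support 10 | overhangs 10
#> iteration 2: extended | contig 13974 bp | support 10 | overhangs 10
#> ...
#> iteration 14: extended | contig 32637 bp | support 13 | overhangs 13
#> iteration 15: circularized | contig 30000 bp | support NA | overhangs 10

contig
#> contig contig1 - 30000 bp, circular | status: circularized | 15 iterations

same_circle(genome$chromosomes[[1]], contig$sequence)
#> [1] TRUE
```

Each `extended` line reports how many reads overhung the 3′ end and how
many backed the chosen consensus. At iteration 15 the contig (32,637 bp)
has grown past its own origin; the terminal duplication is detected,
trimmed, and the returned 30,000 bp sequence equals the simulated truth
exactly, up to rotation and strand. `assembly_log(contig)` returns the
same trace as a data frame, including per-iteration rejection tallies;
`write_contig()` writes FASTA with `circular=true|false` in the header.

The same functions drive read filtering and homology scanning:

```r
filter_reads_by_copy(reads$reads, k = 15, min_copy = 5)
#> k-mer copy-number filter (mode = median , k = 15 , min copy = 5 )
#>   input: 150 reads; retained: 150 ; discarded: 0 ( 0 with undefined median )
# (a pure organellar read set: every read has high-copy k-mers)

find_repeats(genome$chromosomes, min_length = 500, min_identity = 95)
find_plastid_inserts(mito, plastid, annotations, min_length = 100, min_identity = 90)
mask_variants(read_vcf("calls.vcf"), read_intervals("mipt.bed"))
```

## Command line

A thin wrapper script is installed with the package
(`system.file("scripts", "circleseed", package = "circleseed")`) and
exposes `simulate`, `downsample`, `subsample`, `assemble`, `repeats`,
`mipt` and `mask-variants`. Assembly flags mirror the run parameters
(`--minimum-read-similarity`, `--minimum-length-of-mapped-read-part`,
`--contig-edge-size-to-use-for-mapping`; snake_case aliases accepted),
`--config file.yaml` supplies defaults, and every run writes a
reproducibility header (version, parameters, input checksums, seed)
into its log.

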