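# Independent oracles and small fixture builders. These deliberately do
# not share code with the package internals: reverse complements and
# alignments come from Biostrings, k-mer enumeration from plain string
# slicing, interval overlap from direct comparison.

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# exactly n substitutions at distinct positions (never a no-op base)
substitute_bases <- function(seq, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  pos <- sample(length(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  paste(ch, collapse = "")
}

# reverse complement through Biostrings (independent of revcomp())
rc_oracle <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# brute-force canonical k-mer counting over a read set
kmer_counts_oracle <- function(reads, k) {
  all_kmers <- unlist(lapply(reads, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, 1:(n - k + 1L), k:n)
    km[!grepl("N", km, fixed = TRUE)]
  }), use.names = FALSE)
  if (length(all_kmers) == 0L) return(integer(0))
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(all_kmers)))
  canon <- ifelse(all_kmers <= rcs, all_kmers, rcs)
  table(canon)
}

# brute-force per-read median copy number under a count table
median_copy_oracle <- function(read, counts, k) {
  n <- nchar(read)
  if (n < k) return(NA_real_)
  km <- substring(read, 1:(n - k + 1L), k:n)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(NA_real_)
  rcs <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(km)))
  canon <- ifelse(km <= rcs, km, rcs)
  stats::median(as.numeric(counts[canon]))
}

# exact global percent identity via Biostrings dynamic programming
identity_oracle <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  cmp <- Biostrings::compareStrings(aln)
  100 * sum(strsplit(cmp, "")[[1L]] %in% c("A", "C", "G", "T")) / nchar(cmp)
}

# brute-force interval overlap check (0-based half-open)
overlaps_oracle <- function(pos, ref_len, intervals, seq_id) {
  any(intervals$seq_id == seq_id &
        intervals$start < pos + ref_len &
        intervals$end > pos)
}

# small circular-genome read set used by several extender tests:
# 12 kb circle, ~3-5 kb error-free reads, thresholds scaled accordingly
small_circle_fixture <- function(genome_seed = 11, read_seed = 12,
                                 error_rate = c(0, 0, 0)) {
  g <- simulate_genome(lengths = 12000, seed = genome_seed)
  rs <- simulate_reads(g, coverage = 50,
                       read_length = c(4000, 400, 3000, 5000),
                       error_rate = error_rate, seed = read_seed)
  list(genome = g, reads = rs,
       config = extender_config(min_read_similarity = 99,
                                min_mapped_part = 2000,
                                edge_size = 5000,
                                circular_min_overlap = 500))
}
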