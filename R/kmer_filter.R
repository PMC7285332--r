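#' Canonical k-mer occurrence table for a read set
#'
#' Counts every occurrence (overlapping occurrences included) of each
#' canonical k-mer across a set of reads. A k-mer and its reverse
#' complement are the same molecule read from opposite strands, so each
#' k-mer is stored under the lexicographic minimum of the two. K-mers
#' containing `N` are skipped.
#'
#' In a whole-genome read set, k-mers from a high-copy organellar genome
#' occur far more often than k-mers from single-copy nuclear regions;
#' this table is the substrate for copy-number read filtering
#' ([filter_reads_by_copy()]).
#'
#' @param reads Named character vector of reads.
#' @param k K-mer length, in `[3, 31]`. Default 15.
#' @return An object of class `kmer_table`: a list with elements `k` and
#'   `counts` (named integer vector, canonical k-mer -> occurrence
#'   count).
#' @export
kmer_table <- function(reads, k = 15L) {
  k <- as.integer(k)
  if (k < 3L || k > 31L) stop("k must be in [3, 31]")
  if (length(reads) == 0L) stop("no reads")
  if (all(nchar(reads) < k)) {
    stop("k = ", k, " is larger than every read")
  }
  res <- kmer_count_cpp(as.character(reads), k)
  counts <- res$counts
  names(counts) <- res$kmers
  structure(list(k = k, counts = counts), class = "kmer_table")
}

#' @export
print.kmer_table <- function(x, ...) {
  cat("k-mer table: k =", x$k, "|", length(x$counts),
      "distinct canonical k-mers |", sum(x$counts), "occurrences\n")
  invisible(x)
}

#' Median k-mer copy number of reads
#'
#' For each read, the median of the copy numbers (under `table`) of all
#' its canonical k-mers, with k-mers containing `N` excluded. An
#' even-sized multiset takes the mean of the two central values. Reads
#' contributing no countable k-mer (shorter than `k`, or all k-mers
#' contain `N`) get `NA`.
#'
#' @param reads Character vector of reads.
#' @param table A [kmer_table()].
#' @return Numeric vector of medians, one per read.
#' @export
median_kmer_copy <- function(reads, table) {
  stopifnot(inherits(table, "kmer_table"))
  if (length(reads) == 0L) return(numeric(0))
  out <- median_copy_batch_cpp(as.character(reads),
                               names(table$counts),
                               as.integer(table$counts), table$k)
  names(out) <- names(reads)
  out
}

#' Filter reads by k-mer copy number
#'
#' Reimplements the median-based k-mer read filter: a k-mer table is
#' built from the read set itself, and reads whose median k-mer copy
#' number falls below `min_copy` are discarded. This enriches for reads
#' from high-copy molecules (organellar genomes) and removes the bulk of
#' single-copy nuclear reads. A read whose median is exactly `min_copy`
#' is retained - the removal rule is "median less than the threshold".
#'
#' `mode = "fraction"` instead applies the classic criterion of
#' discarding reads where at least `fraction` of the k-mers have a copy
#' number below `min_copy` (the default behaviour of the Stacks
#' `kmer_filter` program); the median rule is the `fraction = 0.5` special
#' case and is the default here.
#'
#' Reads shorter than `k` (or with no countable k-mer) have no defined
#' median; they are discarded with a warning and counted separately in
#' the report.
#'
#' @param reads Named character vector of reads.
#' @param k K-mer length (default 15).
#' @param min_copy Copy-number threshold (default 5).
#' @param mode `"median"` (default) or `"fraction"`.
#' @param fraction For `mode = "fraction"`: discard a read when at least
#'   this fraction of its k-mers is below `min_copy` (default 0.8).
#' @return A list of class `kmer_filter_result`:
#'   * `reads`: the retained reads (named character vector);
#'   * `report`: list with `n_input`, `n_retained`, `n_discarded`,
#'     `n_undefined` (reads with no countable k-mer), `k`, `min_copy`,
#'     `mode`, `fraction`.
#' @export
filter_reads_by_copy <- function(reads, k = 15L, min_copy = 5,
                                 mode = c("median", "fraction"),
                                 fraction = 0.8) {
  mode <- match.arg(mode)
  tab <- kmer_table(reads, k)
  if (mode == "median") {
    med <- median_copy_batch_cpp(as.character(reads), names(tab$counts),
                                 as.integer(tab$counts), tab$k)
    keep <- !is.na(med) & med >= min_copy
    undefined <- is.na(med)
  } else {
    frac_low <- low_copy_fraction_batch_cpp(
      as.character(reads), names(tab$counts),
      as.integer(tab$counts), tab$k, as.integer(min_copy))
    keep <- !is.na(frac_low) & frac_low < fraction
    undefined <- is.na(frac_low)
  }
  if (any(undefined)) {
    warning(sum(undefined), " read(s) shorter than k or without countable ",
            "k-mers were discarded")
  }
  structure(list(
    reads = reads[keep],
    report = list(
      n_input = length(reads),
      n_retained = sum(keep),
      n_discarded = sum(!keep),
      n_undefined = sum(undefined),
      k = tab$k,
      min_copy = min_copy,
      mode = mode,
      fraction = if (mode == "fraction") fraction else NA_real_
    )
  ), class = "kmer_filter_result")
}

#' @export
print.kmer_filter_result <- function(x, ...) {
  r <- x$report
  cat("k-mer copy-number filter (mode =", r$mode, ", k =", r$k,
      ", min copy =", r$min_copy, ")\n")
  cat("  input:", r$n_input, "reads; retained:", r$n_retained,
      "; discarded:", r$n_discarded,
      "(", r$n_undefined, "with undefined median )\n")
  invisible(x)
}

#' Random downsampling of reads
#'
#' Selects exactly `n` distinct reads uniformly at random without
#' replacement. Deterministic given `seed`; the calling session's RNG
#' state is left untouched.
#'
#' @param reads Named character vector of reads.
#' @param n Number of reads to keep; `0 < n <= length(reads)`.
#' @param seed Integer seed.
#' @return Named character vector of `n` reads (in original relative
#'   order).
#' @export
sample_reads <- function(reads, n, seed = 1L) {
  if (n <= 0 || n > length(reads)) {
    stop("n must be in [1, ", length(reads), "]")
  }
  idx <- withr::with_seed(seed, sample.int(length(reads), n))
  out <- reads[sort(idx)]
  q <- attr(reads, "qualities")
  if (!is.null(q)) attr(out, "qualities") <- q[sort(idx)]
  out
}
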