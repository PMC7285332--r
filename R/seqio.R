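#' Read sequences from FASTA or FASTQ
#'
#' Loads DNA sequences into a named character vector, one element per
#' record, uppercased. IUPAC ambiguity codes other than `N` are converted
#' to `N` with a warning, so that downstream consensus and k-mer logic
#' only ever sees the alphabet `{A,C,G,T,N}`. Gzip-compressed files are
#' handled transparently.
#'
#' @param path Path to a FASTA or FASTQ file (optionally gzipped).
#' @param format `"auto"` (default; decided by inspecting the first
#'   non-empty character of the file), `"fasta"` or `"fastq"`.
#' @return A named character vector of uppercase DNA sequences. For FASTQ
#'   input, the per-record quality strings are attached as the
#'   `"qualities"` attribute (a character vector parallel to the
#'   sequences).
#' @seealso [write_seqs()]
#' @export
read_seqs <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    first <- ""
    while (TRUE) {
      line <- readLines(con, n = 1L)
      if (length(line) == 0L) break
      if (nzchar(trimws(line))) {
        first <- substr(trimws(line), 1L, 1L)
        break
      }
    }
    format <- switch(first,
      ">" = "fasta",
      "@" = "fastq",
      stop("cannot auto-detect format of ", path,
           " (first record starts with '", first, "')")
    )
  }
  set <- tryCatch(
    Biostrings::readDNAStringSet(path, format = format,
                                 with.qualities = (format == "fastq")),
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ",
           conditionMessage(e), call. = FALSE)
    }
  )
  if (length(set) == 0L) {
    stop("no sequence records in ", path)
  }
  seqs <- toupper(as.character(set))
  # first word of the header is the record id, as is conventional
  names(seqs) <- sub("\\s.*$", "", names(set))
  amb <- grepl("[^ACGTN]", seqs)
  if (any(amb)) {
    warning(sum(amb), " record(s) contain IUPAC ambiguity codes; ",
            "converted to N")
    seqs <- chartr("RYSWKMBDHVU", "NNNNNNNNNNN", seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad)) {
      stop("record ", names(seqs)[which(bad)[1L]],
           " contains characters outside the DNA alphabet")
    }
  }
  if (format == "fastq") {
    quals <- as.character(S4Vectors::mcols(set)$qualities)
    names(quals) <- names(seqs)
    attr(seqs, "qualities") <- quals
  }
  seqs
}

#' Write sequences to FASTA or FASTQ
#'
#' Round-trip safe with [read_seqs()]: ids and sequences are reproduced
#' exactly (FASTA line wrapping is cosmetic).
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @param format `"fasta"` (default) or `"fastq"`. FASTQ output uses the
#'   `"qualities"` attribute of `seqs` when present, and a flat `I`
#'   quality string otherwise.
#' @param width Line width for FASTA wrapping.
#' @return `path`, invisibly.
#' @export
write_seqs <- function(seqs, path, format = c("fasta", "fastq"),
                       width = 80L) {
  format <- match.arg(format)
  if (length(seqs) == 0L) stop("no sequences to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  set <- Biostrings::DNAStringSet(unname(as.character(seqs)))
  names(set) <- names(seqs)
  if (format == "fastq") {
    quals <- attr(seqs, "qualities")
    if (is.null(quals)) {
      quals <- vapply(nchar(seqs), function(n) strrep("I", n), "")
    }
    Biostrings::writeXStringSet(
      set, path, format = "fastq",
      qualities = Biostrings::BStringSet(unname(quals)))
  } else {
    Biostrings::writeXStringSet(set, path, format = "fasta", width = width)
  }
  invisible(path)
}

#' Reverse complement
#'
#' Vectorized reverse complement over the alphabet `{A,C,G,T,N}`
#' (`N` maps to `N`). Errors on any other character.
#'
#' @param seqs Character vector of DNA sequences.
#' @return Character vector of reverse-complemented sequences, names
#'   preserved.
#' @export
revcomp <- function(seqs) {
  if (length(seqs) == 0L) return(character(0))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  out <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  names(out) <- names(seqs)
  out
}

#' Rotate a circular sequence
#'
#' Moves `offset` bases from the end of the sequence to its start, the
#' operation used to test assemblies of circular molecules: after moving
#' a chunk across the origin, read coverage over the new junction should
#' stay uniform if the molecule is truly circular.
#'
#' @param seq A single DNA sequence (character scalar).
#' @param offset Number of bases to move from the end to the start;
#'   `0 <= offset < nchar(seq)`. Rotating by 0 is the identity, and
#'   rotating by `offset` then by `nchar(seq) - offset` restores the
#'   original sequence.
#' @return The rotated sequence.
#' @export
rotate_circular <- function(seq, offset) {
  stopifnot(length(seq) == 1L, is.character(seq))
  n <- nchar(seq)
  if (!is.numeric(offset) || length(offset) != 1L ||
      offset != trunc(offset) || offset < 0 || offset >= n) {
    stop("offset must be an integer in [0, ", n - 1L, "]")
  }
  if (offset == 0) return(seq)
  paste0(substr(seq, n - offset + 1L, n), substr(seq, 1L, n - offset))
}

#' Read genomic intervals from BED or GFF3
#'
#' Intervals are returned in 0-based, half-open coordinates (the BED
#' convention), which is the coordinate system used throughout the
#' package.
#'
#' @param path A BED or GFF/GFF3 file; the format is chosen from the file
#'   extension by `rtracklayer::import()`.
#' @return A data.frame with columns `seq_id`, `start`, `end` (0-based,
#'   half-open) and `name` (empty string when absent).
#' @export
read_intervals <- function(path) {
  gr <- rtracklayer::import(path)
  nm <- if (!is.null(gr$name)) as.character(gr$name)
        else if (!is.null(gr$ID)) as.character(gr$ID)
        else rep("", length(gr))
  nm[is.na(nm)] <- ""
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    stringsAsFactors = FALSE
  )
}

#' Write intervals as BED
#'
#' @param intervals Data.frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open) and optionally `name` and `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("seq_id", "start", "end") %in% names(intervals)))
  n <- nrow(intervals)
  df <- data.frame(
    chrom = intervals$seq_id,
    start = as.integer(intervals$start),
    end = as.integer(intervals$end),
    name = if ("name" %in% names(intervals)) intervals$name
           else rep(".", n),
    score = if ("score" %in% names(intervals)) intervals$score
            else rep(0L, n),
    stringsAsFactors = FALSE
  )
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# shared validation helper
.check_dna <- function(seq, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar")
  }
  if (grepl("[^ACGTN]", seq)) {
    stop(what, " contains characters outside {A,C,G,T,N}")
  }
  invisible(seq)
}
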