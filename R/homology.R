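# One-strand seeded homology scan between two sequences.
# Seeds are exact seed_k-mers; every seed not already inside a reported
# hit on its diagonal is extended gaplessly with an X-drop rule. The
# search is therefore substitution-oriented: hits diverged by indels are
# split at the indel (documented limitation).
.scan_strand <- function(q, s, min_length, min_identity, seed_k,
                         self_forward = FALSE) {
  seeds <- seed_hits_batch_cpp(q, s, as.integer(seed_k))[[1L]]
  if (nrow(seeds) == 0L) return(NULL)
  diag <- seeds[, 2L] - seeds[, 1L]
  if (self_forward) {
    keep <- diag > 0L   # drop the trivial self-diagonal; one pair per
    seeds <- seeds[keep, , drop = FALSE]
    diag <- diag[keep]
  }
  if (nrow(seeds) == 0L) return(NULL)
  ord <- order(diag, seeds[, 1L])
  seeds <- seeds[ord, , drop = FALSE]
  diag <- diag[ord]
  out <- list()
  i <- 1L
  n <- nrow(seeds)
  while (i <= n) {
    d <- diag[i]
    covered_to <- -1L
    while (i <= n && diag[i] == d) {
      qp <- seeds[i, 1L]
      if (qp >= covered_to) {
        ext <- diag_extend_cpp(q, s, qp, seeds[i, 2L], as.integer(seed_k))
        covered_to <- ext$q_end
        if (ext$length >= min_length &&
            100 * ext$matches / ext$length >= min_identity) {
          out[[length(out) + 1L]] <- data.frame(
            q_start = ext$q_start, q_end = ext$q_end,
            s_start = ext$s_start, s_end = ext$s_end,
            length = ext$length,
            identity = 100 * ext$matches / ext$length,
            stringsAsFactors = FALSE)
        }
      }
      i <- i + 1L
    }
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# Drop hits contained in another hit on both axes.
.drop_contained <- function(hits) {
  if (is.null(hits) || nrow(hits) <= 1L) return(hits)
  n <- nrow(hits)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !keep[i]) next
      if (hits$q_start[j] <= hits$q_start[i] &&
          hits$q_end[j] >= hits$q_end[i] &&
          hits$s_start[j] <= hits$s_start[i] &&
          hits$s_end[j] >= hits$s_end[i] &&
          hits$strand[j] == hits$strand[i] &&
          (hits$length[j] > hits$length[i] || j < i)) {
        keep[i] <- FALSE
      }
    }
  }
  hits[keep, , drop = FALSE]
}

.empty_hits <- function() {
  data.frame(query_id = character(0), q_start = integer(0),
             q_end = integer(0), subject_id = character(0),
             s_start = integer(0), s_end = integer(0),
             strand = character(0), length = integer(0),
             identity = numeric(0), stringsAsFactors = FALSE)
}

#' Local homology search between two sequences
#'
#' Reports maximal local alignments on both strands passing a pure
#' length-and-identity filter (no e-value statistics): alignment length
#' at least `min_length` columns and identity (matches over columns) at
#' least `min_identity` percent. When `query` and `subject` are the same
#' sequence the trivial full-length self-alignment is suppressed and
#' each repeat pair is reported once. Coordinates are 0-based,
#' half-open.
#'
#' The engine is a seeded gapless extension (exact `seed_k`-mer seeds,
#' X-drop extension, containment merging); it resolves
#' substitution-diverged homology exactly but splits alignments at
#' indels.
#'
#' @param query,subject Single DNA sequences (named or not).
#' @param min_length Minimum alignment length in bp (default 500).
#' @param min_identity Minimum percent identity (default 95).
#' @param seed_k Seed length (default 11).
#' @param query_id,subject_id Ids used in the output (default from
#'   names).
#' @return A data.frame of hits: `query_id`, `q_start`, `q_end`,
#'   `subject_id`, `s_start`, `s_end`, `strand` (`forward`/`reverse`),
#'   `length`, `identity`.
#' @export
local_homology_search <- function(query, subject, min_length = 500,
                                  min_identity = 95, seed_k = 11L,
                                  query_id = names(query) %||% "query",
                                  subject_id = names(subject) %||%
                                    "subject") {
  q <- unname(as.character(query))
  s <- unname(as.character(subject))
  .check_dna(q, "query")
  .check_dna(s, "subject")
  is_self <- identical(q, s)
  fwd <- .scan_strand(q, s, min_length, min_identity, seed_k,
                      self_forward = is_self)
  if (!is.null(fwd) && nrow(fwd)) fwd$strand <- "forward"
  sry <- revcomp(s)
  rev <- .scan_strand(q, sry, min_length, min_identity, seed_k)
  if (!is.null(rev) && nrow(rev)) {
    ls <- nchar(s)
    tmp <- ls - rev$s_end
    rev$s_end <- ls - rev$s_start
    rev$s_start <- tmp
    rev$strand <- "reverse"
    if (is_self) {
      # each inverted pair appears twice (once from each copy); keep the
      # canonical orientation, plus true palindromes once
      rev <- rev[rev$q_start < rev$s_start |
                   (rev$q_start == rev$s_start & rev$q_end <= rev$s_end), ,
                 drop = FALSE]
    }
  }
  hits <- rbind(fwd, rev)
  if (is.null(hits) || nrow(hits) == 0L) return(.empty_hits())
  hits <- .drop_contained(hits)
  hits <- data.frame(query_id = query_id, hits[, c("q_start", "q_end")],
                     subject_id = subject_id,
                     hits[, c("s_start", "s_end", "strand", "length",
                              "identity")],
                     stringsAsFactors = FALSE)
  hits <- hits[order(hits$query_id, hits$q_start, hits$s_start), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Find repeats within a genome
#'
#' Scans every sequence against itself and every pair of sequences for
#' repeats passing the length and identity thresholds (defaults: 500 bp
#' and 95%, the settings used for plant mitochondrial repeat maps).
#' Each unordered pair of copies is reported once, with the strand
#' recording direct (`forward`) versus inverted (`reverse`) orientation.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param min_length Minimum repeat length, bp (default 500).
#' @param min_identity Minimum percent identity (default 95).
#' @param seed_k Seed length (default 11).
#' @return A data.frame of hits (see [local_homology_search()]).
#' @export
find_repeats <- function(genome, min_length = 500, min_identity = 95,
                         seed_k = 11L) {
  stopifnot(length(genome) >= 1L)
  ids <- names(genome)
  if (is.null(ids)) ids <- paste0("chr", seq_along(genome))
  out <- list()
  for (i in seq_along(genome)) {
    for (j in i:length(genome)) {
      h <- local_homology_search(genome[[i]], genome[[j]],
                                 min_length = min_length,
                                 min_identity = min_identity,
                                 seed_k = seed_k,
                                 query_id = ids[i], subject_id = ids[j])
      if (nrow(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (length(out) == 0L) return(.empty_hits())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Find mitochondrial inserts of plastid origin (MIPT)
#'
#' Scans mitochondrial chromosomes against the plastid genome with
#' permissive thresholds (defaults: 100 bp and 90%), then suppresses any
#' hit whose mitochondrial interval overlaps an annotated gene by at
#' least one base. The annotation filter removes genuinely shared genes
#' (ribosomal RNAs, *atp* genes, plastid-like tRNAs) whose similarity is
#' ancestral rather than evidence of sequence transfer.
#'
#' @param mito Named character vector of mitochondrial chromosome
#'   sequences.
#' @param plastid Single plastid genome sequence.
#' @param annotations Data.frame of gene intervals on the mitochondrial
#'   chromosomes (`seq_id`, `start`, `end`; 0-based half-open), e.g.
#'   from [read_intervals()]. `NULL` disables the filter.
#' @param min_length Minimum hit length, bp (default 100).
#' @param min_identity Minimum percent identity (default 90).
#' @param seed_k Seed length (default 11).
#' @return A data.frame of hits with the mitochondrial interval as the
#'   query side.
#' @export
find_plastid_inserts <- function(mito, plastid, annotations = NULL,
                                 min_length = 100, min_identity = 90,
                                 seed_k = 11L) {
  ids <- names(mito)
  if (is.null(ids)) ids <- paste0("chr", seq_along(mito))
  pid <- names(plastid) %||% "plastid"
  out <- list()
  for (i in seq_along(mito)) {
    h <- local_homology_search(mito[[i]], unname(plastid[[1L]]),
                               min_length = min_length,
                               min_identity = min_identity,
                               seed_k = seed_k,
                               query_id = ids[i], subject_id = pid)
    if (nrow(h)) out[[length(out) + 1L]] <- h
  }
  if (length(out) == 0L) return(.empty_hits())
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  if (!is.null(annotations) && nrow(annotations)) {
    overlaps <- vapply(seq_len(nrow(hits)), function(r) {
      any(annotations$seq_id == hits$query_id[r] &
            annotations$start < hits$q_end[r] &
            annotations$end > hits$q_start[r])
    }, TRUE)
    hits <- hits[!overlaps, , drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Write homology hits as BED and TSV
#'
#' The BED file carries the query-side intervals; the TSV carries both
#' coordinate pairs, strand, length and identity.
#'
#' @param hits Data.frame from [find_repeats()] or
#'   [find_plastid_inserts()].
#' @param bed_path,tsv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list of the paths written.
#' @export
write_hits <- function(hits, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    nm <- if (nrow(hits)) paste0(hits$subject_id, ":", hits$s_start, "-",
                                 hits$s_end, ":", hits$strand)
          else character(0)
    write_bed(data.frame(seq_id = hits$query_id, start = hits$q_start,
                         end = hits$q_end, name = nm,
                         score = round(hits$identity),
                         stringsAsFactors = FALSE),
              bed_path)
  }
  if (!is.null(tsv_path)) {
    write.table(hits, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(list(bed = bed_path, tsv = tsv_path))
}

#' Partition variants by overlap with plastid-origin regions
#'
#' Splits variant records into those outside and those inside a set of
#' intervals (typically MIPT regions). Reads mapping ambiguously between
#' a high-coverage plastid genome and its mitochondrial insert copies
#' produce false variant calls inside the inserts, so variants falling
#' in plastid-origin regions are excluded from diversity analyses. A
#' variant overlaps an interval when its reference span
#' `[pos, pos + nchar(ref))` shares at least one base with the interval
#' (intervals are 0-based, half-open, so a variant exactly at an
#' interval's `end` is kept).
#'
#' @param variants Data.frame with columns `seq_id`, `pos` (0-based),
#'   `ref`, `alt` (plus any pass-through columns), e.g. from
#'   [read_vcf()].
#' @param intervals Data.frame with columns `seq_id`, `start`, `end`
#'   (0-based half-open).
#' @param known_seqs Optional character vector of valid sequence ids;
#'   when given, a variant on any other sequence is an error.
#' @return A list with data.frames `kept` and `excluded`, both
#'   preserving input order; together they partition the input.
#' @export
mask_variants <- function(variants, intervals, known_seqs = NULL) {
  stopifnot(all(c("seq_id", "pos", "ref") %in% names(variants)),
            all(c("seq_id", "start", "end") %in% names(intervals)))
  if (!is.null(known_seqs)) {
    bad <- !(variants$seq_id %in% known_seqs)
    if (any(bad)) {
      stop("variant on unknown sequence id: ",
           paste(unique(variants$seq_id[bad]), collapse = ", "))
    }
  }
  if (nrow(variants) == 0L) {
    return(list(kept = variants, excluded = variants))
  }
  span_end <- variants$pos + nchar(variants$ref)
  excluded <- vapply(seq_len(nrow(variants)), function(r) {
    any(intervals$seq_id == variants$seq_id[r] &
          intervals$start < span_end[r] &
          intervals$end > variants$pos[r])
  }, TRUE)
  kept_df <- variants[!excluded, , drop = FALSE]
  excl_df <- variants[excluded, , drop = FALSE]
  rownames(kept_df) <- rownames(excl_df) <- NULL
  for (a in c("meta", "gt")) {
    m <- attr(variants, a)
    if (!is.null(m)) {
      attr(kept_df, a) <- if (a == "gt" && is.matrix(m))
        m[!excluded, , drop = FALSE] else m
      attr(excl_df, a) <- if (a == "gt" && is.matrix(m))
        m[excluded, , drop = FALSE] else m
    }
  }
  list(kept = kept_df, excluded = excl_df)
}
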