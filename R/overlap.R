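#' Extender configuration
#'
#' Collects the parameters governing one assembly run. The defaults are
#' the settings used for mitochondrial assembly from PacBio CCS reads:
#' a read must align to the contig's 3' edge over at least 8,000 bp at
#' 99% identity or better before its overhang is allowed to vote on the
#' extension, and reads are mapped against the terminal 15,000 bp of the
#' contig only. For plastome assembly the same machinery is run with
#' `min_read_similarity = 100`.
#'
#' @param min_read_similarity Minimum percent identity (matches /
#'   alignment columns, gap columns included) for a read-to-edge
#'   alignment to be accepted. Default 99.
#' @param min_mapped_part Minimum aligned read length on the edge, bp.
#'   Default 8000.
#' @param edge_size Length of the contig's 3' window that reads are
#'   mapped against, bp. Default 15000.
#' @param min_support Minimum number of reads that must back an
#'   extension (and cover every consensus column kept). Default 3: with
#'   8-12 kb reads and an 8 kb anchor requirement, only the read-length
#'   excess over the anchor can support a junction, so at moderate
#'   coverage the support at the sparsest position of a circle is easily
#'   an order of magnitude below mean coverage (see the methods
#'   vignette); 3 concordant low-error reads already give a reliable
#'   plurality vote. Raise it for high-coverage data.
#' @param fork_fraction A fork is declared when at least two alternative
#'   extensions each hold at least this fraction of the overhang
#'   support. In (0, 0.5]; default 0.2.
#' @param max_iterations Iteration cap for [assemble()]. Default 1000.
#' @param circular_min_overlap Minimum length of the terminal
#'   suffix/prefix duplication that declares the contig circular, bp.
#'   Default 1000.
#' @param end_slack Alignments must reach within this many bp of the
#'   edge's 3' terminus to count as reaching the contig end (absorbs
#'   terminal indel wobble). Default 10.
#' @param cluster_similarity Percent identity at which two overhangs
#'   co-cluster during consensus. `NULL` (default) derives it as
#'   `100 - 2 * (100 - min_read_similarity)`: read-vs-read comparisons
#'   accumulate the errors of both reads, twice the read-vs-contig rate.
#' @param seed_k Exact-match seed length used to locate candidate
#'   alignments before banded dynamic programming. Default 15.
#' @param band Half-width of the alignment band, bp. Default 150, ample
#'   for the <1% indel rates of CCS-like reads over 15 kb.
#' @return An object of class `extender_config`.
#' @export
extender_config <- function(min_read_similarity = 99,
                            min_mapped_part = 8000L,
                            edge_size = 15000L,
                            min_support = 3L,
                            fork_fraction = 0.2,
                            max_iterations = 1000L,
                            circular_min_overlap = 1000L,
                            end_slack = 10L,
                            cluster_similarity = NULL,
                            seed_k = 15L,
                            band = 150L) {
  stopifnot(min_read_similarity > 0, min_read_similarity <= 100,
            min_mapped_part >= 1, min_mapped_part <= edge_size,
            min_support >= 1,
            fork_fraction > 0, fork_fraction <= 0.5,
            max_iterations >= 1,
            circular_min_overlap >= 1,
            end_slack >= 0, seed_k >= 5, band >= 10)
  if (is.null(cluster_similarity)) {
    cluster_similarity <- max(0, 100 - 2 * (100 - min_read_similarity))
  }
  structure(list(
    min_read_similarity = min_read_similarity,
    min_mapped_part = as.integer(min_mapped_part),
    edge_size = as.integer(edge_size),
    min_support = as.integer(min_support),
    fork_fraction = fork_fraction,
    max_iterations = as.integer(max_iterations),
    circular_min_overlap = as.integer(circular_min_overlap),
    end_slack = as.integer(end_slack),
    cluster_similarity = cluster_similarity,
    seed_k = as.integer(seed_k),
    band = as.integer(band)
  ), class = "extender_config")
}

#' @export
print.extender_config <- function(x, ...) {
  cat("extender config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Extract the 3' edge of a contig
#'
#' Returns the last `min(edge_size, nchar(contig))` bases - the window
#' that reads are mapped against during extension.
#'
#' @param contig A single DNA sequence.
#' @param edge_size Window size in bp.
#' @return The edge sequence.
#' @export
extract_edge <- function(contig, edge_size) {
  .check_dna(contig, "contig")
  n <- nchar(contig)
  substr(contig, max(1L, n - as.integer(edge_size) + 1L), n)
}

# Modal seed diagonal for one read vs the edge. Returns NULL when there
# is no credible diagonal (fewer than min_seeds co-diagonal seeds).
.modal_diagonal <- function(seeds, band, min_seeds = 3L) {
  if (nrow(seeds) < min_seeds) return(NULL)
  d <- seeds[, 2L] - seeds[, 1L]           # tpos - qpos
  bin <- round(d / band)
  tab <- table(bin)
  top <- names(tab)[which.max(tab)]        # ties: first (lowest bin)
  sel <- d[bin == as.integer(top)]
  if (length(sel) < min_seeds) return(NULL)
  as.integer(round(median(sel)))
}

# Core acceptance test of one oriented read against the edge.
# Returns a list with accepted/reason and alignment details.
.align_one_orientation <- function(seq, edge, seeds, config) {
  elen <- nchar(edge)
  rlen <- nchar(seq)
  d <- .modal_diagonal(seeds, config$band)
  if (is.null(d)) {
    return(list(accepted = FALSE, reason = "low_identity", n_seeds = 0L))
  }
  n_seeds <- nrow(seeds)
  # projection of the read onto the edge: edge_pos = read_pos + d
  proj_end <- (rlen - 1L) + d              # edge coordinate of last base
  if (proj_end < elen - 1L - config$end_slack) {
    return(list(accepted = FALSE, reason = "internal_only",
                n_seeds = n_seeds))
  }
  ov_r_start <- max(0L, -d)                # first read base inside window
  ov_e_start <- ov_r_start + d             # >= 0
  a <- substr(seq, ov_r_start + 1L, rlen)
  b <- substr(edge, ov_e_start + 1L, elen)
  if (!nzchar(a) || !nzchar(b)) {
    return(list(accepted = FALSE, reason = "low_identity",
                n_seeds = n_seeds))
  }
  aln <- band_align_cpp(a, b, band = config$band, mode = 1L)
  if (!isTRUE(aln$feasible)) {
    # read cannot span the edge terminus within the band
    return(list(accepted = FALSE, reason = "no_overhang",
                n_seeds = n_seeds))
  }
  mapped_length <- aln$a_used
  identity <- 100 * aln$matches / aln$columns
  overhang <- substr(seq, ov_r_start + aln$a_used + 1L, rlen)
  if (!nzchar(overhang)) {
    return(list(accepted = FALSE, reason = "no_overhang",
                n_seeds = n_seeds, identity = identity,
                mapped_length = mapped_length))
  }
  if (mapped_length < config$min_mapped_part) {
    return(list(accepted = FALSE, reason = "short_mapped_part",
                n_seeds = n_seeds, identity = identity,
                mapped_length = mapped_length))
  }
  if (identity < config$min_read_similarity) {
    return(list(accepted = FALSE, reason = "low_identity",
                n_seeds = n_seeds, identity = identity,
                mapped_length = mapped_length))
  }
  list(accepted = TRUE, reason = NA_character_, n_seeds = n_seeds,
       identity = identity, mapped_length = mapped_length,
       edge_start = ov_e_start, edge_end = elen,
       overhang = overhang, reaches_contig_end = TRUE)
}

#' Align one read to the contig edge
#'
#' Attempts both the read and its reverse complement against the 3' edge
#' window. An alignment is accepted when (a) its identity (matches over
#' alignment columns, gaps included) reaches `min_read_similarity`, (b)
#' the aligned read part is at least `min_mapped_part` bp, and (c) the
#' alignment reaches the 3' terminus of the edge (within `end_slack`)
#' with the read continuing past it. The returned overhang is the
#' unaligned read suffix, already in contig orientation.
#'
#' @param read A single read sequence.
#' @param edge The contig's 3' edge (from [extract_edge()]).
#' @param config An [extender_config()].
#' @return A list: `accepted` (logical); on acceptance `orientation`
#'   (`"forward"`/`"reverse"`), `identity`, `mapped_length`,
#'   `edge_start`, `edge_end` (0-based half-open span on the edge),
#'   `overhang` and `reaches_contig_end`; on rejection `reason`, one of
#'   `low_identity`, `short_mapped_part`, `no_overhang`,
#'   `internal_only`.
#' @export
align_read_to_edge <- function(read, edge, config = extender_config()) {
  .check_dna(read, "read")
  .check_dna(edge, "edge")
  fwd <- read
  rev <- revcomp(read)
  seeds <- seed_hits_batch_cpp(c(fwd, rev), edge, config$seed_k)
  res_f <- .align_one_orientation(fwd, edge, seeds[[1L]], config)
  res_r <- .align_one_orientation(rev, edge, seeds[[2L]], config)
  if (res_f$accepted && res_r$accepted) {
    # palindromic corner case: prefer the higher-identity orientation,
    # forward on ties, for determinism
    pick <- if (res_r$identity > res_f$identity) "r" else "f"
  } else if (res_f$accepted) {
    pick <- "f"
  } else if (res_r$accepted) {
    pick <- "r"
  } else {
    # report the rejection from the orientation with more seed support
    res <- if (res_r$n_seeds > res_f$n_seeds) res_r else res_f
    return(list(accepted = FALSE, reason = res$reason))
  }
  res <- if (pick == "f") res_f else res_r
  res$orientation <- if (pick == "f") "forward" else "reverse"
  res
}

#' Collect overhanging reads at the contig's 3' end
#'
#' Runs [align_read_to_edge()] for every read against the contig's edge
#' window and returns the accepted alignments sorted by descending
#' overhang length. Rejection tallies by reason code are attached as the
#' `"rejections"` attribute.
#'
#' @param reads Named character vector of reads.
#' @param contig A single contig sequence.
#' @param config An [extender_config()].
#' @return A data.frame with columns `read_id`, `orientation`,
#'   `identity`, `mapped_length`, `edge_start`, `edge_end`, `overhang`,
#'   `reaches_contig_end`.
#' @export
collect_overhangs <- function(reads, contig, config = extender_config()) {
  .check_dna(contig, "contig")
  edge <- extract_edge(contig, config$edge_size)
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read_", seq_along(reads))
  fwd <- as.character(reads)
  rev <- revcomp(fwd)
  seeds <- seed_hits_batch_cpp(c(fwd, rev), edge, config$seed_k)
  n <- length(reads)
  acc <- vector("list", n)
  reasons <- character(n)
  for (i in seq_len(n)) {
    rf <- .align_one_orientation(fwd[i], edge, seeds[[i]], config)
    rr <- .align_one_orientation(rev[i], edge, seeds[[n + i]], config)
    if (rf$accepted && rr$accepted) {
      res <- if (rr$identity > rf$identity) rr else rf
      res$orientation <- if (rr$identity > rf$identity) "reverse" else "forward"
    } else if (rf$accepted) {
      res <- rf; res$orientation <- "forward"
    } else if (rr$accepted) {
      res <- rr; res$orientation <- "reverse"
    } else {
      reasons[i] <- if (rr$n_seeds > rf$n_seeds) rr$reason else rf$reason
      next
    }
    acc[[i]] <- data.frame(
      read_id = ids[i], orientation = res$orientation,
      identity = res$identity, mapped_length = res$mapped_length,
      edge_start = res$edge_start, edge_end = res$edge_end,
      overhang = res$overhang, reaches_contig_end = TRUE,
      stringsAsFactors = FALSE)
  }
  acc <- acc[!vapply(acc, is.null, TRUE)]
  out <- if (length(acc)) do.call(rbind, acc) else data.frame(
    read_id = character(0), orientation = character(0),
    identity = numeric(0), mapped_length = integer(0),
    edge_start = integer(0), edge_end = integer(0),
    overhang = character(0), reaches_contig_end = logical(0),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    out <- out[order(-nchar(out$overhang), out$read_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejections") <- table(factor(
    reasons[nzchar(reasons)],
    levels = c("low_identity", "short_mapped_part", "no_overhang",
               "internal_only")))
  out
}
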