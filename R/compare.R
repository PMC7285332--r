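#' Test whether two sequences are the same circle
#'
#' Circular molecules have no natural start point or strand, so two
#' assemblies of the same circle may be arbitrary rotations and/or
#' reverse complements of each other. This tests exact equality up to
#' rotation and strand.
#'
#' @param a,b Single DNA sequences.
#' @return `TRUE` when `b` equals some rotation of `a` or of its reverse
#'   complement.
#' @export
same_circle <- function(a, b) {
  a <- unname(as.character(a)); b <- unname(as.character(b))
  if (nchar(a) != nchar(b)) return(FALSE)
  doubled <- paste0(a, a)
  grepl(b, doubled, fixed = TRUE) || grepl(revcomp(b), doubled, fixed = TRUE)
}

#' Percent identity between two circular sequences
#'
#' Finds the best rotation and strand of `b` against `a` (via shared
#' seed k-mers against the doubled sequence) and computes the banded
#' global alignment identity. Intended for measuring how closely an
#' assembled circle matches a known truth.
#'
#' @param a Reference circle (single sequence).
#' @param b Assembled circle (single sequence).
#' @param band Alignment band half-width (default 200).
#' @param seed_k Seed length for locating the rotation (default 15).
#' @return Percent identity (matches over alignment columns) of the best
#'   rotation/strand, or 0 when no alignment is found.
#' @export
circular_identity <- function(a, b, band = 200L, seed_k = 15L) {
  a <- unname(as.character(a)); b <- unname(as.character(b))
  doubled <- paste0(a, a)
  best <- 0
  for (cand in c(b, revcomp(b))) {
    seeds <- seed_hits_batch_cpp(cand, doubled, as.integer(seed_k))[[1L]]
    if (nrow(seeds) == 0L) next
    d <- seeds[, 2L] - seeds[, 1L]
    d <- d[d >= 0 & d < nchar(a)]
    if (length(d) == 0L) next
    bin <- round(d / band)
    tab <- table(bin)
    off <- as.integer(round(median(d[bin == as.numeric(names(tab)[
      which.max(tab)])])))
    rot <- if (off == 0) a else rotate_circular(a, nchar(a) - off)
    # rot now starts where cand starts; global alignment of equal-ish spans
    aln <- band_align_cpp(cand, rot, band = as.integer(band), mode = 0L)
    if (isTRUE(aln$feasible) && aln$columns > 0) {
      best <- max(best, 100 * aln$matches / aln$columns)
    }
  }
  best
}
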