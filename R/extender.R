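# Star alignment of overhangs against the longest member (the anchor).
# members: character vector, longest first. Returns the per-member
# symbol matrix in anchor coordinates (0 uncovered, 1..4 = A,C,G,T,
# 5 = gap, 6 = N), the covered extent of each member, and any
# insertions relative to the anchor.
.star_matrix <- function(members, config) {
  anchor <- members[1L]
  al <- nchar(anchor)
  nmem <- length(members)
  base_code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  sym <- matrix(0L, nrow = nmem, ncol = al)
  cov_len <- integer(nmem)
  ins <- vector("list", nmem)   # per member: named list anchor_pos -> string
  for (i in seq_len(nmem)) {
    m <- members[i]
    lm <- nchar(m)
    if (m == substr(anchor, 1L, lm)) {
      # fast path: member is an exact prefix of the anchor
      ch <- strsplit(m, "", fixed = TRUE)[[1L]]
      v <- unname(base_code[ch])
      v[is.na(v)] <- 6L
      sym[i, seq_len(lm)] <- v
      cov_len[i] <- lm
      next
    }
    aln <- band_align_cpp(m, anchor, band = config$band, mode = 2L,
                          keep_alignment = TRUE)
    if (!isTRUE(aln$feasible)) next
    a <- strsplit(aln$a_aln, "", fixed = TRUE)[[1L]]  # member
    b <- strsplit(aln$b_aln, "", fixed = TRUE)[[1L]]  # anchor
    bpos <- 0L
    inserts <- list()
    pending <- character(0)
    for (col in seq_along(a)) {
      if (b[col] != "-") {
        if (length(pending)) {
          inserts[[as.character(bpos)]] <- paste(pending, collapse = "")
          pending <- character(0)
        }
        bpos <- bpos + 1L
        code <- unname(base_code[a[col]])
        sym[i, bpos] <- if (a[col] == "-") 5L
                        else if (is.na(code)) 6L else code
      } else if (a[col] != "-") {
        pending <- c(pending, a[col])
      }
    }
    if (length(pending)) {
      inserts[[as.character(bpos)]] <- paste(pending, collapse = "")
    }
    cov_len[i] <- aln$b_used
    ins[[i]] <- inserts
  }
  list(sym = sym, cov_len = cov_len, ins = ins, n = nmem, al = al)
}

# Column walk over a star alignment: plurality consensus truncated at
# the first column covered by fewer than min_support members. With
# detect_branch, stops at the first column where the second-most-common
# base is backed by at least max(2, fork_fraction * coverage) members -
# the signature of two genuinely different continuations - and reports
# the two member groups.
.column_walk <- function(star, config, detect_branch = FALSE) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (p in seq_len(star$al)) {
    covered <- star$cov_len >= p
    cov <- sum(covered)
    if (cov < config$min_support) break
    s <- star$sym[covered, p]
    counts <- tabulate(s[s >= 1L & s <= 4L], nbins = 4L)
    if (detect_branch) {
      ord <- order(counts, decreasing = TRUE)
      c2 <- counts[ord[2L]]
      if (c2 >= max(2, config$fork_fraction * cov)) {
        idx <- which(covered)
        g1 <- idx[star$sym[idx, p] == ord[1L]]
        g2 <- idx[star$sym[idx, p] == ord[2L]]
        return(list(consensus = paste(out, collapse = ""),
                    branch = list(col = p, g1 = g1, g2 = g2)))
      }
    }
    gap_n <- sum(s == 5L)
    if (gap_n <= cov / 2 && any(counts > 0L)) {
      out <- c(out, bases[which.max(counts)])  # ties: A < C < G < T
    }
    # insertion column after anchor position p: only when a majority of
    # the covering members inserted there
    key <- as.character(p)
    inserted <- vapply(seq_len(star$n), function(i) {
      covered[i] && !is.null(star$ins[[i]]) &&
        !is.null(star$ins[[i]][[key]])
    }, TRUE)
    if (sum(inserted) > cov / 2) {
      strs <- sort(vapply(which(inserted),
                          function(i) star$ins[[i]][[key]], ""))
      tab <- table(strs)
      out <- c(out, names(tab)[which.max(tab)])
    }
  }
  list(consensus = paste(out, collapse = ""), branch = NULL)
}

# Branch-free star consensus of a set of overhangs (longest first).
.star_consensus <- function(members, config) {
  .column_walk(.star_matrix(members, config), config)$consensus
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consensus of overhanging read parts
#'
#' Clusters overhangs by prefix similarity and collapses each cluster
#' into a consensus. Two overhangs co-cluster when their common-length
#' prefixes align at `cluster_similarity` percent identity or better
#' (clusters are seeded greedily from the longest overhang down, and a
#' new overhang joins the first cluster whose anchor it matches). Within
#' a cluster a star alignment anchored on the longest member is built and
#' each column takes the plurality base (ties broken A < C < G < T); a
#' gap wins a column only when more than half of the covering members
#' have one, in which case the column is omitted. The consensus stops at
#' the first column covered by fewer than `min_support` members, so the
#' contig is only ever extended as far as the evidence is deep enough.
#'
#' @param overhangs Character vector of overhang sequences (typically
#'   the `overhang` column of [collect_overhangs()] output).
#' @param config An [extender_config()].
#' @return A data.frame with columns `consensus` and `support`, sorted
#'   by descending support.
#' @details All overhangs start at the same contig position, so they
#'   are jointly star-aligned against the longest one and collapsed
#'   column by column. A branch - two different bases at one column,
#'   the minority backed by at least `max(2, fork_fraction * coverage)`
#'   members - splits the overhangs into two groups whose consensi are
#'   rebuilt independently and returned as two clusters; reads that end
#'   before the branch column are consistent with both alternatives and
#'   are credited to both supports. Without a branch a single cluster
#'   is returned.
#' @export
consensus_overhangs <- function(overhangs, config = extender_config()) {
  empty <- data.frame(consensus = character(0), support = integer(0),
                      stringsAsFactors = FALSE)
  overhangs <- as.character(overhangs)
  overhangs <- overhangs[nzchar(overhangs)]
  if (length(overhangs) == 0L) return(empty)
  ord <- order(-nchar(overhangs), overhangs)
  overhangs <- overhangs[ord]
  n <- length(overhangs)
  star <- .star_matrix(overhangs, config)
  walk <- .column_walk(star, config, detect_branch = TRUE)
  if (is.null(walk$branch)) {
    return(data.frame(consensus = walk$consensus, support = n,
                      stringsAsFactors = FALSE))
  }
  # two continuations: rebuild each group's consensus on its own
  # anchor. The coverage floor is capped at the group size: an
  # alternative is reported for the user, not appended to the contig,
  # so a branch backed by fewer than min_support reads must still show
  # its diverging sequence. When a group is too thin to extend past the
  # shared prefix, the prefix itself (covered by everyone) stands in.
  build_alt <- function(g) {
    mem <- overhangs[g]
    mem <- mem[order(-nchar(mem), mem)]
    alt_config <- config
    alt_config$min_support <- max(1L, min(config$min_support,
                                          length(mem) -
                                            (length(mem) >= 3L)))
    cons <- .star_consensus(mem, alt_config)
    if (nchar(cons) < nchar(walk$consensus)) walk$consensus else cons
  }
  alt1 <- build_alt(walk$branch$g1)
  alt2 <- build_alt(walk$branch$g2)
  # one reassignment round: a base shared by chance at the branch
  # column can put a read in the wrong group, so each member covering
  # the branch column is moved to the alternative its sequence matches
  # better, and the consensi are rebuilt from the refined groups
  if (alt1 != alt2) {
    covered <- which(star$cov_len >= walk$branch$col)
    sim_to <- function(s, cons) {
      L <- min(nchar(s), nchar(cons))
      if (L == 0L) return(0)
      a <- substr(s, 1L, L)
      b <- substr(cons, 1L, L)
      if (a == b) return(100)
      aln <- band_align_cpp(a, b, band = config$band, mode = 0L)
      if (isTRUE(aln$feasible) && aln$columns > 0) {
        100 * aln$matches / aln$columns
      } else 0
    }
    pick <- vapply(covered, function(i) {
      sim_to(overhangs[i], alt2) > sim_to(overhangs[i], alt1)
    }, TRUE)
    g1 <- covered[!pick]
    g2 <- covered[pick]
    if (length(g1) && length(g2)) {
      walk$branch$g1 <- g1
      walk$branch$g2 <- g2
      alt1 <- build_alt(g1)
      alt2 <- build_alt(g2)
    }
  }
  out <- data.frame(
    consensus = c(alt1, alt2),
    support = c(n - length(walk$branch$g2), n - length(walk$branch$g1)),
    stringsAsFactors = FALSE)
  out <- out[order(-out$support, -nchar(out$consensus), out$consensus), ,
             drop = FALSE]
  rownames(out) <- NULL
  # where the alternatives stop sharing sequence; used by detect_fork()
  # to judge whether they genuinely disagree
  attr(out, "prefix_len") <- nchar(walk$consensus)
  out
}

#' Fork decision over extension candidates
#'
#' A fork - the signature of a repeat-mediated branch point - is declared
#' when at least two alternative extensions each hold at least
#' `fork_fraction` of the total overhang support. Otherwise the top
#' cluster is the unique extension candidate.
#'
#' @param clusters Data.frame from [consensus_overhangs()] (sorted by
#'   descending support).
#' @param config An [extender_config()].
#' @param total Total overhang count that the support fractions are
#'   measured against. Defaults to `sum(clusters$support)`; callers
#'   that know the true number of overhangs (cluster supports can
#'   overlap, see [consensus_overhangs()]) should pass it.
#' @return A list: `fork` (logical), `alternatives` (the qualifying,
#'   genuinely distinct clusters), `candidate` (the top cluster row, or
#'   `NULL` when there are no clusters).
#' @details Eligible clusters that do not genuinely disagree in
#'   sequence describe the same extension, not alternatives - the
#'   smaller one is absorbed rather than reported as a branch. When the
#'   clusters carry a `prefix_len` attribute (set by
#'   [consensus_overhangs()] at a branch), disagreement is judged on
#'   the tails beyond the shared prefix: at least two mismatching
#'   columns and a tail identity below `cluster_similarity` are
#'   required, so a group formed by coincident sequencing errors (one
#'   mismatch, then near-perfect agreement) is absorbed while a true
#'   branch (whose tail is essentially unrelated sequence) is kept
#'   however short it is. Without the attribute, whole common prefixes
#'   are compared at `cluster_similarity`.
#' @export
detect_fork <- function(clusters, config = extender_config(),
                        total = NULL) {
  if (is.null(clusters) || nrow(clusters) == 0L) {
    return(list(fork = FALSE, alternatives = clusters, candidate = NULL))
  }
  if (is.null(total)) total <- sum(clusters$support)
  prefix_len <- attr(clusters, "prefix_len")
  eligible <- which(clusters$support >= config$fork_fraction * total)
  disagree <- function(a, b) {
    if (!is.null(prefix_len)) {
      a <- substr(a, prefix_len + 1L, nchar(a))
      b <- substr(b, prefix_len + 1L, nchar(b))
      L <- min(nchar(a), nchar(b))
      if (L == 0L) return(FALSE)
      a <- substr(a, 1L, L)
      b <- substr(b, 1L, L)
      if (a == b) return(FALSE)
      # both tails start at the same contig position (the branch
      # column), so they are compared ungapped and position by
      # position: aligning them with gaps would let random DNA reach
      # ~50-60% identity and blur the decision. Unrelated
      # continuations mismatch at ~75% of positions; tails that merely
      # carry scattered read errors mismatch at a few percent. The
      # verdict needs a window of at least 8 columns - shorter tails
      # cannot be told apart from error clusters and are absorbed, and
      # the next iteration, starting from the branch point itself,
      # sees the full-length divergence.
      if (L < 8L) return(FALSE)
      mism <- sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
                    strsplit(b, "", fixed = TRUE)[[1L]])
      return(mism >= 3L && mism / L >= 0.4)
    }
    L <- min(nchar(a), nchar(b))
    if (L == 0L) return(FALSE)
    aa <- substr(a, 1L, L)
    bb <- substr(b, 1L, L)
    idty <- if (aa == bb) 100 else {
      aln <- band_align_cpp(aa, bb, band = config$band, mode = 0L)
      if (isTRUE(aln$feasible) && aln$columns > 0) {
        100 * aln$matches / aln$columns
      } else 0
    }
    idty < config$cluster_similarity
  }
  # drop eligible clusters that do not really disagree with a
  # better-supported one
  distinct <- integer(0)
  for (i in eligible) {
    dup <- FALSE
    for (j in distinct) {
      if (!disagree(clusters$consensus[i], clusters$consensus[j])) {
        dup <- TRUE
        break
      }
    }
    if (!dup) distinct <- c(distinct, i)
  }
  fork <- length(distinct) >= 2L
  list(
    fork = fork,
    alternatives = clusters[distinct, , drop = FALSE],
    candidate = clusters[1L, , drop = FALSE]
  )
}

#' Test a contig for circularity
#'
#' A contig that has been extended past its own origin carries a
#' duplication: a suffix identical (up to sequencing error) to its
#' prefix. The contig is declared circular when a suffix of at least
#' `circular_min_overlap` bp aligns to the prefix at
#' `min_read_similarity` percent identity or better with both termini
#' anchored; the duplicated suffix is then trimmed so the returned
#' sequence contains the junction exactly once.
#'
#' @param contig A single contig sequence.
#' @param config An [extender_config()].
#' @return A list: `circular` (logical), `sequence` (trimmed on
#'   success, unchanged otherwise), `overlap` (bp of terminal
#'   duplication, 0 if not circular), `identity` (of the terminal
#'   alignment, `NA` if none).
#' @export
check_circular <- function(contig, config = extender_config()) {
  .check_dna(contig, "contig")
  n <- nchar(contig)
  not_circ <- list(circular = FALSE, sequence = contig, overlap = 0L,
                   identity = NA_real_)
  if (n <= 2L * config$circular_min_overlap) return(not_circ)
  W <- min(n - 1L, max(config$edge_size, 2L * config$circular_min_overlap))
  prefix <- substr(contig, 1L, W)
  suffix <- substr(contig, n - W + 1L, n)
  seeds <- seed_hits_batch_cpp(prefix, suffix, config$seed_k)[[1L]]
  if (nrow(seeds) == 0L) return(not_circ)
  off <- (n - W + seeds[, 2L]) - seeds[, 1L]  # candidate trimmed length
  x <- n - off                                # implied terminal overlap
  valid <- off > 0L & x >= config$circular_min_overlap & x <= W
  if (!any(valid)) return(not_circ)
  ob <- off[valid]
  bin <- round(ob / config$band)
  tab <- table(bin)
  top <- as.numeric(names(tab)[which.max(tab)])
  osel <- ob[bin == top]
  if (length(osel) < 3L) return(not_circ)
  o <- as.integer(round(median(osel)))
  x <- n - o
  a <- substr(contig, o + 1L, n)   # terminal copy
  b <- substr(contig, 1L, x)       # leading copy
  aln <- band_align_cpp(a, b, band = config$band, mode = 0L)
  if (!isTRUE(aln$feasible) || aln$columns == 0) return(not_circ)
  identity <- 100 * aln$matches / aln$columns
  if (identity < config$min_read_similarity ||
      aln$columns < config$circular_min_overlap) {
    return(not_circ)
  }
  list(circular = TRUE, sequence = substr(contig, 1L, o),
       overlap = x, identity = identity)
}

#' One extension iteration
#'
#' Runs the per-iteration pipeline: collect overhanging reads at the 3'
#' edge, build consensus clusters, test for a fork, test for
#' circularity. Status precedence is `circularized` > `fork` >
#' `dead_end` (no cluster with `min_support` reads) > `extended`; a
#' completed circle is a stronger, directly checkable claim than a
#' branch point, so it wins.
#'
#' @param contig A contig object (see [assemble()]) or a bare sequence.
#' @param reads Named character vector of reads.
#' @param config An [extender_config()].
#' @return A list with `contig` (updated) and `outcome`: `status`
#'   (one of `extended`, `dead_end`, `fork`, `circularized`),
#'   `consensus`, `support`, `alternatives` (data.frame),
#'   `iteration`, `n_overhangs`, `contig_length`, `rejections`.
#' @export
extend_iteration <- function(contig, reads, config = extender_config()) {
  if (is.character(contig)) {
    contig <- new_contig(contig)
  }
  stopifnot(inherits(contig, "contig"))
  if (isTRUE(contig$circular)) stop("contig is already circular")
  ov <- collect_overhangs(reads, contig$sequence, config)
  clusters <- consensus_overhangs(ov$overhang, config)
  fork <- detect_fork(clusters, config, total = nrow(ov))
  circ <- check_circular(contig$sequence, config)
  iteration <- length(contig$history) + 1L
  alternatives <- fork$alternatives
  if (circ$circular) {
    status <- "circularized"
    contig$sequence <- circ$sequence
    contig$circular <- TRUE
    consensus <- ""
    support <- NA_integer_
  } else if (fork$fork) {
    status <- "fork"
    consensus <- ""
    support <- NA_integer_
  } else if (nrow(clusters) == 0L ||
             clusters$support[1L] < config$min_support ||
             !nzchar(clusters$consensus[1L])) {
    status <- "dead_end"
    consensus <- ""
    support <- if (nrow(clusters)) clusters$support[1L] else 0L
  } else {
    status <- "extended"
    consensus <- clusters$consensus[1L]
    support <- clusters$support[1L]
    contig$sequence <- paste0(contig$sequence, consensus)
  }
  outcome <- list(
    status = status, consensus = consensus, support = support,
    alternatives = alternatives, iteration = iteration,
    n_overhangs = nrow(ov), contig_length = nchar(contig$sequence),
    circular_overlap = circ$overlap,
    rejections = attr(ov, "rejections")
  )
  contig$history[[iteration]] <- outcome
  list(contig = contig, outcome = outcome)
}

#' Create a contig object
#'
#' @param sequence Starter sequence (single character string; a contig
#'   from another assembly or simply one long read).
#' @param id Contig id (default `"contig1"`).
#' @param starter_id Id of the starter sequence, recorded for
#'   provenance.
#' @return An object of class `contig`.
#' @export
new_contig <- function(sequence, id = "contig1",
                       starter_id = names(sequence) %||% id) {
  .check_dna(unname(sequence), "starter")
  structure(list(
    id = id,
    sequence = unname(as.character(sequence)),
    circular = FALSE,
    history = list(),
    starter_id = starter_id,
    status = "seeded"
  ), class = "contig")
}

#' Targeted seed-and-extend assembly
#'
#' The main loop: starting from a seed sequence, reads are mapped to the
#' 3' edge of the growing contig, the overhanging read parts are
#' collapsed into a consensus, and the contig is extended - iterating
#' until it circularizes (its two ends become identical), dead-ends (no
#' extension with enough read support), forks (two or more alternative
#' extensions each backed by a substantial share of the reads, the
#' signature of a long repeat), or hits the iteration cap.
#'
#' On a fork the alternatives are reported so the caller can restart
#' from a chosen branch (append an alternative's consensus to the contig
#' sequence and call `assemble()` again with that as the starter).
#'
#' @param starter Starter sequence (single named or unnamed character
#'   string).
#' @param reads Named character vector of reads.
#' @param config An [extender_config()].
#' @param verbose Print one line per iteration.
#' @return A `contig` object: `sequence`, `circular`, `status` (one of
#'   `circularized`, `dead_end`, `fork`, `max_iterations`), `history`
#'   (list of per-iteration outcomes), `starter_id`.
#' @export
assemble <- function(starter, reads, config = extender_config(),
                     verbose = FALSE) {
  if (length(reads) == 0L) stop("no reads")
  contig <- if (inherits(starter, "contig")) starter else new_contig(starter)
  for (i in seq_len(config$max_iterations)) {
    step <- extend_iteration(contig, reads, config)
    contig <- step$contig
    st <- step$outcome$status
    if (verbose) {
      message(sprintf(
        "iteration %d: %s | contig %d bp | support %s | overhangs %d",
        step$outcome$iteration, st, step$outcome$contig_length,
        format(step$outcome$support), step$outcome$n_overhangs))
    }
    if (st != "extended") {
      contig$status <- st
      return(contig)
    }
  }
  contig$status <- "max_iterations"
  contig
}

#' @export
print.contig <- function(x, ...) {
  cat("contig", x$id, "-", nchar(x$sequence), "bp,",
      if (x$circular) "circular" else "linear",
      "| status:", x$status,
      "|", length(x$history), "iterations\n")
  invisible(x)
}

#' Per-iteration assembly log
#'
#' @param contig A `contig` from [assemble()].
#' @return A data.frame with one row per iteration: `iteration`,
#'   `status`, `contig_length`, `support`, `n_overhangs`,
#'   `n_alternatives`, and the rejection tallies by reason code.
#' @export
assembly_log <- function(contig) {
  stopifnot(inherits(contig, "contig"))
  if (length(contig$history) == 0L) {
    return(data.frame(iteration = integer(0), status = character(0),
                      contig_length = integer(0), support = integer(0),
                      n_overhangs = integer(0),
                      n_alternatives = integer(0)))
  }
  rows <- lapply(contig$history, function(h) {
    rej <- as.list(h$rejections)
    data.frame(
      iteration = h$iteration, status = h$status,
      contig_length = h$contig_length,
      support = if (is.na(h$support)) NA_integer_ else h$support,
      n_overhangs = h$n_overhangs,
      n_alternatives = if (h$status == "fork") nrow(h$alternatives) else 0L,
      rej_low_identity = rej$low_identity %||% 0L,
      rej_short_mapped_part = rej$short_mapped_part %||% 0L,
      rej_no_overhang = rej$no_overhang %||% 0L,
      rej_internal_only = rej$internal_only %||% 0L,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write the final contig as FASTA
#'
#' The header carries `circular=true|false` so downstream tools can tell
#' a closed circle from a linear or interrupted assembly.
#'
#' @param contig A `contig` object.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_contig <- function(contig, path) {
  stopifnot(inherits(contig, "contig"))
  seqs <- setNames(contig$sequence,
                   paste0(contig$id, " circular=",
                          if (contig$circular) "true" else "false"))
  write_seqs(seqs, path, format = "fasta")
}
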