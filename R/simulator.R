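# random DNA of length n (uses the current RNG stream)
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# introduce exactly round(rate * n) substitutions at distinct random
# positions, so a planted copy has a well-defined nominal identity
.diverge <- function(seq, identity) {
  n <- nchar(seq)
  nmut <- round((100 - identity) / 100 * n)
  if (nmut == 0L) return(seq)
  pos <- sample.int(n, nmut)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
  }
  paste(ch, collapse = "")
}

# pick a placement interval of length len on a chromosome, at least
# `margin` bp away from the ends and from every occupied interval;
# errors after max_try failures
.place <- function(chrom_len, len, occupied, margin = 200L,
                   max_try = 200L) {
  lo <- margin
  hi <- chrom_len - len - margin
  if (hi < lo) stop("feature of length ", len,
                    " cannot be placed on a chromosome of length ",
                    chrom_len)
  for (t in seq_len(max_try)) {
    start <- sample(lo:hi, 1L)
    end <- start + len
    clash <- any(vapply(occupied, function(iv) {
      iv[1L] - margin < end && iv[2L] + margin > start
    }, TRUE))
    if (!clash) return(c(start, end))
  }
  stop("could not place a feature of length ", len,
       " without overlap; chromosome too crowded")
}

#' Simulate a multipartite circular genome
#'
#' Generates one or more chromosomes of i.i.d.-uniform random DNA, plus
#' a plastid sequence, and plants structured features into them:
#' repeats (a segment copied within or across chromosomes, optionally
#' inverted, diverged to a stated identity by substitutions) and
#' plastid-derived inserts (segments copied from the simulated plastid
#' into a mitochondrial chromosome). Every planted feature is recorded
#' with its true coordinates, so downstream detections can be scored
#' against truth. Deterministic given `seed`.
#'
#' @param lengths Integer vector of chromosome lengths, bp.
#' @param repeat_spec List of repeat descriptions, each a list/vector
#'   with elements `length`, `identity` (percent), `orientation`
#'   (`"direct"`/`"inverted"`), `scope` (`"intra"`/`"inter"`).
#' @param mipt_spec List of insert descriptions, each with `length`,
#'   `identity`, `chromosome` (index of the receiving chromosome).
#' @param plastid_length Length of the simulated plastid, bp (default
#'   15000).
#' @param circular Logical: are the chromosomes circular molecules
#'   (default `TRUE`)? Affects read sampling in [simulate_reads()].
#' @param seed Integer seed.
#' @return An object of class `sim_genome`: `chromosomes` (named
#'   character vector `chr1`, `chr2`, ...), `plastid`,
#'   `planted_repeats` and `planted_mipts` (data.frames in hit
#'   coordinates, 0-based half-open), `circular`, `seed`.
#' @export
simulate_genome <- function(lengths = 30000L, repeat_spec = NULL,
                            mipt_spec = NULL, plastid_length = 15000L,
                            circular = TRUE, seed = 1L) {
  stopifnot(all(lengths > 0), plastid_length > 0)
  withr::with_seed(as.integer(seed), {
    nchr <- length(lengths)
    chroms <- vapply(lengths, .random_dna, "")
    names(chroms) <- paste0("chr", seq_len(nchr))
    plastid <- c(plastid = .random_dna(plastid_length))
    occupied <- rep(list(list()), nchr)
    reps <- list()
    for (spec in repeat_spec) {
      spec <- as.list(spec)
      len <- as.integer(spec$length)
      idty <- as.numeric(spec$identity)
      orientation <- match.arg(spec$orientation, c("direct", "inverted"))
      scope <- match.arg(spec$scope, c("intra", "inter"))
      src_chr <- sample.int(nchr, 1L)
      dst_chr <- if (scope == "intra") src_chr else {
        if (nchr < 2L) stop("inter-chromosome repeat needs >= 2 chromosomes")
        others <- setdiff(seq_len(nchr), src_chr)
        others[sample.int(length(others), 1L)]
      }
      src <- .place(lengths[src_chr], len, occupied[[src_chr]])
      occupied[[src_chr]] <- c(occupied[[src_chr]], list(src))
      segment <- substr(chroms[src_chr], src[1L] + 1L, src[2L])
      copy <- .diverge(segment, idty)
      if (orientation == "inverted") copy <- revcomp(copy)
      dst <- .place(lengths[dst_chr], len, occupied[[dst_chr]])
      occupied[[dst_chr]] <- c(occupied[[dst_chr]], list(dst))
      substr(chroms[dst_chr], dst[1L] + 1L, dst[2L]) <- copy
      reps[[length(reps) + 1L]] <- data.frame(
        query_id = names(chroms)[src_chr], q_start = src[1L],
        q_end = src[2L],
        subject_id = names(chroms)[dst_chr], s_start = dst[1L],
        s_end = dst[2L],
        strand = if (orientation == "direct") "forward" else "reverse",
        length = len, identity = idty, stringsAsFactors = FALSE)
    }
    mipts <- list()
    p_occupied <- list()
    for (spec in mipt_spec) {
      spec <- as.list(spec)
      len <- as.integer(spec$length)
      idty <- as.numeric(spec$identity)
      chr <- as.integer(spec$chromosome)
      src <- .place(plastid_length, len, p_occupied)
      p_occupied <- c(p_occupied, list(src))
      segment <- substr(plastid, src[1L] + 1L, src[2L])
      copy <- .diverge(segment, idty)
      dst <- .place(lengths[chr], len, occupied[[chr]])
      occupied[[chr]] <- c(occupied[[chr]], list(dst))
      substr(chroms[chr], dst[1L] + 1L, dst[2L]) <- copy
      mipts[[length(mipts) + 1L]] <- data.frame(
        query_id = names(chroms)[chr], q_start = dst[1L], q_end = dst[2L],
        subject_id = "plastid", s_start = src[1L], s_end = src[2L],
        strand = "forward", length = len, identity = idty,
        stringsAsFactors = FALSE)
    }
    structure(list(
      chromosomes = chroms,
      plastid = plastid,
      planted_repeats = if (length(reps)) do.call(rbind, reps)
                        else .empty_hits(),
      planted_mipts = if (length(mipts)) do.call(rbind, mipts)
                      else .empty_hits(),
      circular = circular,
      seed = as.integer(seed)
    ), class = "sim_genome")
  })
}

#' @export
print.sim_genome <- function(x, ...) {
  cat("simulated genome:", length(x$chromosomes),
      if (x$circular) "circular" else "linear",
      "chromosome(s) of", paste(nchar(x$chromosomes), collapse = ", "),
      "bp; plastid", nchar(x$plastid), "bp\n")
  cat("  planted repeats:", nrow(x$planted_repeats),
      "| planted plastid inserts:", nrow(x$planted_mipts),
      "| seed:", x$seed, "\n")
  invisible(x)
}

# apply i.i.d. per-base substitution / insertion / deletion errors;
# returns list(seq, n_sub, n_ins, n_del)
.mutate_read <- function(seq, p_sub, p_ins, p_del) {
  n <- nchar(seq)
  if (p_sub + p_ins + p_del == 0) {
    return(list(seq = seq, n_sub = 0L, n_ins = 0L, n_del = 0L))
  }
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  sub_at <- runif(n) < p_sub
  n_sub <- sum(sub_at)
  if (n_sub) {
    ch[sub_at] <- vapply(ch[sub_at],
                         function(b) sample(setdiff(bases, b), 1L), "")
  }
  del_at <- runif(n) < p_del
  ins_at <- runif(n) < p_ins
  n_del <- sum(del_at)
  n_ins <- sum(ins_at)
  if (n_del || n_ins) {
    pieces <- ch
    pieces[del_at] <- ""
    if (n_ins) {
      ins_bases <- sample(bases, n_ins, replace = TRUE)
      pieces[ins_at] <- paste0(pieces[ins_at], ins_bases)
    }
    out <- paste(pieces, collapse = "")
  } else {
    out <- paste(ch, collapse = "")
  }
  list(seq = out, n_sub = n_sub, n_ins = n_ins, n_del = n_del)
}

#' Simulate long reads from a genome
#'
#' Emulates a low-error long-read (PacBio CCS-like) run over the
#' simulated chromosomes. Start positions are uniform; on circular
#' chromosomes reads may wrap the origin, on linear ones reads are
#' truncated at the molecule ends (fragments of a linear molecule really
#' do end at its termini). Read lengths are truncated-normal, strands
#' uniform, and substitution/insertion/deletion errors i.i.d. per base.
#' The true origin of every read is recorded. Deterministic given
#' `seed`.
#'
#' @param genome A `sim_genome`, or a named character vector of
#'   chromosome sequences.
#' @param coverage Target fold-coverage per chromosome (default 50).
#' @param read_length Numeric vector `(mean, sd, min, max)` of the read
#'   length distribution, bp. Default `c(10000, 1000, 8000, 12000)`.
#' @param error_rate Numeric vector `(substitution, insertion,
#'   deletion)` of per-base error rates. Default
#'   `c(0.003, 0.001, 0.001)` (0.5% total, CCS-like).
#' @param circular Logical; defaults to the genome's flag (`TRUE` for a
#'   bare character vector).
#' @param seed Integer seed.
#' @return An object of class `sim_reads`: `reads` (named character
#'   vector with flat-quality `"qualities"` attribute) and `origins` (a
#'   data.frame: `read_id`, `chrom`, `start` (0-based), `fragment_length`,
#'   `strand`, `n_sub`, `n_ins`, `n_del`).
#' @export
simulate_reads <- function(genome, coverage = 50,
                           read_length = c(10000, 1000, 8000, 12000),
                           error_rate = c(0.003, 0.001, 0.001),
                           circular = NULL, seed = 1L) {
  if (inherits(genome, "sim_genome")) {
    chroms <- genome$chromosomes
    if (is.null(circular)) circular <- genome$circular
  } else {
    chroms <- genome
    if (is.null(circular)) circular <- TRUE
  }
  stopifnot(coverage > 0, length(read_length) == 4L,
            read_length[3L] <= read_length[1L],
            read_length[1L] <= read_length[4L],
            length(error_rate) == 3L, all(error_rate >= 0))
  rl_mean <- read_length[1L]; rl_sd <- read_length[2L]
  rl_min <- read_length[3L]; rl_max <- read_length[4L]
  withr::with_seed(as.integer(seed), {
    reads <- character(0)
    origins <- list()
    idx <- 0L
    for (ci in seq_along(chroms)) {
      chrom <- chroms[[ci]]
      cname <- names(chroms)[ci] %||% paste0("chr", ci)
      L <- nchar(chrom)
      n <- max(1L, round(coverage * L / rl_mean))
      doubled <- paste0(chrom, chrom)
      for (r in seq_len(n)) {
        idx <- idx + 1L
        repeat {
          rl <- round(rnorm(1L, rl_mean, rl_sd))
          if (rl >= rl_min && rl <= rl_max) break
        }
        rl <- min(rl, L)
        start <- sample.int(L, 1L) - 1L
        if (circular) {
          frag <- substr(doubled, start + 1L, start + rl)
        } else {
          frag <- substr(chrom, start + 1L, min(start + rl, L))
        }
        mut <- .mutate_read(frag, error_rate[1L], error_rate[2L],
                            error_rate[3L])
        strand <- if (runif(1L) < 0.5) "+" else "-"
        out_seq <- if (strand == "-") revcomp(mut$seq) else mut$seq
        reads[[sprintf("read_%05d", idx)]] <- out_seq
        origins[[idx]] <- data.frame(
          read_id = sprintf("read_%05d", idx), chrom = cname,
          start = start, fragment_length = nchar(frag), strand = strand,
          n_sub = mut$n_sub, n_ins = mut$n_ins, n_del = mut$n_del,
          stringsAsFactors = FALSE)
      }
    }
    origins <- do.call(rbind, origins)
    attr(reads, "qualities") <- setNames(
      vapply(nchar(reads), function(nn) strrep("I", nn), ""),
      names(reads))
    structure(list(reads = reads, origins = origins,
                   seed = as.integer(seed)),
              class = "sim_reads")
  })
}

#' @export
print.sim_reads <- function(x, ...) {
  cat("simulated read set:", length(x$reads), "reads,",
      sum(nchar(x$reads)), "bp total | seed:", x$seed, "\n")
  invisible(x)
}

#' Write a simulation to disk
#'
#' Emits the genome FASTA, plastid FASTA, reads FASTQ (flat qualities)
#' and plain-text truth tables (read origins as TSV; planted repeats and
#' inserts as TSV and BED).
#'
#' @param genome A `sim_genome`.
#' @param readset A `sim_reads` (or `NULL` to skip reads).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named list of paths written.
#' @export
write_simulation <- function(genome, readset = NULL, dir = ".") {
  stopifnot(inherits(genome, "sim_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fasta"),
    plastid = file.path(dir, "plastid.fasta"),
    repeats_tsv = file.path(dir, "truth_repeats.tsv"),
    repeats_bed = file.path(dir, "truth_repeats.bed"),
    mipts_tsv = file.path(dir, "truth_mipts.tsv"),
    mipts_bed = file.path(dir, "truth_mipts.bed")
  )
  write_seqs(genome$chromosomes, paths$genome)
  write_seqs(genome$plastid, paths$plastid)
  write_hits(genome$planted_repeats, paths$repeats_bed, paths$repeats_tsv)
  write_hits(genome$planted_mipts, paths$mipts_bed, paths$mipts_tsv)
  if (!is.null(readset)) {
    stopifnot(inherits(readset, "sim_reads"))
    paths$reads <- file.path(dir, "reads.fastq")
    paths$origins <- file.path(dir, "truth_reads.tsv")
    write_seqs(readset$reads, paths$reads, format = "fastq")
    write.table(readset$origins, paths$origins, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' Apply sequencing errors to an existing read set
#'
#' Adds i.i.d. per-base substitution/insertion/deletion errors to reads
#' that were already sampled (for example an error-free set from
#' [simulate_reads()]), leaving the sampling layout untouched. This
#' gives a controlled comparison: the same molecules and coordinates,
#' with and without noise. Deterministic given `seed`.
#'
#' @param reads Named character vector of reads, or a `sim_reads`.
#' @param error_rate Numeric vector `(substitution, insertion,
#'   deletion)` of per-base rates.
#' @param seed Integer seed.
#' @return A named character vector of mutated reads (qualities, when
#'   present, are reset to flat).
#' @export
add_read_errors <- function(reads, error_rate = c(0.01, 0, 0),
                            seed = 1L) {
  if (inherits(reads, "sim_reads")) reads <- reads$reads
  stopifnot(length(error_rate) == 3L, all(error_rate >= 0))
  withr::with_seed(as.integer(seed), {
    out <- vapply(reads, function(s)
      .mutate_read(s, error_rate[1L], error_rate[2L],
                   error_rate[3L])$seq, "")
    names(out) <- names(reads)
    attr(out, "qualities") <- setNames(
      vapply(nchar(out), function(nn) strrep("I", nn), ""), names(out))
    out
  })
}
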