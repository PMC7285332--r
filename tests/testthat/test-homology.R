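test_that("planted repeats are recovered at the length/identity thresholds", {
  g <- simulate_genome(
    lengths = c(30000, 30000),
    repeat_spec = list(
      list(length = 600, identity = 96, orientation = "direct",
           scope = "intra"),
      list(length = 400, identity = 100, orientation = "direct",
           scope = "intra"),
      list(length = 1000, identity = 100, orientation = "inverted",
           scope = "inter")),
    seed = 71)
  hits <- find_repeats(g$chromosomes, min_length = 500, min_identity = 95)
  expect_equal(nrow(hits), 2L)  # the 400 bp copy is below min_length
  truth <- g$planted_repeats
  # the 600 bp / 96% intra-chromosome pair, within 10 bp of truth
  t600 <- truth[truth$length == 600, ]
  h600 <- hits[hits$strand == "forward", ]
  expect_equal(nrow(h600), 1L)
  # copy pairs are unordered: compare {query, subject} as a set
  hit_iv <- list(c(h600$q_start, h600$q_end), c(h600$s_start, h600$s_end))
  tru_iv <- list(c(t600$q_start, t600$q_end), c(t600$s_start, t600$s_end))
  pair_dist <- function(a, b) max(abs(a[[1]] - b[[1]]), abs(a[[2]] - b[[2]]))
  expect_lt(min(pair_dist(hit_iv, tru_iv),
                pair_dist(hit_iv, rev(tru_iv))), 10)
  expect_gte(h600$identity, 95)
  # the inverted inter-chromosome pair carries strand = reverse
  hinv <- hits[hits$strand == "reverse", ]
  expect_equal(nrow(hinv), 1L)
  expect_false(hinv$query_id == hinv$subject_id)
})

test_that("repeat-free random sequences yield no hits at (500 bp, 95%)", {
  g <- simulate_genome(lengths = c(30000, 30000), seed = 72)
  hits <- find_repeats(g$chromosomes, min_length = 500, min_identity = 95)
  expect_equal(nrow(hits), 0L)
})

test_that("hit coordinates are symmetric under query/subject swap", {
  g <- simulate_genome(
    lengths = c(20000, 20000),
    repeat_spec = list(list(length = 2000, identity = 100,
                            orientation = "direct", scope = "inter")),
    seed = 73)
  a <- local_homology_search(g$chromosomes[[1]], g$chromosomes[[2]],
                             min_length = 500, min_identity = 95,
                             query_id = "chr1", subject_id = "chr2")
  b <- local_homology_search(g$chromosomes[[2]], g$chromosomes[[1]],
                             min_length = 500, min_identity = 95,
                             query_id = "chr2", subject_id = "chr1")
  expect_equal(nrow(a), 1L)
  expect_equal(nrow(b), 1L)
  expect_equal(a$q_start, b$s_start)
  expect_equal(a$s_start, b$q_start)
  expect_equal(a$length, b$length)
})

test_that("identity of a recovered repeat matches exact dynamic programming", {
  g <- simulate_genome(
    lengths = 20000,
    repeat_spec = list(list(length = 800, identity = 96,
                            orientation = "direct", scope = "intra")),
    seed = 74)
  hit <- find_repeats(g$chromosomes, min_length = 500, min_identity = 90)
  expect_equal(nrow(hit), 1L)
  qa <- substr(g$chromosomes[[1]], hit$q_start + 1, hit$q_end)
  sa <- substr(g$chromosomes[[1]], hit$s_start + 1, hit$s_end)
  expect_equal(hit$identity, identity_oracle(qa, sa), tolerance = 0.01)
})

test_that("thresholds are monotone: loosening never removes a hit", {
  g <- simulate_genome(
    lengths = 20000,
    repeat_spec = list(list(length = 700, identity = 96,
                            orientation = "direct", scope = "intra")),
    seed = 75)
  strict <- find_repeats(g$chromosomes, min_length = 600,
                         min_identity = 95)
  loose_len <- find_repeats(g$chromosomes, min_length = 300,
                            min_identity = 95)
  loose_id <- find_repeats(g$chromosomes, min_length = 600,
                           min_identity = 90)
  key <- function(h) paste(h$q_start, h$s_start)
  expect_true(all(key(strict) %in% key(loose_len)))
  expect_true(all(key(strict) %in% key(loose_id)))
})

test_that("plastid inserts are reported unless they overlap annotations", {
  g <- simulate_genome(
    lengths = 30000,
    mipt_spec = list(list(length = 3000, identity = 97, chromosome = 1)),
    seed = 76)
  hits <- find_plastid_inserts(g$chromosomes, g$plastid)
  expect_equal(nrow(hits), 1L)
  t <- g$planted_mipts
  expect_lt(abs(hits$q_start - t$q_start), 10)
  expect_lt(abs(hits$q_end - t$q_end), 10)
  expect_gte(hits$identity, 90)
  # an annotation overlapping the insert by >= 1 bp suppresses it
  ann <- data.frame(seq_id = "chr1", start = t$q_end - 50L,
                    end = t$q_end + 500L, stringsAsFactors = FALSE)
  expect_equal(nrow(find_plastid_inserts(g$chromosomes, g$plastid,
                                         annotations = ann)), 0L)
  # an annotation elsewhere does not
  far <- data.frame(seq_id = "chr1", start = 0L, end = 50L)
  expect_equal(nrow(find_plastid_inserts(g$chromosomes, g$plastid,
                                         annotations = far)), 1L)
})

test_that("short perfect plastid matches fall below the length cut-off", {
  g <- simulate_genome(lengths = 30000, seed = 77)
  chrom <- g$chromosomes
  # plant an 80 bp perfect plastid segment by hand
  substr(chrom[[1]], 10001, 10080) <- substr(g$plastid, 2001, 2080)
  hits <- find_plastid_inserts(chrom, g$plastid,
                               min_length = 100, min_identity = 90)
  expect_equal(nrow(hits), 0L)
  # it is found once the cut-off admits it
  hits2 <- find_plastid_inserts(chrom, g$plastid,
                                min_length = 60, min_identity = 90)
  expect_equal(nrow(hits2), 1L)
})

test_that("variant masking partitions by half-open interval overlap", {
  iv <- data.frame(seq_id = "chr1", start = c(100L, 500L),
                   end = c(200L, 600L))
  v <- data.frame(
    seq_id = "chr1",
    pos = c(99L, 100L, 150L, 199L, 200L, 550L, 700L),
    ref = c("AC", "A", "A", "A", "A", "A", "A"),
    alt = "T", stringsAsFactors = FALSE)
  res <- mask_variants(v, iv)
  # pos 99 with 2 bp ref reaches into [100,200); pos 200 is outside
  expect_equal(res$excluded$pos, c(99L, 100L, 150L, 199L, 550L))
  expect_equal(res$kept$pos, c(200L, 700L))
  expect_equal(nrow(res$kept) + nrow(res$excluded), nrow(v))
  expect_error(mask_variants(v, iv, known_seqs = "chr2"))
})

test_that("random variants are partitioned exactly as a brute-force oracle says", {
  set.seed(81)
  iv <- data.frame(seq_id = "chr1",
                   start = c(2000L, 12000L, 25000L),
                   end = c(3000L, 12500L, 26000L))
  out_pos <- sample(setdiff(0:29999, c(2000:2999, 12000:12499,
                                       25000:25999)), 97)
  in_pos <- c(2500L, 12100L, 25999L)
  v <- data.frame(seq_id = "chr1", pos = sample(c(out_pos, in_pos)),
                  ref = "A", alt = "G", stringsAsFactors = FALSE)
  res <- mask_variants(v, iv)
  oracle <- vapply(seq_len(nrow(v)), function(i)
    overlaps_oracle(v$pos[i], 1L, iv, "chr1"), TRUE)
  expect_equal(sort(res$excluded$pos), sort(v$pos[oracle]))
  expect_equal(nrow(res$excluded), 3L)
  expect_equal(res$kept$pos, v$pos[!oracle])  # order preserved
})

test_that("VCF records round-trip with pass-through fields intact", {
  p <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=30000>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    "chr1\t100\t.\tA\tT\t50\tPASS\tDP=10",
    "chr1\t5000\trs1\tAC\tA\t99\tPASS\tDP=22;AF=0.5"), p)
  v <- read_vcf(p)
  expect_equal(v$pos, c(99L, 4999L))  # 0-based
  p2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(v, p2)
  expect_identical(readLines(p2), readLines(p))
  # empty VCF: header preserved, zero records
  pe <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), pe)
  ve <- read_vcf(pe)
  expect_equal(nrow(ve), 0L)
  res <- mask_variants(ve, data.frame(seq_id = "chr1", start = 1L,
                                      end = 10L))
  expect_equal(nrow(res$kept), 0L)
  expect_equal(nrow(res$excluded), 0L)
})
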