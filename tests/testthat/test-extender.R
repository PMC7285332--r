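test_that("unanimous overhangs give their common sequence as consensus", {
  cfg <- extender_config(min_support = 3)
  cl <- consensus_overhangs(rep("ACGTACGT", 10), cfg)
  expect_equal(nrow(cl), 1L)
  expect_identical(cl$consensus, "ACGTACGT")
  expect_equal(cl$support, 10L)
  expect_equal(nrow(consensus_overhangs(character(0), cfg)), 0L)
})

test_that("column plurality overrides a single deviant overhang", {
  base <- random_dna(400, seed = 61)
  mutant <- substitute_bases(base, 1, seed = 62)
  cl <- consensus_overhangs(c(rep(base, 9), mutant), extender_config())
  expect_equal(nrow(cl), 1L)
  expect_identical(cl$consensus, base)
  expect_equal(cl$support, 10L)
})

test_that("divergent overhangs split into separate clusters", {
  a <- random_dna(300, seed = 63)
  b <- random_dna(300, seed = 64)
  cl <- consensus_overhangs(c(rep(a, 5), rep(b, 5)), extender_config())
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$support, c(5L, 5L))
  expect_setequal(cl$consensus, c(a, b))
})

test_that("consensus truncates where coverage drops below min_support", {
  base <- random_dna(500, seed = 65)
  members <- c(rep(base, 3), rep(substr(base, 1, 200), 4))
  cl <- consensus_overhangs(members, extender_config(min_support = 5))
  expect_equal(nrow(cl), 1L)
  # only the first 200 columns are covered by >= 5 members
  expect_identical(cl$consensus, substr(base, 1, 200))
  expect_equal(cl$support, 7L)
})

test_that("fork calls depend on the support fractions", {
  cfg <- extender_config(fork_fraction = 0.2)
  even <- data.frame(consensus = c("A", "C"), support = c(50L, 50L))
  expect_true(detect_fork(even, cfg)$fork)
  skewed <- data.frame(consensus = c("A", "C"), support = c(97L, 3L))
  d <- detect_fork(skewed, cfg)
  expect_false(d$fork)
  expect_identical(d$candidate$consensus, "A")
  single <- data.frame(consensus = "A", support = 4L)
  expect_false(detect_fork(single, cfg)$fork)
  expect_false(detect_fork(single[0, ], cfg)$fork)
})

test_that("terminal duplication is detected and trimmed exactly", {
  truth <- random_dna(30000, seed = 66)
  cfg <- extender_config()
  over <- paste0(truth, substr(truth, 1, 2000))
  res <- check_circular(over, cfg)
  expect_true(res$circular)
  expect_identical(res$sequence, truth)
  expect_equal(res$overlap, 2000L)
  # a plain random sequence is not circular
  expect_false(check_circular(truth, cfg)$circular)
})

test_that("junction identity is compared against min_read_similarity", {
  truth <- random_dna(30000, seed = 67)
  # suffix copy at 98% identity: circular at threshold 99 (config for
  # noisy data) but not at the plastid run's 100%
  noisy_prefix <- substitute_bases(substr(truth, 1, 2000), 40, seed = 68)
  over <- paste0(truth, noisy_prefix)
  strict <- extender_config(min_read_similarity = 100)
  loose <- extender_config(min_read_similarity = 98)
  expect_false(check_circular(over, strict)$circular)
  expect_true(check_circular(over, loose)$circular)
})

test_that("an iteration with no overhangs is a dead end", {
  reads <- setNames(vapply(1:5, function(i) random_dna(3000), ""),
                    paste0("r", 1:5))
  contig <- random_dna(8000, seed = 69)
  step <- extend_iteration(contig, reads,
                           extender_config(min_mapped_part = 2000,
                                           edge_size = 5000))
  expect_identical(step$outcome$status, "dead_end")
  expect_identical(step$contig$sequence, contig)
})

test_that("unanimous overhangs extend the contig by their full length", {
  truth <- random_dna(12000, seed = 70)
  contig <- substr(truth, 1, 6000)
  # five reads anchored 3000 bp, overhanging 2000 bp
  reads <- setNames(rep(substr(truth, 3001, 8000), 5), paste0("r", 1:5))
  cfg <- extender_config(min_mapped_part = 2000, edge_size = 5000,
                         min_support = 3, circular_min_overlap = 500)
  step <- extend_iteration(contig, reads, cfg)
  expect_identical(step$outcome$status, "extended")
  expect_equal(step$outcome$support, 5L)
  expect_identical(step$contig$sequence, substr(truth, 1, 8000))
})

test_that("assembly of an error-free circle round-trips to the exact truth", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 12)
  ct <- assemble(fx$reads$reads[1], fx$reads$reads, fx$config)
  expect_identical(ct$status, "circularized")
  expect_true(ct$circular)
  expect_equal(nchar(ct$sequence), 12000)
  expect_true(same_circle(fx$genome$chromosomes[[1]], ct$sequence))
  # contig length never decreases across extended iterations
  lens <- vapply(ct$history, function(h) h$contig_length, 0)
  st <- vapply(ct$history, function(h) h$status, "")
  expect_true(all(diff(lens[st == "extended"]) >= 0))
})

test_that("assembly is deterministic", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 12)
  a <- assemble(fx$reads$reads[1], fx$reads$reads, fx$config)
  b <- assemble(fx$reads$reads[1], fx$reads$reads, fx$config)
  expect_identical(a$sequence, b$sequence)
  expect_identical(assembly_log(a), assembly_log(b))
})

test_that("the iteration cap stops a run and is recorded", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 12)
  cfg <- fx$config
  cfg$max_iterations <- 2L
  ct <- assemble(fx$reads$reads[1], fx$reads$reads, cfg)
  expect_identical(ct$status, "max_iterations")
  expect_length(ct$history, 2L)
})

test_that("contigs serialize with a circular flag in the FASTA header", {
  ct <- new_contig(random_dna(100, seed = 71), id = "tig")
  ct$circular <- TRUE
  p <- withr::local_tempfile(fileext = ".fasta")
  write_contig(ct, p)
  expect_match(readLines(p, n = 1), "circular=true")
})
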