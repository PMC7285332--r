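# Constructed reads against a known edge exercise the acceptance rules
# at their exact thresholds.

make_edge_fixture <- function(seed = 101) {
  contig <- random_dna(20000, seed = seed)
  cfg <- extender_config()  # 99% / 8000 / 15000
  list(contig = contig, edge = extract_edge(contig, cfg$edge_size),
       config = cfg, novel = random_dna(2000, seed = seed + 1))
}

test_that("edge extraction clamps to the contig", {
  contig <- random_dna(40000, seed = 1)
  e <- extract_edge(contig, 15000)
  expect_identical(e, substr(contig, 25001, 40000))
  short <- random_dna(8000, seed = 2)
  expect_identical(extract_edge(short, 15000), short)
  expect_identical(extract_edge(short, 8000), short)
})

test_that("an exactly-anchored read is accepted with the right overhang", {
  fx <- make_edge_fixture()
  read <- paste0(substr(fx$edge, 7001, 15000), fx$novel)
  res <- align_read_to_edge(read, fx$edge, fx$config)
  expect_true(res$accepted)
  expect_equal(res$identity, 100)
  expect_equal(res$mapped_length, 8000)
  expect_identical(res$overhang, fx$novel)
  expect_identical(res$orientation, "forward")
})

test_that("mapped parts of 7999 vs 8000 bp sit exactly on the length threshold", {
  fx <- make_edge_fixture()
  ok <- align_read_to_edge(paste0(substr(fx$edge, 7001, 15000), fx$novel),
                           fx$edge, fx$config)
  expect_true(ok$accepted)
  bad <- align_read_to_edge(paste0(substr(fx$edge, 7002, 15000), fx$novel),
                            fx$edge, fx$config)
  expect_false(bad$accepted)
  expect_identical(bad$reason, "short_mapped_part")
})

test_that("identities of 98.9% vs 99.0% sit exactly on the identity threshold", {
  fx <- make_edge_fixture()
  anchor <- substr(fx$edge, 7001, 15000)
  # 80 substitutions over 8000 columns: identity exactly 99.00 -> accepted
  ok <- align_read_to_edge(
    paste0(substitute_bases(anchor, 80, seed = 7), fx$novel),
    fx$edge, fx$config)
  expect_true(ok$accepted)
  expect_equal(ok$identity, 99, tolerance = 1e-9)
  # 88 substitutions: identity exactly 98.90 -> rejected
  bad <- align_read_to_edge(
    paste0(substitute_bases(anchor, 88, seed = 8), fx$novel),
    fx$edge, fx$config)
  expect_false(bad$accepted)
  expect_identical(bad$reason, "low_identity")
})

test_that("reads are found on either strand with identical overhangs", {
  fx <- make_edge_fixture()
  read <- paste0(substr(fx$edge, 7001, 15000), fx$novel)
  fwd <- align_read_to_edge(read, fx$edge, fx$config)
  rev <- align_read_to_edge(rc_oracle(read), fx$edge, fx$config)
  expect_true(rev$accepted)
  expect_identical(rev$orientation, "reverse")
  expect_identical(rev$overhang, fwd$overhang)
  expect_equal(rev$identity, fwd$identity)
})

test_that("contained and non-overhanging reads are rejected with their reason", {
  fx <- make_edge_fixture()
  internal <- substr(fx$edge, 1001, 11000)
  res <- align_read_to_edge(internal, fx$edge, fx$config)
  expect_false(res$accepted)
  expect_identical(res$reason, "internal_only")
  flush <- substr(fx$edge, 7001, 15000)  # ends exactly at the terminus
  res2 <- align_read_to_edge(flush, fx$edge, fx$config)
  expect_false(res2$accepted)
  expect_identical(res2$reason, "no_overhang")
})

test_that("overhang collection matches simulator truth on error-free reads", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 12)
  truth <- fx$genome$chromosomes[[1]]
  prefix_len <- 6000
  contig <- substr(truth, 1, prefix_len)
  ov <- collect_overhangs(fx$reads$reads, contig, fx$config)
  # expected: reads anchored >= min_mapped_part before the contig end and
  # extending past it (computed from true origin coordinates)
  o <- fx$reads$origins
  ends <- o$start + o$fragment_length
  expected <- o$read_id[o$start <= prefix_len - fx$config$min_mapped_part &
                          ends > prefix_len]
  expect_setequal(ov$read_id, expected)
  # sorted by descending overhang length
  expect_true(all(diff(nchar(ov$overhang)) <= 0))
  # every error-free overhang is an exact substring of the circular truth
  doubled <- paste0(truth, truth)
  for (s in ov$overhang) expect_true(grepl(s, doubled, fixed = TRUE))
})

test_that("relaxing either threshold never shrinks the accepted set", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 13,
                             error_rate = c(0.005, 0, 0))
  contig <- substr(fx$genome$chromosomes[[1]], 1, 6000)
  strict <- collect_overhangs(fx$reads$reads, contig, fx$config)
  lax_id <- collect_overhangs(
    fx$reads$reads, contig,
    extender_config(min_read_similarity = 97, min_mapped_part = 2000,
                    edge_size = 5000, circular_min_overlap = 500))
  lax_len <- collect_overhangs(
    fx$reads$reads, contig,
    extender_config(min_read_similarity = 99, min_mapped_part = 1500,
                    edge_size = 5000, circular_min_overlap = 500))
  expect_true(all(strict$read_id %in% lax_id$read_id))
  expect_true(all(strict$read_id %in% lax_len$read_id))
})

test_that("reverse-complementing all reads flips orientations only", {
  fx <- small_circle_fixture(genome_seed = 11, read_seed = 12)
  contig <- substr(fx$genome$chromosomes[[1]], 1, 6000)
  fwd <- collect_overhangs(fx$reads$reads, contig, fx$config)
  flipped <- setNames(vapply(fx$reads$reads, rc_oracle, ""),
                      names(fx$reads$reads))
  rev <- collect_overhangs(flipped, contig, fx$config)
  expect_setequal(fwd$read_id, rev$read_id)
  m <- merge(fwd, rev, by = "read_id")
  expect_identical(m$overhang.x, m$overhang.y)
  expect_true(all(m$orientation.x != m$orientation.y))
})
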