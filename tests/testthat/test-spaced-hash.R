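# Spaced pattern design, worst-case mismatch guarantees, probe extraction,
# and read screening.

test_that("pattern design satisfies all structural invariants", {
  p <- build_patterns()
  expect_length(p, 6L)
  expect_true(all(lengths(p) == 16L))
  expect_true(all(unlist(p) >= 0 & unlist(p) < 32))
  # every position in exactly 3 patterns (each block sits in 3 of the 6 pairs)
  cov <- table(factor(unlist(p), levels = 0:31))
  expect_true(all(cov == 3L))
  # pair exclusion: for every pair of positions some pattern avoids both
  pairs <- utils::combn(0:31, 2L)
  excluded <- vapply(seq_len(ncol(pairs)), function(j) {
    any(vapply(p, function(pat) !any(pairs[, j] %in% pat), logical(1)))
  }, logical(1))
  expect_equal(sum(excluded), 496L)
})

test_that("worst-case enumeration matches position-level brute force at small m", {
  # block-occupancy enumeration is a shortcut; prove equivalence by exhaustion
  for (m in 0:2) {
    brute <- if (m == 0L) hits_for_mismatch_positions(integer(0)) else {
      placements <- utils::combn(96L, m)
      min(apply(placements, 2L, function(pp) hits_for_mismatch_positions(pp - 1L)))
    }
    expect_identical(worst_case_min_hits(m), as.integer(brute), label = paste("m =", m))
  }
})

test_that("guarantee ladder: thresholds 3 and 10 are defeated at exactly 7 and 3", {
  hits <- vapply(0:8, worst_case_min_hits, integer(1))
  expect_true(all(diff(hits) <= 0))           # non-increasing in m
  expect_gte(hits[6 + 1], 3L)                 # m = 6 still passes k = 3
  expect_lt(hits[7 + 1], 3L)                  # m = 7 can defeat k = 3
  expect_gte(hits[2 + 1], 10L)                # m = 2 still passes k = 10
  expect_lt(hits[3 + 1], 10L)                 # m = 3 can defeat k = 10
  expect_identical(min_mismatches_to_defeat(3L), 7L)
  expect_identical(min_mismatches_to_defeat(10L), 3L)
})

test_that("any 32-mer with <= 2 mismatches keeps at least one intact table", {
  expect_gte(min_tables_single_window(2L), 1L)
  # and with 3 spread mismatches all tables can die
  expect_identical(worst_case_min_hits(3L, n_windows = 1L), 0L)
})

test_that("probe extraction: 18 probes from the first 96 bases, N gives null keys", {
  for (len in c(96L, 100L, 150L)) {
    pk <- extract_probe_keys(rand_dna(len, seed = len))
    expect_identical(nrow(pk), 18L)
    expect_true(all(table(pk$window) == 6L))
    expect_true(all(!is.na(pk$key)))
  }
  # N at position 0 nulls exactly the 3 window-0 probes whose pattern holds position 0
  s <- rand_dna(96L, seed = 5)
  substr(s, 1L, 1L) <- "N"
  pk <- extract_probe_keys(s)
  expect_identical(sum(is.na(pk$key)), 3L)
  expect_true(all(pk$window[is.na(pk$key)] == 0L))
  # short reads: 1 or 2 windows; under 32 bp unscreenable
  expect_identical(nrow(extract_probe_keys(rand_dna(64L, seed = 1))), 12L)
  expect_identical(nrow(extract_probe_keys(rand_dna(40L, seed = 1))), 6L)
  expect_identical(nrow(extract_probe_keys(rand_dna(31L, seed = 1))), 0L)
})

test_that("index covers every window once per pattern and handles degenerate contigs", {
  w <- small_world()
  idx <- w$idx
  expected_windows <- sum(pmax(w$ref$contigs$len - 31L, 0L))
  for (p in 1:6) expect_identical(length(idx$tables[[p]]$key), expected_windows)
  # degenerate poly-A contig: all keys identical, lookups still well-defined
  ref1 <- w$ref
  ref1$contigs <- data.table::data.table(
    name = "polyA", chrom = "chr1", pos = 100L, ref = "A", alt = "C", af = 0.5,
    w = 50L, flank_class = "short", genome_offset = 49L, len = 101L,
    callable_start = 49L, callable_end = 52L, seq = strrep("A", 101L))
  idx1 <- index_reference(ref1)
  expect_identical(length(unique(idx1$tables[[1L]]$key)), 1L)
  sc <- screen_reads(strrep("A", 100L), idx1)
  expect_identical(sc$hit_count, 18L)
  expect_true(sc$passed)
  # empty reference errors
  ref0 <- ref1; ref0$contigs <- ref1$contigs[0L]
  expect_error(index_reference(ref0), "empty")
})

test_that("screening: exact reads pass with 18 hits, orientation-symmetric, random reads fail", {
  w <- small_world()
  contig <- w$ref$contigs$seq[3L]
  read <- substr(contig, 51L, 200L)
  sc <- screen_reads(c(read, revcomp(read)), w$idx)
  expect_identical(sc$hit_count, c(18L, 18L))
  expect_true(all(sc$passed))
  expect_identical(unlist(sc[1L, .(w1, w2, w3)]), c(w1 = 6L, w2 = 6L, w3 = 6L))
  # random reads against this index: fail at k_min = 3 (chance hit rate ~ L/4^16)
  rnd <- vapply(1:200, function(i) rand_dna(150L, seed = 1000L + i), character(1))
  scr <- screen_reads(rnd, w$idx, k_min = 3L)
  expect_true(mean(!scr$passed) > 0.99)
})

test_that("two mismatches within one 32-mer keep >= 13 hits and always pass at k = 3", {
  w <- small_world()
  contig <- w$ref$contigs$seq[1L]
  read <- substr(contig, 101L, 196L)   # 96-mer
  # both mismatches inside window 2 (positions 33..64)
  mutated <- mutate_at(read, c(40L, 55L))
  sc <- screen_reads(mutated, w$idx)
  expect_gte(sc$hit_count, 13L)
  expect_gte(sc$w2, 1L)
  expect_true(sc$passed)
})

test_that("raising k_min never admits more reads; short reads scale the threshold", {
  w <- small_world()
  withr::with_seed(42, {
    reads <- vapply(1:50, function(i) {
      contig <- w$ref$contigs$seq[sample.int(nrow(w$ref$contigs), 1L)]
      start <- sample.int(nchar(contig) - 150L, 1L)
      mutate_at(substr(contig, start, start + 149L),
                sample.int(150L, sample(0:12, 1L)))
    }, character(1))
  })
  prev <- rep(TRUE, length(reads))
  for (k in c(1L, 3L, 7L, 10L, 18L)) {
    cur <- screen_reads(reads, w$idx, k_min = k)$passed
    expect_true(all(cur <= prev), label = paste("k =", k))
    prev <- cur
  }
  # 64-bp read: 2 windows, threshold ceiling(3 * 2/3) = 2
  contig <- w$ref$contigs$seq[2L]
  r64 <- substr(contig, 11L, 74L)
  sc <- screen_reads(r64, w$idx, k_min = 3L)
  expect_identical(sc$n_windows, 2L)
  expect_identical(sc$hit_count, 12L)
  expect_true(sc$passed)
  # under 32 bp: unscreenable, counted as filtered
  sc2 <- screen_reads(substr(contig, 1L, 20L), w$idx)
  expect_true(is.na(sc2$hit_count))
  expect_false(sc2$passed)
})

test_that("hash index round-trips through its sidecar file", {
  w <- small_world()
  tf <- tempfile(fileext = ".shx")
  write_hash_index(w$idx, tf)
  idx2 <- read_hash_index(tf)
  expect_identical(idx2$tables, w$idx$tables)
  expect_identical(idx2$patterns, w$idx$patterns)
  writeBin(as.raw(1:10), tf)
  expect_error(read_hash_index(tf))
})
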