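# Mini-aligner: seeding, verification, banded fallback, pairing, SAM output.

test_that("verbatim and mutated reads map back to their true locus", {
  w <- small_world()
  contig7 <- w$ref$contigs$seq[7L]
  read <- substr(contig7, 101L, 250L)
  a <- align_read(read, w$idx, w$ref)
  expect_true(a$mapped)
  expect_identical(a$contig, 7L)
  expect_identical(a$start, 100L)
  expect_identical(a$strand, "+")
  expect_identical(a$nm, 0L)
  expect_identical(a$mapq, 60L)
  expect_identical(a$cigar, "150M")
  # 3 substitutions: same locus, nm = 3
  a3 <- align_read(mutate_at(read, c(10L, 75L, 140L)), w$idx, w$ref)
  expect_identical(a3$contig, 7L)
  expect_identical(a3$start, 100L)
  expect_identical(a3$nm, 3L)
  # reverse-complement read maps at the same locus on the minus strand,
  # stored in reference orientation
  arc <- align_read(revcomp(read), w$idx, w$ref)
  expect_identical(arc$start, 100L)
  expect_identical(arc$strand, "-")
  expect_identical(arc$seq, read)
  # random reads stay unmapped
  rnd <- align_reads(vapply(1:20, function(i) rand_dna(150L, seed = 300L + i),
                            character(1)), w$idx, w$ref)
  expect_true(all(!rnd$mapped))
})

test_that("stored nm always equals the mismatch count recomputed from sequences", {
  w <- small_world()
  withr::with_seed(17, {
    reads <- vapply(1:60, function(i) {
      ci <- sample.int(nrow(w$ref$contigs), 1L)
      contig <- w$ref$contigs$seq[ci]
      start <- sample.int(nchar(contig) - 150L, 1L)
      r <- mutate_at(substr(contig, start, start + 149L),
                     sample.int(150L, sample(0:5, 1L)))
      if (runif(1) < 0.5) revcomp(r) else r
    }, character(1))
  })
  a <- align_reads(reads, w$idx, w$ref)
  expect_true(all(a$mapped))
  for (i in seq_len(nrow(a))) {
    if (a$cigar[i] != "150M") next
    refseq <- substr(w$ref$contigs$seq[a$contig[i]], a$start[i] + 1L, a$end[i])
    nm <- sum(utf8ToInt(refseq) != utf8ToInt(a$seq[i]))
    expect_identical(a$nm[i], as.integer(nm))
  }
  # determinism
  a2 <- align_reads(reads, w$idx, w$ref)
  expect_identical(a, a2)
})

test_that("simulated reads are recovered at their true locus >= 99% of the time", {
  w <- small_world()
  cfg <- w$cfg
  co <- w$ref$contigs
  contigs <- setNames(co$seq, co$name)
  sim <- simulate_reads(contigs, NULL, cfg, n_pairs = 1000L, seed = 31L)
  a1 <- align_reads(sim$reads$seq1, w$idx, w$ref, qname = sim$reads$qname)
  truth_contig <- match(sim$truth$seq_name, co$name)
  ok <- a1$mapped & a1$contig == truth_contig & a1$start == sim$truth$frag_start
  expect_gte(mean(ok), 0.99)
})

test_that("banded fallback aligns reads containing a small indel", {
  w <- small_world()
  contig <- w$ref$contigs$seq[4L]
  base <- substr(contig, 51L, 203L)           # 153 bases
  with_del <- paste0(substr(base, 1L, 100L), substr(base, 104L, 153L))  # 3-base deletion
  a <- align_read(with_del, w$idx, w$ref, max_mismatch = 5L, max_gap = 3L)
  expect_true(a$mapped)
  expect_identical(a$contig, 4L)
  expect_identical(a$nm, 3L)
  expect_match(a$cigar, "D")
  base152 <- substr(contig, 51L, 202L)        # 152 bases
  with_ins <- paste0(substr(base152, 1L, 80L), "GG", substr(base152, 81L, 148L))
  ai <- align_read(with_ins, w$idx, w$ref, max_mismatch = 5L, max_gap = 3L)
  expect_true(ai$mapped)
  expect_match(ai$cigar, "I")
  # with max_gap = 0 the same read is unalignable (a value, not an error)
  a0 <- align_read(with_del, w$idx, w$ref, max_mismatch = 5L, max_gap = 0L)
  expect_false(a0$mapped)
})

test_that("pairing derives proper flags, observed insert, and rejects name mismatches", {
  w <- small_world()
  co <- w$ref$contigs
  mk <- function(qname, mate, contig, start, len, strand, mapped = TRUE, mapq = 60L) {
    data.table::data.table(qname = qname, mate = mate, mapped = mapped,
                           contig = if (mapped) contig else NA_integer_,
                           start = if (mapped) start else NA_integer_,
                           end = if (mapped) start + len else NA_integer_,
                           strand = if (mapped) strand else NA_character_,
                           nm = 0L, mapq = if (mapped) mapq else NA_integer_,
                           cigar = if (mapped) paste0(len, "M") else NA_character_,
                           seq = strrep("A", len), qual = strrep("I", len))
  }
  aln <- rbind(
    mk("p1", 1L, 1L, 100L, 150L, "+"), mk("p1", 2L, 1L, 300L, 150L, "-"),
    mk("p2", 1L, 1L, 100L, 150L, "+"), mk("p2", 2L, 2L, 300L, 150L, "-"),
    mk("p3", 1L, 1L, 100L, 150L, "+"), mk("p3", 2L, 1L, 300L, 150L, "+"),
    mk("p4", 1L, 1L, 100L, 150L, "+"), mk("p4", 2L, 1L, 300L, 150L, "-", mapq = 5L),
    mk("p5", 1L, 2L, 100L, 150L, "+"), mk("p5", 2L, 2L, 0L, 0L, "+", mapped = FALSE))
  p <- pair_and_flag(aln)
  data.table::setkey(p, qname)
  expect_true(p["p1", proper])
  expect_identical(p["p1", t_o], 450L - 100L)
  expect_false(p["p2", proper])   # different contigs
  expect_false(p["p3", proper])   # same strand
  expect_false(p["p4", proper])   # low mapq
  expect_false(p["p5", proper])   # mate unmapped (censored case downstream)
  expect_error(pair_and_flag(aln[qname != "p5" | mate != 2L]), "names")
})

test_that("SAM output is valid, flag-consistent, and parseable by Rsamtools", {
  w <- small_world()
  co <- w$ref$contigs
  contigs <- setNames(co$seq, co$name)
  sim <- simulate_reads(contigs, NULL, w$cfg, n_pairs = 150L, seed = 77L)
  a1 <- align_reads(sim$reads$seq1, w$idx, w$ref, qname = sim$reads$qname,
                    qual = sim$reads$qual1, mate = 1L)
  a2 <- align_reads(sim$reads$seq2, w$idx, w$ref, qname = sim$reads$qname,
                    qual = sim$reads$qual2, mate = 2L)
  aln <- rbind(a1, a2)
  pairs <- mark_duplicates(pair_and_flag(aln))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, w$ref, sam, pairs = pairs)
  lines <- readLines(sam)
  expect_identical(sum(startsWith(lines, "@SQ")), nrow(co))
  expect_identical(sum(!startsWith(lines, "@")), nrow(aln))
  # proper pair: 0x1|0x2|0x20|0x40 for a forward first mate
  pq <- pairs$qname[pairs$proper][1L]
  fl <- as.integer(sub("^[^\t]+\t([0-9]+)\t.*", "\\1",
                       grep(paste0("^", pq, "\t"), lines, value = TRUE)))
  expect_identical(sort(bitwAnd(fl, 0xC0L)), c(64L, 128L))
  expect_true(all(bitwAnd(fl, 0x2L) == 2L))
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)  # htslib validation
  sb <- Rsamtools::scanBam(bam)[[1L]]
  expect_identical(length(sb$qname), nrow(aln))
  mapped_ours <- sum(aln$mapped)
  expect_identical(sum(!bitwAnd(sb$flag, 4L)), mapped_ours)
  # header-only SAM for zero records
  sam0 <- tempfile(fileext = ".sam")
  write_sam(a1[0L], w$ref, sam0)
  expect_true(all(startsWith(readLines(sam0), "@")))
  # unmapped mate conventions
  un <- aln[mapped == FALSE]
  if (nrow(un)) {
    l <- grep(paste0("^", un$qname[1L], "\t"), lines, value = TRUE)
    f <- data.table::tstrsplit(l, "\t")
    i <- which(bitwAnd(as.integer(f[[2]]), 4L) > 0L)
    expect_identical(f[[3]][i], "*")
  }
})
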