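# Base- and read-level QC: empirical quality, depth, GC bias, duplicates,
# mapping summary.

# small aligned dataset reused across blocks: reads simulated from the
# reduced-reference contigs themselves (plus genome pads for uniform depth)
qc_fixture <- function(base_q = 30L, error_rate = NULL, dup_rate = 0,
                       depth = 8, seed = 50L) {
  w <- small_world()
  cfg <- sim_config(genome_len = w$cfg$genome_len, n_markers = w$cfg$n_markers,
                    depth = depth, base_q = base_q, error_rate = error_rate,
                    dup_rate = dup_rate, seed = seed)
  sim <- simulate_reads(w$sim$genome, NULL, cfg, seed = seed)
  sc1 <- screen_reads(sim$reads$seq1, w$idx)
  sc2 <- screen_reads(sim$reads$seq2, w$idx)
  keep <- sc1$passed | sc2$passed
  kept <- sim$reads[keep]
  a1 <- align_reads(kept$seq1, w$idx, w$ref, qname = kept$qname, qual = kept$qual1, mate = 1L)
  a2 <- align_reads(kept$seq2, w$idx, w$ref, qname = kept$qname, qual = kept$qual2, mate = 2L)
  aln <- rbind(a1, a2)
  pairs <- mark_duplicates(pair_and_flag(aln))
  list(w = w, aln = aln, pairs = pairs, screen = screen_summary(rbind(sc1, sc2)),
       cfg = cfg, truth = sim$truth)
}

test_that("error-free reads produce zero mismatches and capped empirical quality", {
  fx <- qc_fixture(error_rate = 0, depth = 3, seed = 51L)
  tab <- accumulate_base_stats(fx$aln, fx$w$ref)
  eq <- empirical_quality(tab)
  used <- eq[n_total > 0]
  expect_true(all(used$n_mismatch == 0))
  # zero mismatches: the +1/+2 pseudocount gives 10 log10(n + 2), capped at 60
  expect_equal(used$empirical_q, pmin(10 * log10(used$n_total + 2), 60))
  # depth conservation: sum(depth) = aligned callable bases
  expect_identical(sum(tab$depth), as.integer(tab$total_aligned_callable_bases))
})

test_that("planted 1% error at reported Q20 recovers empirical quality 20 +/- 1", {
  fx <- qc_fixture(base_q = 20L, depth = 10, seed = 52L)   # error = 10^-2
  tab <- accumulate_base_stats(fx$aln, fx$w$ref)
  eq <- empirical_quality(tab)
  q20 <- eq[q == 20L]
  expect_gt(q20$n_total, 1e5)   # enough bases for a tight CI
  expect_lt(abs(q20$empirical_q - 20), 1)
})

test_that("marker column is excluded from mismatch tallies", {
  # heterozygous alt bases at the center column must not count as errors
  w <- small_world()
  co <- w$ref$contigs[1L]
  alt_read <- co$seq
  substr(alt_read, co$w + 1L, co$w + 1L) <- co$alt
  read <- substr(alt_read, co$w - 70L, co$w + 79L)   # covers the marker column
  a <- align_reads(read, w$idx, w$ref)
  expect_identical(a$nm, 1L)
  tab <- accumulate_base_stats(a, w$ref)
  expect_identical(sum(tab$qual_counts$n_mismatch), 0)
})

test_that("single fully-callable read contributes exactly its length in depth", {
  w <- small_world()
  co <- w$ref$contigs[1L]
  read <- substr(co$seq, co$callable_start + 1L, co$callable_start + 150L)
  a <- align_reads(read, w$idx, w$ref)
  tab <- accumulate_base_stats(a, w$ref)
  expect_identical(sum(tab$depth), 150L)
  dd <- depth_distribution(tab)
  expect_identical(sum(dd$histogram[depth > 0, n_positions]), 150L)
  # no aligned reads: all mass at depth zero
  tab0 <- accumulate_base_stats(a[0L], w$ref)
  dd0 <- depth_distribution(tab0)
  expect_identical(dd0$mean, 0)
  expect_identical(dd0$histogram$depth, 0L)
})

test_that("mean callable depth matches the planted sequencing depth", {
  fx <- qc_fixture(depth = 8, seed = 53L)
  tab <- accumulate_base_stats(fx$aln, fx$w$ref)
  dd <- depth_distribution(tab)
  # contig-level SE of the mean callable depth
  cs <- tab$contig_stats
  se <- stats::sd(cs$mean_callable_depth) / sqrt(nrow(cs))
  expect_lt(abs(dd$mean - 8), 3 * se + 0.2)
})

test_that("GC bias is flat under unbiased simulation; empty bins are missing", {
  fx <- qc_fixture(depth = 8, seed = 54L)
  tab <- accumulate_base_stats(fx$aln, fx$w$ref)
  g <- gc_bias(tab)
  conf <- g[n_contigs >= 5L]
  expect_gt(nrow(conf), 0L)
  expect_true(all(abs(conf$normalized_depth - 1) < 0.1))
  expect_true(all(is.na(g[n_contigs == 0L, normalized_depth])))
  expect_true(all(g[n_contigs > 0L & n_contigs < 5L, low_confidence]))
  # planted GC trend is recovered: double the depth of high-GC contigs
  aln2 <- data.table::copy(fx$aln)
  cs <- tab$contig_stats
  hi_gc <- cs$contig[cs$gc > stats::median(cs$gc)]
  extra <- aln2[mapped == TRUE & contig %in% hi_gc]
  extra[, qname := paste0(qname, "_x")]
  tab2 <- accumulate_base_stats(rbind(aln2, extra), fx$w$ref)
  g2 <- gc_bias(tab2)
  conf2 <- g2[n_contigs >= 5L]
  expect_gt(stats::cor(conf2$normalized_depth, (conf2$gc_lo + conf2$gc_hi) / 2), 0.5)
})

test_that("duplicate marking and rate follow the group-size definition", {
  mkp <- function(qname, contig, sl, er, proper = TRUE) {
    data.table::data.table(qname = qname, contig = contig, start_l = sl, end_r = er,
                           strand1 = "+", strand2 = "-", proper = proper,
                           t_o = er - sl, mapped1 = TRUE, mapped2 = TRUE,
                           mapq1 = 60L, mapq2 = 60L)
  }
  # all distinct loci -> 0
  p <- rbind(mkp("a", 1L, 0L, 300L), mkp("b", 1L, 5L, 300L), mkp("c", 2L, 0L, 300L))
  expect_identical(duplicate_rate(p), 0)
  # 3 identical among 10 -> 2/10
  p10 <- data.table::rbindlist(c(
    lapply(1:3, function(i) mkp(paste0("d", i), 1L, 50L, 400L)),
    lapply(1:7, function(i) mkp(paste0("u", i), 1L, 50L + i * 10L, 400L + i))))
  expect_identical(duplicate_rate(p10), 0.2)
  expect_identical(sum(mark_duplicates(data.table::copy(p10))$dup), 2L)
  # improper pairs never counted
  expect_true(is.na(duplicate_rate(mkp("z", 1L, 0L, 300L, proper = FALSE))))
})

test_that("planted duplicate rate is recovered by the estimator", {
  fx <- qc_fixture(dup_rate = 0.1, depth = 10, seed = 55L)
  r <- duplicate_rate(fx$pairs)
  expect_lt(abs(r - 0.1), 0.03)
})

test_that("mapping summary reports explicit fractions and handles empty input", {
  fx <- qc_fixture(depth = 3, seed = 56L)
  ms <- mapping_summary(fx$screen, fx$aln, pairs = fx$pairs)
  # footprint of the reduced reference in this world is ~ 20% of the genome
  footprint <- sum(fx$w$ref$contigs$len) / fx$w$cfg$genome_len
  expect_lt(abs(ms$screen_pass_fraction - footprint), 0.05)
  expect_true(ms$mapped_fraction_of_screened > 0.3 &&
                ms$mapped_fraction_of_screened <= 1)
  expect_identical(ms$mapped_fraction_of_screened, ms$mapped_fraction_wgs_proxy)
  expect_match(ms$wgs_proxy_caveat, "whole-genome")
  # empty input: zero counts, missing fractions
  empty_screen <- screen_summary(screen_reads(character(0), fx$w$idx))
  ms0 <- mapping_summary(empty_screen, fx$aln[0L])
  expect_identical(ms0$total_reads, 0L)
  expect_true(is.na(ms0$screen_pass_fraction))
  expect_true(is.na(ms0$mapped_fraction_of_screened))
})
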