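# Base-level and read-level QC: quality by cycle, empirical vs reported base
# quality, depth over callable positions, GC bias, duplicate rate, mapping
# summary.
#
# Mismatch- and depth-based tallies are restricted to the callable interval
# of each contig (the central 2(w-r)+1 bases where reads align fully),
# excluding the marker column itself so heterozygous alternate alleles do
# not inflate the apparent sequencing error rate.

#' Accumulate base-level QC tables from alignments
#'
#' Streams mapped, gapless alignments in chunks and tallies, over callable
#' non-variant positions: reported-quality x match/mismatch counts and
#' per-position depth; per-cycle mean reported quality is computed over all
#' reads (mapped or not) in original machine orientation.
#'
#' @param aln alignment data.table from [align_reads()] (both mates).
#' @param ref `ReducedReference`.
#' @param exclude optional logical vector (length `nrow(aln)`): alignments to
#'   drop from callable tallies (e.g. PCR duplicates).
#' @param chunk_size alignments per accumulation chunk.
#' @return a `BaseQcTables`: list with `cycle_quality` (data.table `cycle`,
#'   `mean_q`, `n`), `qual_counts` (`q`, `n_total`, `n_mismatch`),
#'   `depth` (integer vector over all callable positions, contig-major),
#'   `contig_stats` (`contig`, `gc`, `callable_len`, `mean_callable_depth`),
#'   `n_gapped_skipped`, `total_aligned_callable_bases`.
#' @export
accumulate_base_stats <- function(aln, ref, exclude = NULL, chunk_size = 20000L) {
  a <- data.table::as.data.table(aln)
  co <- ref$contigs
  goff <- c(0L, cumsum(co$len))[seq_len(nrow(co))]
  refcodes <- unlist(lapply(co$seq, seq_codes), use.names = FALSE)
  # callable bookkeeping: map (contig, pos-in-contig) -> callable index
  call_len <- pmax(co$callable_end - co$callable_start, 0L)
  ccum <- c(0L, cumsum(call_len))[seq_len(nrow(co))]
  total_callable <- sum(call_len)
  center <- co$w  # 0-based center column per contig
  # per-cycle reported quality over ALL reads (machine orientation)
  max_cycle <- max(nchar(a$seq), 1L)
  cyc_sum <- numeric(max_cycle); cyc_n <- numeric(max_cycle)
  for (L in unique(nchar(a$qual))) {
    rows <- which(nchar(a$qual) == L)
    qm <- matrix(utf8ToInt(paste(a$qual[rows], collapse = "")) - 33L, nrow = L)
    # mapped reverse-strand reads are stored ref-oriented; flip back to cycles
    rev_rows <- a$mapped[rows] %in% TRUE & a$strand[rows] %in% "-"
    if (any(rev_rows)) qm[, rev_rows] <- qm[rev(seq_len(L)), rev_rows, drop = FALSE]
    cyc_sum[seq_len(L)] <- cyc_sum[seq_len(L)] + rowSums(qm)
    cyc_n[seq_len(L)] <- cyc_n[seq_len(L)] + ncol(qm)
  }
  cycle_quality <- data.table::data.table(cycle = seq_len(max_cycle),
                                          mean_q = ifelse(cyc_n > 0, cyc_sum / cyc_n, NA_real_),
                                          n = as.integer(cyc_n))
  # callable tallies over mapped, gapless alignments
  keep <- a$mapped %in% TRUE & grepl("^[0-9]+M$", a$cigar)
  n_gapped <- sum(a$mapped %in% TRUE) - sum(keep)
  if (!is.null(exclude)) keep <- keep & !exclude
  idx_keep <- which(keep)
  qmax <- 61L
  qual_tot <- numeric(qmax); qual_mis <- numeric(qmax)
  depth <- integer(total_callable)
  total_bases <- 0
  for (ch in split(idx_keep, ceiling(seq_along(idx_keep) / chunk_size))) {
    lens <- a$end[ch] - a$start[ch]
    contig <- rep(a$contig[ch], lens)
    in_read <- sequence(lens)                     # 1..len per alignment
    pos <- rep(a$start[ch], lens) + in_read - 1L  # 0-based pos in contig
    gpos <- goff[contig] + pos
    rcode <- .dna_code_table[utf8ToInt(paste(a$seq[ch], collapse = ""))]
    qv <- utf8ToInt(paste(a$qual[ch], collapse = "")) - 33L
    callable <- pos >= co$callable_start[contig] & pos < co$callable_end[contig]
    is_center <- pos == center[contig]
    # depth over callable positions (marker column included)
    cidx <- ccum[contig[callable]] + (pos[callable] - co$callable_start[contig[callable]]) + 1L
    tb <- tabulate(cidx, nbins = total_callable)
    depth <- depth + tb
    total_bases <- total_bases + sum(callable)
    # match/mismatch by reported quality, marker column excluded
    sel <- callable & !is_center
    mism <- refcodes[gpos[sel] + 1L] != rcode[sel]
    mism[is.na(mism)] <- TRUE
    qb <- clamp(qv[sel], 0L, qmax - 1L) + 1L
    qual_tot <- qual_tot + tabulate(qb, nbins = qmax)
    qual_mis <- qual_mis + tabulate(qb[mism], nbins = qmax)
  }
  qual_counts <- data.table::data.table(q = 0:(qmax - 1L),
                                        n_total = as.numeric(qual_tot),
                                        n_mismatch = as.numeric(qual_mis))
  # per-contig GC (whole contig) and mean callable depth
  gc <- vapply(co$seq, function(s) {
    cd <- seq_codes(s); mean(cd == 1L | cd == 2L, na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
  mean_depth <- vapply(seq_len(nrow(co)), function(ci) {
    if (call_len[ci] == 0L) return(NA_real_)
    mean(depth[(ccum[ci] + 1L):(ccum[ci] + call_len[ci])])
  }, numeric(1))
  contig_stats <- data.table::data.table(contig = seq_len(nrow(co)), gc = gc,
                                         callable_len = call_len,
                                         mean_callable_depth = mean_depth)
  structure(list(cycle_quality = cycle_quality, qual_counts = qual_counts,
                 depth = depth, contig_stats = contig_stats,
                 n_gapped_skipped = n_gapped,
                 total_aligned_callable_bases = total_bases),
            class = "BaseQcTables")
}

#' Empirical base quality per reported-quality bin
#'
#' `-10 log10` of the observed mismatch rate at callable non-variant
#' positions per reported quality, with a +1 mismatch / +2 total pseudocount
#' so bins with zero mismatches stay finite; capped at Q60.
#'
#' @param tables `BaseQcTables`.
#' @return data.table `q`, `n_total`, `n_mismatch`, `empirical_q` (NA for
#'   empty bins).
#' @export
empirical_quality <- function(tables) {
  qc <- data.table::copy(tables$qual_counts)
  qc[, empirical_q := ifelse(n_total > 0,
                             pmin(-10 * log10((n_mismatch + 1) / (n_total + 2)), 60),
                             NA_real_)]
  qc[]
}

#' Depth distribution over callable positions
#'
#' @param tables `BaseQcTables`.
#' @return list: `histogram` (data.table `depth`, `n_positions`), `mean`,
#'   `median`, `total_positions`.
#' @export
depth_distribution <- function(tables) {
  d <- tables$depth
  hist <- data.table::as.data.table(table(depth = d))
  hist[, depth := as.integer(as.character(depth))]
  data.table::setnames(hist, "N", "n_positions")
  list(histogram = hist[], mean = mean(d), median = median(d),
       total_positions = length(d))
}

#' GC bias curve
#'
#' Contigs are binned by whole-contig GC fraction; each bin's value is the
#' mean callable depth of its contigs divided by the overall mean callable
#' depth. Bins with fewer than 5 contigs are flagged low-confidence; empty
#' bins are reported as missing, not zero.
#'
#' @param tables `BaseQcTables`.
#' @param n_bins number of GC bins over `[0, 1]` (default 40, i.e. 2.5%).
#' @return data.table `gc_lo`, `gc_hi`, `n_contigs`, `normalized_depth`,
#'   `low_confidence`.
#' @export
gc_bias <- function(tables, n_bins = 40L) {
  cs <- tables$contig_stats[!is.na(mean_callable_depth)]
  overall <- mean(cs$mean_callable_depth)
  breaks <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(cs$gc, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.table::data.table(gc_lo = breaks[-length(breaks)], gc_hi = breaks[-1L])
  agg <- cs[, .(n_contigs = .N, mean_depth = mean(mean_callable_depth)),
            by = .(bin = bin)]
  out[, n_contigs := 0L]
  out$n_contigs[agg$bin] <- agg$n_contigs
  out[, normalized_depth := NA_real_]
  out$normalized_depth[agg$bin] <- if (overall > 0) agg$mean_depth / overall else NA_real_
  out[, low_confidence := n_contigs < 5L]
  out[]
}

#' Mark PCR duplicates among proper pairs
#'
#' Pairs are grouped by (contig, leftmost start, rightmost end, orientation);
#' within each group every pair after the first (in read-name order) is
#' flagged a duplicate. Improper/unmapped pairs are never flagged.
#'
#' @param pairs pairs table from [pair_and_flag()].
#' @return the pairs table with a logical `dup` column, by reference.
#' @export
mark_duplicates <- function(pairs) {
  p <- pairs
  p[, dup := FALSE]
  pr <- which(p$proper)
  if (length(pr)) {
    key <- paste(p$contig[pr], p$start_l[pr], p$end_r[pr],
                 paste0(p$strand1[pr], p$strand2[pr]), sep = "|")
    ord <- order(key, p$qname[pr])
    first <- !duplicated(key[ord])
    dup <- logical(length(pr)); dup[ord] <- !first
    p$dup[pr] <- dup
  }
  p[]
}

#' PCR duplicate rate
#'
#' Fraction of proper pairs that are duplicates: pairs sharing (contig,
#' leftmost start, rightmost end, orientation) count `group size - 1` each;
#' rate = duplicates / proper pairs.
#'
#' @param pairs pairs table from [pair_and_flag()].
#' @return numeric fraction (NA when there are no proper pairs).
#' @export
duplicate_rate <- function(pairs) {
  p <- mark_duplicates(data.table::copy(pairs))
  n_proper <- sum(p$proper)
  if (n_proper == 0L) return(NA_real_)
  sum(p$dup) / n_proper
}

#' Read-level mapping summary
#'
#' Three explicit numbers rather than a single extrapolation: the fraction
#' of all reads passing the screen, the fraction of screened reads mapped,
#' and a whole-genome mapped-fraction proxy (equal to the latter, with a
#' caveat flag — markers are drawn from uniquely alignable regions, so the
#' proxy is only recommended for whole-genome data). The estimated mean
#' depth over callable bases serves as the genome-wide depth proxy.
#'
#' @param screen_sum summary list from [screen_summary()].
#' @param aln alignment data.table of screened reads.
#' @param tables optional `BaseQcTables` (adds mean callable depth).
#' @param pairs optional pairs table (adds duplicate rate).
#' @return a `ReadQcSummary` list.
#' @export
mapping_summary <- function(screen_sum, aln, tables = NULL, pairs = NULL) {
  n_total <- screen_sum$total_reads
  n_pass <- screen_sum$passed
  n_mapped <- sum(aln$mapped %in% TRUE)
  lens <- table(nchar(aln$seq))
  structure(list(
    total_reads = n_total,
    screen_pass_fraction = if (n_total > 0) n_pass / n_total else NA_real_,
    mapped_fraction_of_screened = if (nrow(aln) > 0) n_mapped / nrow(aln) else NA_real_,
    mapped_fraction_wgs_proxy = if (nrow(aln) > 0) n_mapped / nrow(aln) else NA_real_,
    wgs_proxy_caveat = "proxy assumes whole-genome sequencing; not recommended for targeted data",
    duplicate_rate = if (!is.null(pairs)) duplicate_rate(pairs) else NA_real_,
    read_length_histogram = setNames(as.integer(lens), names(lens)),
    mean_callable_depth = if (!is.null(tables)) mean(tables$depth) else NA_real_
  ), class = "ReadQcSummary")
}
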