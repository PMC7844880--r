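# Seed-and-extend mini-aligner over the reduced reference.
#
# Candidate loci come from the same spaced-hash index used for screening:
# each probe hit votes for a (contig, diagonal) pair, top-voted candidates
# are verified by vectorized ungapped comparison, and reads that only fail
# through indels fall back to a small banded dynamic program. The engine is
# deliberately simple — the reduced-reference QC semantics, not the
# alignment algorithm, are the point — but its output contract (SAM records,
# NM, proper-pair flags) is standard.

#' Align reads to the reduced reference
#'
#' Batch aligner. Candidate positions are taken from spaced-hash probe hits
#' by diagonal voting over `(contig, window offset - probe offset)`, in both
#' orientations; the top candidates are verified by ungapped mismatch
#' counting, with a banded alignment (band `max_gap`) fallback for reads
#' whose best ungapped candidate exceeds `max_mismatch` mismatches. The best
#' candidate wins; ties break to (lowest contig, lowest start, forward
#' strand) and score mapq 0. A unique best with no runner-up scores mapq 60,
#' otherwise mapq is scaled by the edit-distance gap to the runner-up.
#' Reads with no admissible candidate are returned unmapped.
#'
#' @param reads character vector of read sequences.
#' @param index `SpacedHashIndex` over `ref`.
#' @param ref `ReducedReference`.
#' @param qname read names (default `read1..n`).
#' @param qual base-quality strings (Phred+33); default constant Q30.
#' @param mate integer mate labels (1/2) carried through to pairing.
#' @param max_mismatch maximum mismatches for an ungapped alignment
#'   (default 5).
#' @param max_gap banded-alignment band half-width / maximum indel bases
#'   (default 3).
#' @param max_candidates candidates verified per read (default 4).
#' @return data.table with one row per read: `qname`, `mate`, `mapped`,
#'   `contig` (index into `ref$contigs`), `start`/`end` (0-based half-open),
#'   `strand`, `nm`, `mapq`, `cigar`, `seq`, `qual` (both in reference
#'   orientation for mapped reads).
#' @export
align_reads <- function(reads, index, ref, qname = NULL, qual = NULL, mate = 1L,
                        max_mismatch = 5L, max_gap = 3L, max_candidates = 4L) {
  stopifnot(inherits(index, "SpacedHashIndex"), inherits(ref, "ReducedReference"))
  n <- length(reads)
  if (is.null(qname)) qname <- sprintf("read%d", seq_len(n))
  if (is.null(qual)) qual <- vapply(nchar(reads), function(L)
    strrep(rawToChar(as.raw(30L + 33L)), L), character(1))
  if (length(mate) == 1L) mate <- rep(as.integer(mate), n)
  out <- data.table::data.table(
    qname = qname, mate = mate, mapped = rep(FALSE, n),
    contig = NA_integer_, start = NA_integer_, end = NA_integer_,
    strand = NA_character_, nm = NA_integer_, mapq = NA_integer_,
    cigar = NA_character_, seq = reads, qual = qual)
  if (n == 0L) return(out[])
  # global concatenated reference codes for vectorized verification
  goff <- c(0L, cumsum(ref$contigs$len))[seq_len(nrow(ref$contigs))]
  refcodes <- unlist(lapply(ref$contigs$seq, seq_codes), use.names = FALSE)
  clen <- ref$contigs$len
  np <- length(index$patterns)
  lens <- nchar(reads)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    nw <- min(L, 96L) %/% 32L
    if (nw == 0L) next
    codes <- codes_matrix(reads[sel], L)
    rcodes <- revcomp_codes(codes)
    # -- collect candidate (read, orient, contig, start) votes --------------
    votes <- vector("list", 2L * nw * np)
    vi <- 0L
    for (orient in 1:2) {
      oc <- if (orient == 1L) codes else rcodes
      keys <- .probe_keys_matrix(oc[seq_len(min(L, 96L)), , drop = FALSE], nw,
                                 index$patterns)
      for (w in seq_len(nw) - 1L) {
        for (p in seq_len(np)) {
          kp <- keys[[w * np + p]]
          tab <- index$tables[[p]]
          hi <- findInterval(kp, tab$key)
          lo <- findInterval(kp - 0.5, tab$key) + 1L
          nh <- pmax(hi - lo + 1L, 0L)
          nh[is.na(kp)] <- 0L
          if (sum(nh) == 0L) next
          has <- nh > 0L
          idx <- sequence(nh[has], from = lo[has])
          vi <- vi + 1L
          votes[[vi]] <- data.table::data.table(
            ri = rep(seq_along(sel)[has], nh[has]),
            orient = orient,
            contig = tab$contig[idx],
            start = tab$offset[idx] - 32L * w)
        }
      }
    }
    if (vi == 0L) next
    vt <- data.table::rbindlist(votes[seq_len(vi)])
    vt <- vt[start > -(max_gap + 1L) & start + L <= clen[contig] + max_gap]
    if (nrow(vt) == 0L) next
    cand <- vt[, .(votes = .N), by = .(ri, orient, contig, start)]
    data.table::setorder(cand, ri, -votes, contig, start, orient)
    cand <- cand[, head(.SD, max_candidates), by = ri]
    # -- ungapped verification ---------------------------------------------
    ok <- cand$start >= 0L & cand$start + L <= clen[cand$contig]
    cand[, nm := NA_integer_]
    if (any(ok)) {
      gstart <- goff[cand$contig[ok]] + cand$start[ok]
      idxmat <- outer(gstart, seq_len(L) - 1L, "+") + 1L   # ncand x L
      refm <- matrix(refcodes[idxmat], nrow = sum(ok))
      readm <- t(codes)[cand$ri[ok], , drop = FALSE]
      flip <- cand$orient[ok] == 2L
      if (any(flip)) readm[flip, ] <- t(rcodes)[cand$ri[ok][flip], , drop = FALSE]
      mm <- refm != readm
      mm[is.na(mm)] <- TRUE
      cand$nm[ok] <- as.integer(rowSums(mm))
    }
    cand[, `:=`(cigar = paste0(L, "M"), aln_start = start, aln_len = L)]
    # -- banded fallback for reads with no ungapped candidate within cap ----
    best_ungapped <- cand[!is.na(nm), min(nm), by = ri]
    need_band <- setdiff(unique(cand$ri),
                         best_ungapped[V1 <= max_mismatch, ri])
    if (max_gap > 0L) {
      for (r in need_band) {
        rows <- which(cand$ri == r)[1:min(2L, sum(cand$ri == r))]
        for (cr in rows) {
          ctg <- cand$contig[cr]
          rd <- if (cand$orient[cr] == 1L) codes[, cand$ri[cr]] else rcodes[, cand$ri[cr]]
          ba <- banded_align(rd, refcodes[(goff[ctg] + 1L):(goff[ctg] + clen[ctg])],
                             cand$start[cr], band = max_gap)
          if (!is.null(ba) && ba$nm <= max_mismatch) {
            data.table::set(cand, i = cr, j = "nm", value = ba$nm)
            data.table::set(cand, i = cr, j = "cigar", value = ba$cigar)
            data.table::set(cand, i = cr, j = "aln_start", value = ba$start)
            data.table::set(cand, i = cr, j = "aln_len", value = ba$ref_len)
          }
        }
      }
    }
    cand <- cand[!is.na(nm) & nm <= max_mismatch &
                   aln_start >= 0L & aln_start + aln_len <= clen[contig]]
    if (nrow(cand) == 0L) next
    # -- pick best per read -------------------------------------------------
    data.table::setorder(cand, ri, nm, contig, aln_start, orient)
    best <- cand[, {
      mq <- if (.N == 1L) 60L
      else if (nm[2L] == nm[1L]) 0L
      else min(60L, 20L * (nm[2L] - nm[1L]))
      .(contig = contig[1L], start = aln_start[1L], len = aln_len[1L],
        orient = orient[1L], nm = nm[1L], cigar = cigar[1L], mapq = mq)
    }, by = ri]
    rows <- sel[best$ri]
    rc_rows <- best$orient == 2L
    data.table::set(out, i = rows, j = "mapped", value = TRUE)
    data.table::set(out, i = rows, j = "contig", value = best$contig)
    data.table::set(out, i = rows, j = "start", value = best$start)
    data.table::set(out, i = rows, j = "end", value = best$start + best$len)
    data.table::set(out, i = rows, j = "strand", value = ifelse(rc_rows, "-", "+"))
    data.table::set(out, i = rows, j = "nm", value = best$nm)
    data.table::set(out, i = rows, j = "mapq", value = best$mapq)
    data.table::set(out, i = rows, j = "cigar", value = best$cigar)
    if (any(rc_rows)) {
      rr <- rows[rc_rows]
      data.table::set(out, i = rr, j = "seq", value = revcomp(out$seq[rr]))
      data.table::set(out, i = rr, j = "qual",
                      value = vapply(out$qual[rr],
                                     function(q) intToUtf8(rev(utf8ToInt(q))),
                                     character(1), USE.NAMES = FALSE))
    }
  }
  out[]
}

#' Align a single read
#'
#' Wrapper around [align_reads()]; returns a one-row alignment record.
#' Unalignable reads come back as an unmapped record, not an error.
#'
#' @inheritParams align_reads
#' @param read read sequence.
#' @export
align_read <- function(read, index, ref, max_mismatch = 5L, max_gap = 3L) {
  align_reads(read, index, ref, max_mismatch = max_mismatch, max_gap = max_gap)
}

# Banded global-in-read alignment of read codes against a contig around an
# anchored start. Unit costs (mismatch 1, indel 1 per base), band half-width
# `band` around the anchor diagonal. Returns NULL if no alignment keeps the
# read inside the contig, else list(nm, start, ref_len, cigar).
banded_align <- function(read_codes, contig_codes, anchor_start, band = 3L) {
  L <- length(read_codes)
  clen <- length(contig_codes)
  lo0 <- anchor_start - band
  # DP over read rows; column j = ref position (0-based) in banded window
  INF <- .Machine$integer.max %/% 4L
  width <- 2L * band + 1L
  # D[i, d]: cost aligning first i read bases ending before ref pos
  # (anchor_start + i + d - band - 1) + 1 ; d in 1..width
  D <- matrix(INF, nrow = L + 1L, ncol = width)
  D[1L, ] <- 0L   # start shift within the band is a placement, not an edit
  for (i in seq_len(L)) {
    for (d in seq_len(width)) {
      rpos <- anchor_start + (i - 1L) + (d - band - 1L)  # 0-based ref pos consumed
      best <- INF
      if (rpos >= 0L && rpos < clen) {
        sub <- D[i, d] + as.integer(is.na(read_codes[i]) ||
                                      contig_codes[rpos + 1L] != read_codes[i])
        if (sub < best) best <- sub
      }
      if (d > 1L) {                      # deletion from read (gap in read)
        del <- D[i + 1L, d - 1L] + 1L    # consumes ref base, same read row
        if (del < best) best <- del
      }
      if (d < width) {                   # insertion in read (gap in ref)
        ins <- D[i, d + 1L] + 1L
        if (ins < best) best <- ins
      }
      D[i + 1L, d] <- best
    }
  }
  dbest <- which.min(D[L + 1L, ])
  nm <- D[L + 1L, dbest]
  if (nm >= INF) return(NULL)
  end_ref <- anchor_start + L + (dbest - band - 1L)      # 0-based half-open end
  # traceback for start + cigar
  ops <- character(0)
  i <- L; d <- dbest
  while (i > 0L || d != band + 1L) {
    rpos <- anchor_start + (i - 1L) + (d - band - 1L)
    if (i > 0L && rpos >= 0L && rpos < clen &&
        D[i + 1L, d] == D[i, d] + as.integer(is.na(read_codes[i]) ||
                                             contig_codes[rpos + 1L] != read_codes[i])) {
      ops <- c("M", ops); i <- i - 1L
    } else if (d > 1L && D[i + 1L, d] == D[i + 1L, d - 1L] + 1L) {
      ops <- c("D", ops); d <- d - 1L
    } else if (d < width && i > 0L && D[i + 1L, d] == D[i, d + 1L] + 1L) {
      ops <- c("I", ops); i <- i - 1L; d <- d + 1L
    } else if (i == 0L) {
      # leading shift consumed as start offset, not cigar
      break
    } else {
      return(NULL)  # traceback failed (outside band)
    }
  }
  start <- end_ref - sum(ops != "I")
  if (start < 0L || end_ref > clen) return(NULL)
  r <- rle(ops)
  list(nm = as.integer(nm), start = as.integer(start),
       ref_len = as.integer(end_ref - start),
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Pair mate alignments and flag proper pairs
#'
#' Joins mate-1 and mate-2 alignment records by read name and derives pair
#' status. A pair is proper when both mates map to the same contig on
#' opposite strands with the leftmost mate forward, both with mapping
#' quality at least `mapq_min`, and positive outer distance; the observed
#' insert size `t_o` (rightmost end minus leftmost start) is recorded only
#' then. Pairs on different contigs, in abnormal orientation, or with low
#' mapping quality are flagged improper and are discarded downstream in the
#' insert-size estimation.
#'
#' @param aln alignment data.table from [align_reads()] holding both mates
#'   (column `mate` in 1/2), or mate-1 records if `aln2` is given.
#' @param aln2 optional mate-2 alignment table.
#' @param mapq_min minimum mapping quality for a proper pair (default 20).
#' @return data.table keyed by `qname`: mate coordinates, `proper`, `t_o`,
#'   plus left/right role columns used by the insert-size tuples.
#' @export
pair_and_flag <- function(aln, aln2 = NULL, mapq_min = 20L) {
  if (!is.null(aln2)) {
    a1 <- data.table::as.data.table(aln); a1[, mate := 1L]
    a2 <- data.table::as.data.table(aln2); a2[, mate := 2L]
    aln <- rbind(a1, a2)
  }
  a1 <- aln[mate == 1L]
  a2 <- aln[mate == 2L]
  if (!setequal(a1$qname, a2$qname)) stop("mate read names do not match")
  data.table::setkey(a1, qname); data.table::setkey(a2, qname)
  p <- data.table::data.table(
    qname = a1$qname,
    mapped1 = a1$mapped, contig1 = a1$contig, start1 = a1$start, end1 = a1$end,
    strand1 = a1$strand, mapq1 = a1$mapq,
    mapped2 = a2[a1$qname, mapped], contig2 = a2[a1$qname, contig],
    start2 = a2[a1$qname, start], end2 = a2[a1$qname, end],
    strand2 = a2[a1$qname, strand], mapq2 = a2[a1$qname, mapq])
  both <- p$mapped1 & p$mapped2
  same_contig <- both & p$contig1 == p$contig2
  left1 <- p$start1 <= p$start2
  start_l <- ifelse(left1, p$start1, p$start2)
  end_r <- ifelse(left1, p$end2, p$end1)
  strand_l <- ifelse(left1, p$strand1, p$strand2)
  strand_r <- ifelse(left1, p$strand2, p$strand1)
  p[, `:=`(
    start_l = ifelse(same_contig, start_l, NA_integer_),
    end_r = ifelse(same_contig, end_r, NA_integer_),
    proper = same_contig & strand_l == "+" & strand_r == "-" &
      end_r - start_l > 0L & p$mapq1 >= mapq_min & p$mapq2 >= mapq_min
  )]
  p[is.na(proper), proper := FALSE]
  p[, t_o := ifelse(proper, end_r - start_l, NA_integer_)]
  p[, contig := ifelse(proper, contig1, NA_integer_)]
  p[]
}

#' Write alignments as SAM
#'
#' Emits a valid SAM file (header `@HD`/`@SQ` over all reduced-reference
#' contigs, 1-based coordinates, NM tag). Pairing flags are derived from the
#' `mate` column and, when a pairs table is supplied, proper-pair and
#' duplicate bits are set.
#'
#' @param aln alignment data.table (both mates).
#' @param ref `ReducedReference`.
#' @param path output SAM path.
#' @param pairs optional pairs table from [pair_and_flag()] (adds 0x2); a
#'   logical `dup` column (see [mark_duplicates()]) sets 0x400.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, ref, path, pairs = NULL) {
  co <- ref$contigs
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", co$name, co$len),
           "@PG\tID:seqsentry\tPN:seqsentry")
  a <- data.table::as.data.table(aln)
  if (!"mate" %in% names(a)) a[, mate := 1L]
  proper <- dup <- setNames(rep(FALSE, nrow(a)), NULL)
  if (!is.null(pairs)) {
    pk <- setNames(pairs$proper, pairs$qname)
    proper <- pk[a$qname] %in% TRUE
    if ("dup" %in% names(pairs)) {
      dk <- setNames(pairs$dup, pairs$qname)
      dup <- dk[a$qname] %in% TRUE
    }
  }
  # mate info
  ms <- a[, .(qname, mate, mapped, contig, start, strand)]
  ms[, omate := 3L - mate]
  data.table::setkey(ms, qname, mate)
  om <- ms[data.table::data.table(qname = a$qname, mate = 3L - a$mate)]
  paired <- a$qname %in% a$qname[duplicated(a$qname)] | any(a$mate == 2L)
  flag <- rep(0L, nrow(a))
  flag <- flag + ifelse(paired, 1L, 0L)
  flag <- flag + ifelse(proper & a$mapped, 2L, 0L)
  flag <- flag + ifelse(!a$mapped, 4L, 0L)
  flag <- flag + ifelse(paired & !(om$mapped %in% TRUE), 8L, 0L)
  flag <- flag + ifelse(a$mapped & a$strand == "-", 16L, 0L)
  flag <- flag + ifelse(paired & (om$strand %in% "-"), 32L, 0L)
  flag <- flag + ifelse(paired & a$mate == 1L, 64L, 0L)
  flag <- flag + ifelse(paired & a$mate == 2L, 128L, 0L)
  flag <- flag + ifelse(dup, 1024L, 0L)
  rname <- ifelse(a$mapped, co$name[a$contig], "*")
  pos <- ifelse(a$mapped, a$start + 1L, 0L)
  mapq <- ifelse(a$mapped, a$mapq, 0L)
  cig <- ifelse(a$mapped, a$cigar, "*")
  rnext <- ifelse(om$mapped %in% TRUE,
                  ifelse(a$mapped & om$contig == a$contig, "=", co$name[om$contig]),
                  "*")
  pnext <- ifelse(om$mapped %in% TRUE, om$start + 1L, 0L)
  tlen <- rep(0L, nrow(a))
  if (!is.null(pairs)) {
    tk <- setNames(pairs$t_o, pairs$qname)
    sk <- setNames(pairs$start_l, pairs$qname)
    t_o <- tk[a$qname]
    leftmost <- a$mapped & !is.na(t_o) & a$start == sk[a$qname]
    tlen <- ifelse(is.na(t_o), 0L, ifelse(leftmost, t_o, -t_o))
  }
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s\tNM:i:%d",
                   a$qname, flag, rname, pos, mapq, cig, rnext, pnext, tlen,
                   a$seq, a$qual, ifelse(a$mapped, a$nm, 0L))
  writeLines(c(hdr, lines), path)
  invisible(path)
}
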