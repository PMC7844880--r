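# Marker selection and construction of the reduced reference genome:
# flanking-sequence contigs centred on known common SNPs.

#' Select the marker panel for the reduced reference
#'
#' Randomly samples a designated number of biallelic SNPs from a candidate
#' set, keeping only common variants (minor allele frequency strictly above
#' `maf_min`), dropping sites overlapping an exclusion mask, optionally
#' restricting to target regions (e.g. an exome list), and enforcing a
#' minimum pairwise spacing of `2 * w_long` so that no two flanking contigs
#' can overlap (greedy left-to-right conflict removal after sampling). A
#' fraction `long_fraction` of the retained markers is flagged for long
#' flanks; the remainder get short flanks.
#'
#' @param candidates data.frame/data.table of candidate SNPs with columns
#'   `chrom`, `pos` (1-based), `ref`, `alt` (single bases), `af`
#'   (alternate-allele frequency).
#' @param exclude_regions optional data.frame with `chrom`,`start`,`end`
#'   (0-based half-open) or a `GRanges`; overlapping SNPs are excluded.
#' @param target_regions optional regions (same conventions); when given,
#'   only SNPs inside them are eligible.
#' @param n_target number of markers to select (all eligible if fewer).
#' @param maf_min minimum minor allele frequency, exclusive (default 0.05).
#' @param long_fraction fraction of markers given long flanks (default 0.10).
#' @param w_short,w_long flank half-widths in bases (defaults 250 / 1000).
#' @param seed integer seed; selection is fully reproducible.
#' @param min_spacing minimum distance between retained markers (default
#'   `2 * w_long`, which guarantees non-overlap of any two contigs; smaller
#'   values allow denser panels at the risk of adjacent long-flank contigs
#'   overlapping).
#' @return a `MarkerPanel`: list with `markers` (data.table sorted by
#'   chrom/pos with `flank_class` column), `w_short`, `w_long`,
#'   `long_fraction`.
#' @export
select_markers <- function(candidates, exclude_regions = NULL, target_regions = NULL,
                           n_target = 10000L, maf_min = 0.05, long_fraction = 0.10,
                           w_short = 250L, w_long = 1000L, seed = 1L,
                           min_spacing = 2L * w_long) {
  if (n_target < 1L) stop("n_target must be >= 1")
  cand <- data.table::as.data.table(candidates)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "af") %in% names(cand)))
  ok <- cand$ref %in% .dna_bases & cand$alt %in% .dna_bases & cand$ref != cand$alt &
    pmin(cand$af, 1 - cand$af) > maf_min
  cand <- cand[ok]
  if (nrow(cand) > 0L && !is.null(exclude_regions)) {
    gr <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$pos, cand$pos))
    hit <- IRanges::overlapsAny(gr, regions_to_granges(exclude_regions))
    cand <- cand[!hit]
  }
  if (nrow(cand) > 0L && !is.null(target_regions)) {
    gr <- GenomicRanges::GRanges(cand$chrom, IRanges::IRanges(cand$pos, cand$pos))
    hit <- IRanges::overlapsAny(gr, regions_to_granges(target_regions))
    cand <- cand[hit]
  }
  if (nrow(cand) == 0L) stop("no eligible markers")
  sel <- withr::with_seed(seed, {
    idx <- if (nrow(cand) <= n_target) seq_len(nrow(cand)) else
      sample.int(nrow(cand), n_target)
    m <- cand[idx][order(chrom, pos)]
    # greedy left-to-right spacing: keep a marker only if >= min_spacing from
    # the last retained marker on the same chromosome
    keep <- logical(nrow(m))
    last_chrom <- ""; last_pos <- -Inf
    for (i in seq_len(nrow(m))) {
      if (m$chrom[i] != last_chrom || m$pos[i] - last_pos >= min_spacing) {
        keep[i] <- TRUE
        last_chrom <- m$chrom[i]; last_pos <- m$pos[i]
      }
    }
    m <- m[keep]
    n_long <- round(nrow(m) * long_fraction)
    m[, flank_class := "short"]
    if (n_long > 0L) m$flank_class[sample.int(nrow(m), n_long)] <- "long"
    m
  })
  structure(list(markers = sel[], w_short = as.integer(w_short),
                 w_long = as.integer(w_long), long_fraction = long_fraction),
            class = "MarkerPanel")
}

#' @export
print.MarkerPanel <- function(x, ...) {
  cat(sprintf("MarkerPanel: %d markers (%d long / %d short), w = %d/%d\n",
              nrow(x$markers), sum(x$markers$flank_class == "long"),
              sum(x$markers$flank_class == "short"), x$w_short, x$w_long))
  invisible(x)
}

#' Extract flanking contigs around panel markers
#'
#' Builds one contig per marker: the `2w + 1` bases of the source genome
#' centred on the SNP (reference allele at the centre), where `w` is the
#' short or long flank half-width by the marker's flank class. Markers whose
#' centre base disagrees with the recorded reference allele, whose flanks
#' contain N, or that lack full flank room are dropped with a warning. Each
#' contig records its callable interval: the central `2(w - r) + 1` bases
#' around the variant column, i.e. the 0-based half-open interval
#' `[r, 2w + 1 - r)`, over which base-level metrics are computed.
#'
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences, uppercase A/C/G/T/N.
#' @param panel a `MarkerPanel` from [select_markers()].
#' @param read_len expected read length `r` (sets callable intervals).
#' @return a `ReducedReference`: list with `contigs` (data.table: `name`,
#'   `chrom`, `pos`, `ref`, `alt`, `af`, `w`, `flank_class`, `genome_offset`
#'   (0-based genome coordinate of contig base 0), `len`, `callable_start`,
#'   `callable_end`, `seq`), `read_len`, `provenance`.
#' @export
extract_flanks <- function(genome, panel, read_len = 150L) {
  stopifnot(inherits(panel, "MarkerPanel"))
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  m <- data.table::copy(panel$markers)
  m[, w := ifelse(flank_class == "long", panel$w_long, panel$w_short)]
  chrom_len <- setNames(nchar(genome), names(genome))
  rows <- vector("list", nrow(m))
  dropped <- 0L
  for (i in seq_len(nrow(m))) {
    chrom <- m$chrom[i]; pos <- m$pos[i]; w <- m$w[i]
    if (!chrom %in% names(genome) || pos - w < 1L || pos + w > chrom_len[[chrom]]) {
      dropped <- dropped + 1L
      next
    }
    s <- substr(genome[[chrom]], pos - w, pos + w)
    if (substr(s, w + 1L, w + 1L) != m$ref[i] || grepl("[^ACGT]", s)) {
      dropped <- dropped + 1L
      next
    }
    rows[[i]] <- data.table::data.table(
      name = sprintf("%s:%d:%s:%s", chrom, pos, m$ref[i], m$alt[i]),
      chrom = chrom, pos = pos, ref = m$ref[i], alt = m$alt[i], af = m$af[i],
      w = w, flank_class = m$flank_class[i],
      genome_offset = pos - w - 1L, len = 2L * w + 1L,
      # central 2(w-r)+1 bases around the variant column
      callable_start = read_len, callable_end = 2L * w + 1L - read_len,
      seq = s)
  }
  if (dropped > 0L) {
    warning(sprintf("%d marker(s) dropped (flank room, N in flank, or reference-allele mismatch)", dropped))
  }
  contigs <- data.table::rbindlist(rows)
  if (nrow(contigs) == 0L) stop("no usable markers after flank extraction")
  structure(list(contigs = contigs, read_len = as.integer(read_len),
                 provenance = list(w_short = panel$w_short, w_long = panel$w_long,
                                   long_fraction = panel$long_fraction,
                                   n_source_markers = nrow(panel$markers))),
            class = "ReducedReference")
}

#' @export
print.ReducedReference <- function(x, ...) {
  cat(sprintf("ReducedReference: %d contigs, %d bp total, read_len = %d\n",
              nrow(x$contigs), sum(x$contigs$len), x$read_len))
  invisible(x)
}

#' Write / read a reduced reference
#'
#' Serializes a `ReducedReference` as `prefix.fa` (one FASTA record per
#' contig, header `name chrom=.. pos=.. ref=.. alt=.. af=.. w=..`) plus a
#' tab-delimited marker index `prefix.markers.tsv` carrying the full contig
#' table and the read length. `read_reduced_reference()` inverts it exactly.
#'
#' @param ref a `ReducedReference`.
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_reduced_reference <- function(ref, prefix) {
  stopifnot(inherits(ref, "ReducedReference"))
  co <- ref$contigs
  headers <- sprintf("%s chrom=%s pos=%d ref=%s alt=%s af=%.17g w=%d",
                     co$name, co$chrom, co$pos, co$ref, co$alt, co$af, co$w)
  dss <- Biostrings::DNAStringSet(co$seq)
  names(dss) <- headers
  Biostrings::writeXStringSet(dss, filepath = paste0(prefix, ".fa"), width = 80L)
  tsv <- co[, .(contig_name = name, chrom, pos, ref, alt, af, w, flank_class,
                genome_offset, callable_start, callable_end)]
  con <- file(paste0(prefix, ".markers.tsv"), "wt")
  writeLines(sprintf("#read_len=%d", ref$read_len), con)
  close(con)
  data.table::fwrite(tsv, paste0(prefix, ".markers.tsv"), sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(prefix)
}

#' @rdname write_reduced_reference
#' @export
read_reduced_reference <- function(prefix) {
  fa <- Biostrings::readDNAStringSet(paste0(prefix, ".fa"))
  hdr <- names(fa)
  parse_field <- function(field) {
    m <- regmatches(hdr, regexpr(paste0(field, "=[^ ]+"), hdr))
    bad <- !grepl(paste0(field, "="), hdr)
    if (any(bad)) {
      stop(sprintf("malformed FASTA header (missing '%s') in record '%s'",
                   field, sub(" .*", "", hdr[bad][1L])))
    }
    sub(paste0(field, "="), "", m)
  }
  first_line <- readLines(paste0(prefix, ".markers.tsv"), n = 1L)
  read_len <- as.integer(sub("#read_len=", "", first_line))
  tsv <- data.table::fread(paste0(prefix, ".markers.tsv"), skip = 1L, sep = "\t")
  contigs <- data.table::data.table(
    name = sub(" .*", "", hdr),
    chrom = parse_field("chrom"),
    pos = as.integer(parse_field("pos")),
    ref = parse_field("ref"),
    alt = parse_field("alt"),
    af = as.numeric(parse_field("af")),
    w = as.integer(parse_field("w")),
    seq = as.character(fa))
  idx <- match(contigs$name, tsv$contig_name)
  if (anyNA(idx)) stop("marker index and FASTA disagree on contig names")
  contigs[, `:=`(flank_class = tsv$flank_class[idx],
                 genome_offset = as.integer(tsv$genome_offset[idx]),
                 len = 2L * w + 1L,
                 callable_start = as.integer(tsv$callable_start[idx]),
                 callable_end = as.integer(tsv$callable_end[idx]))]
  data.table::setcolorder(contigs, c("name", "chrom", "pos", "ref", "alt", "af", "w",
                                     "flank_class", "genome_offset", "len",
                                     "callable_start", "callable_end", "seq"))
  structure(list(contigs = contigs, read_len = read_len,
                 provenance = list(restored_from = prefix)),
            class = "ReducedReference")
}
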