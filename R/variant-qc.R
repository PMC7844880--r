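# Variant-level QC: per-marker pileup at the contig centre column, genotype
# likelihoods under the standard biallelic error model, and VCF output with
# GT/PL/GP.

#' Pile up bases at the marker columns
#'
#' Extracts, for every marker, the base each covering read carries at the
#' contig centre column, with its base quality and the read's mapping
#' quality. Reads below `min_mapq`, bases below `min_baseq`, gapped
#' alignments, and (when `dup_qnames` is given) duplicate pairs are excluded.
#' Uncovered markers still yield an (empty) site so the VCF stays complete.
#'
#' @param aln alignment data.table from [align_reads()].
#' @param ref `ReducedReference`.
#' @param min_mapq minimum mapping quality (default 20).
#' @param min_baseq minimum base quality (default 13).
#' @param dup_qnames optional character vector of duplicate read names to
#'   exclude.
#' @return a `PileupSites`: list with `calls` (data.table `site`, `base`,
#'   `bclass` 0 ref/1 alt/2 other, `qual`) and `sites` (one row per marker:
#'   `site`, `name`, `chrom`, `pos`, `ref`, `alt`, `af`, `n_ref`, `n_alt`,
#'   `n_other`, `depth`).
#' @export
pileup <- function(aln, ref, min_mapq = 20L, min_baseq = 13L, dup_qnames = NULL) {
  a <- data.table::as.data.table(aln)
  co <- ref$contigs
  center <- co$w
  keep <- a$mapped %in% TRUE & a$mapq >= min_mapq & grepl("^[0-9]+M$", a$cigar) &
    a$start <= center[a$contig] & a$end > center[a$contig]
  keep[is.na(keep)] <- FALSE
  if (!is.null(dup_qnames)) keep <- keep & !(a$qname %in% dup_qnames)
  k <- which(keep)
  if (length(k)) {
    off <- center[a$contig[k]] - a$start[k] + 1L
    base <- substr(a$seq[k], off, off)
    qual <- utf8ToInt(paste(substr(a$qual[k], off, off), collapse = "")) - 33L
    calls <- data.table::data.table(site = a$contig[k], base = base, qual = qual)
    calls <- calls[qual >= min_baseq & base %in% .dna_bases]
    calls[, bclass := ifelse(base == co$ref[site], 0L,
                             ifelse(base == co$alt[site], 1L, 2L))]
  } else {
    calls <- data.table::data.table(site = integer(0), base = character(0),
                                    qual = integer(0), bclass = integer(0))
  }
  agg <- calls[, .(n_ref = sum(bclass == 0L), n_alt = sum(bclass == 1L),
                   n_other = sum(bclass == 2L)), by = site]
  sites <- data.table::data.table(site = seq_len(nrow(co)), name = co$name,
                                  chrom = co$chrom, pos = co$pos, ref = co$ref,
                                  alt = co$alt, af = co$af,
                                  n_ref = 0L, n_alt = 0L, n_other = 0L)
  if (nrow(agg)) {
    sites$n_ref[agg$site] <- agg$n_ref
    sites$n_alt[agg$site] <- agg$n_alt
    sites$n_other[agg$site] <- agg$n_other
  }
  sites[, depth := n_ref + n_alt + n_other]
  structure(list(calls = calls[], sites = sites[]), class = "PileupSites")
}

# log10 P(base | genotype g) per call: p = (g/2) P(b|alt) + (1-g/2) P(b|ref),
# P(b|allele) = 1-e if b equals the allele else e/3. Returns n x 3 matrix.
.base_gl_matrix <- function(bclass, qual) {
  e <- phred_to_error(qual)
  pref <- ifelse(bclass == 0L, 1 - e, e / 3)
  palt <- ifelse(bclass == 1L, 1 - e, e / 3)
  cbind(g0 = pref, g1 = 0.5 * (pref + palt), g2 = palt)
}

#' Genotype likelihoods, posteriors and calls at panel markers
#'
#' Standard biallelic model: per-base error `e = 10^(-q/10)`;
#' `GL(g) = sum_b log10[(g/2) P(b|alt) + (1 - g/2) P(b|ref)]` with
#' `P(b|allele) = 1 - e` when the base equals the allele and `e/3` otherwise.
#' PL is the rescaled integer Phred likelihood (min 0); GP is the posterior
#' under a Hardy-Weinberg prior at the panel allele frequency; GT is the
#' argmax-posterior genotype (`./.` for uncovered sites).
#'
#' @param pile a `PileupSites` from [pileup()].
#' @return data.table: one row per marker with `GL0..GL2` (log10), `PL0..PL2`,
#'   `GP0..GP2`, `GT`, `depth`.
#' @export
genotype_calls <- function(pile) {
  sites <- pile$sites
  n <- nrow(sites)
  gl <- matrix(0, nrow = n, ncol = 3L)
  if (nrow(pile$calls)) {
    m <- .base_gl_matrix(pile$calls$bclass, pile$calls$qual)
    lg <- log10(m)
    for (g in 1:3) {
      s <- rowsum(lg[, g], group = pile$calls$site)
      gl[as.integer(rownames(s)), g] <- s
    }
  }
  af <- sites$af
  prior <- cbind((1 - af)^2, 2 * af * (1 - af), af^2)
  post <- prior * 10^(gl - apply(gl, 1L, max))
  post <- post / rowSums(post)
  pl <- round(-10 * (gl - apply(gl, 1L, max)))
  gt_idx <- max.col(post, ties.method = "first")
  gt <- c("0/0", "0/1", "1/1")[gt_idx]
  gt[sites$depth == 0L] <- "./."
  out <- data.table::data.table(
    site = sites$site, name = sites$name, chrom = sites$chrom, pos = sites$pos,
    ref = sites$ref, alt = sites$alt, af = af, depth = sites$depth,
    GL0 = gl[, 1L], GL1 = gl[, 2L], GL2 = gl[, 3L],
    PL0 = pl[, 1L], PL1 = pl[, 2L], PL2 = pl[, 3L],
    GP0 = post[, 1L], GP1 = post[, 2L], GP2 = post[, 3L], GT = gt)
  out[]
}

#' Genotype likelihoods for a single site
#'
#' @param bclass integer base classes (0 ref, 1 alt, 2 other).
#' @param qual integer base qualities (Phred).
#' @return numeric GL triple (log10) for genotypes 0, 1, 2.
#' @export
genotype_likelihoods <- function(bclass, qual) {
  if (length(bclass) == 0L) return(c(0, 0, 0))
  unname(colSums(log10(.base_gl_matrix(bclass, qual))))
}

#' Write genotype calls as VCF 4.2
#'
#' One record per marker in genome coordinates, sorted by (chrom, pos), with
#' FORMAT `GT:PL:GP` and INFO `AF` (panel allele frequency) and `DP` (site
#' depth).
#'
#' @param calls data.table from [genotype_calls()].
#' @param path output path.
#' @param sample_name sample column name.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, path, sample_name = "SAMPLE") {
  cl <- data.table::as.data.table(calls)[order(chrom, pos)]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=seqsentry",
           sprintf("##contig=<ID=%s>", unique(cl$chrom)),
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Panel alternate allele frequency\">",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Pileup depth at site\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PL,Number=G,Type=Integer,Description=\"Phred-scaled genotype likelihoods\">",
           "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype posterior probabilities\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_name))
  fmt <- sprintf("%s:%d,%d,%d:%.4g,%.4g,%.4g", cl$GT, cl$PL0, cl$PL1, cl$PL2,
                 cl$GP0, cl$GP1, cl$GP2)
  recs <- sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\tAF=%g;DP=%d\tGT:PL:GP\t%s",
                  cl$chrom, cl$pos, cl$name, cl$ref, cl$alt, cl$af, cl$depth, fmt)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
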