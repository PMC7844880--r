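# Deterministic synthetic data: genome, marker panel with SVD ancestry
# structure, diploid paired reads with errors/duplicates/insert-size law,
# and in-silico contamination mixing. Every estimator in the package is
# exercised against this ground truth.

#' Simulation configuration
#'
#' Defaults describe a realistic short-read experiment at desk scale: a 1 Mb
#' genome at GC 0.5, 500 common markers (minor allele frequency above 0.05),
#' 150-bp paired reads, fragment length Normal(350, 50) truncated at twice
#' the read length (substantial censoring on 501-bp contigs, nearly full
#' observation on 2001-bp contigs), constant Q30 base quality with errors at
#' the reported rate, no duplicates and no contamination unless asked for.
#'
#' @param genome_len genome length in bases.
#' @param gc target GC fraction.
#' @param n_markers number of planted SNPs.
#' @param read_len read length r.
#' @param depth mean sequenced depth (read bases per genome base).
#' @param insert_mean,insert_sd fragment-length law (Normal, truncated at
#'   `2 * read_len`).
#' @param base_q reported base quality (constant) or a per-cycle vector.
#' @param error_rate per-base error probability; default `10^(-base_q/10)`
#'   (reported quality is truthful).
#' @param dup_rate fraction of emitted pairs that are PCR duplicates.
#' @param alpha contamination fraction (used by [mix_contamination()]).
#' @param n_pops,K synthetic ancestry populations and PC dimensions.
#' @param seed mandatory integer seed.
#' @return a `SimConfig` list.
#' @export
sim_config <- function(genome_len = 1e6, gc = 0.5, n_markers = 500L,
                       read_len = 150L, depth = 10, insert_mean = 350,
                       insert_sd = 50, base_q = 30L, error_rate = NULL,
                       dup_rate = 0, alpha = 0, n_pops = 3L, K = 2L,
                       seed = 1L) {
  if (is.null(error_rate)) error_rate <- phred_to_error(base_q[1L])
  stopifnot(dup_rate >= 0, dup_rate < 1, alpha >= 0, alpha <= 1,
            error_rate >= 0, error_rate <= 1, !is.null(seed))
  structure(list(genome_len = as.integer(genome_len), gc = gc,
                 n_markers = as.integer(n_markers), read_len = as.integer(read_len),
                 depth = depth, insert_mean = insert_mean, insert_sd = insert_sd,
                 base_q = as.integer(base_q), error_rate = error_rate,
                 dup_rate = dup_rate, alpha = alpha, n_pops = as.integer(n_pops),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a genome, a candidate-SNP set, and an SVD ancestry panel
#'
#' Draws a random genome at the target GC, plants `n_markers` biallelic SNPs
#' at well-spaced positions with minor allele frequency above 0.05, and
#' builds a synthetic SVD panel: marker mean dosages `mu = 2 af`, random PC
#' loadings, and `n_pops` populations at well-separated PC centroids with 20
#' labelled reference samples each (so PC clusters are separable by
#' construction).
#'
#' @param cfg a `SimConfig`.
#' @param spacing minimum distance in bases between planted markers
#'   (default 2100, just above `2 * w_long` for the default long flank so
#'   selected contigs can never overlap).
#' @param w_edge flank room kept clear at chromosome edges (default 1000).
#' @return list: `genome` (named character vector, one chromosome `chr1`),
#'   `snps` (data.table `chrom`,`pos`,`ref`,`alt`,`af`), `panel`
#'   (`SvdPanel`), `pop_centroids` (matrix n_pops x K).
#' @export
simulate_reference_and_panel <- function(cfg, spacing = 2100L, w_edge = 1000L) {
  withr::with_seed(cfg$seed, {
    p <- c(A = (1 - cfg$gc) / 2, C = cfg$gc / 2, G = cfg$gc / 2, T = (1 - cfg$gc) / 2)
    genome <- paste(sample(names(p), cfg$genome_len, replace = TRUE, prob = p),
                    collapse = "")
    lo <- w_edge + 1L
    hi <- cfg$genome_len - w_edge
    slots <- seq.int(lo, hi, by = spacing)
    if (length(slots) < cfg$n_markers) {
      stop(sprintf("genome too short for %d markers at spacing %d", cfg$n_markers, spacing))
    }
    pos <- sort(sample(slots, cfg$n_markers))
    ref <- substring(genome, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(.dna_bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    maf <- runif(cfg$n_markers, 0.05 + 1e-6, 0.5)
    flip <- runif(cfg$n_markers) < 0.5
    af <- ifelse(flip, 1 - maf, maf)
    snps <- data.table::data.table(chrom = "chr1", pos = pos, ref = ref,
                                   alt = alt, af = af)
    # SVD ancestry panel: centroids on a circle of radius 2, random loadings
    ang <- 2 * pi * (seq_len(cfg$n_pops) - 1L) / cfg$n_pops
    cent <- cbind(2 * cos(ang), 2 * sin(ang))
    if (cfg$K > 2L) cent <- cbind(cent, matrix(0, cfg$n_pops, cfg$K - 2L))
    cent <- cent[, seq_len(cfg$K), drop = FALSE]
    L <- matrix(rnorm(cfg$n_markers * cfg$K, sd = 0.12), ncol = cfg$K)
    markers <- data.table::data.table(chrom = "chr1", pos = pos, ref = ref,
                                      alt = alt, mu = clamp(2 * af, 0.02, 1.98))
    for (k in seq_len(cfg$K)) markers[[paste0("L", k)]] <- L[, k]
    rc <- data.table::rbindlist(lapply(seq_len(cfg$n_pops), function(pp) {
      n <- 20L
      co <- matrix(rep(cent[pp, ], each = n), nrow = n) +
        matrix(rnorm(n * cfg$K, sd = 0.08), nrow = n)
      d <- data.table::data.table(sample = sprintf("POP%d_S%02d", pp, seq_len(n)),
                                  pop = sprintf("POP%d", pp))
      for (k in seq_len(cfg$K)) d[[paste0("pc", k)]] <- co[, k]
      d
    }))
    list(genome = c(chr1 = genome), snps = snps,
         panel = svd_panel(markers, rc), pop_centroids = cent)
  })
}

#' Write candidate SNPs as a minimal VCF
#'
#' @param snps data.table `chrom`,`pos`,`ref`,`alt`,`af`.
#' @param path output path.
#' @export
write_snp_vcf <- function(snps, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
                  snps$chrom, snps$pos, snps$ref, snps$alt, snps$af)
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read candidate SNPs from a VCF
#'
#' Parses biallelic SNP records and the `AF` INFO field.
#'
#' @param path VCF path.
#' @return data.table `chrom`,`pos`,`ref`,`alt`,`af`.
#' @export
read_snp_vcf <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  f <- data.table::tstrsplit(lines, "\t")
  af <- suppressWarnings(as.numeric(sub(".*AF=([0-9.eE+-]+).*", "\\1", f[[8]])))
  dt <- data.table::data.table(chrom = f[[1]], pos = as.integer(f[[2]]),
                               ref = f[[4]], alt = f[[5]], af = af)
  dt[nchar(ref) == 1L & nchar(alt) == 1L & !is.na(af)]
}

#' Sample a diploid individual's marker genotypes
#'
#' Genotypes drawn as `Binomial(2, f_i(pc))` from the panel's
#' individual-specific allele frequencies at ancestry coordinates `pc`.
#'
#' @param panel an `SvdPanel`.
#' @param pc ancestry coordinates.
#' @param seed integer seed.
#' @return integer vector of alternate-allele dosages (0/1/2) per marker.
#' @export
simulate_genotypes <- function(panel, pc, seed) {
  f <- site_af(pc, panel)
  withr::with_seed(seed, rbinom(length(f), 2L, f))
}

#' Simulate paired-end reads from a diploid sample
#'
#' Fragments are sampled uniformly from the supplied sequences (probability
#' proportional to length), fragment length from the configured truncated
#' normal, mate orientation FR; per-base errors at the configured rate
#' replace the true base with a uniform different base; PCR duplicates are
#' injected by re-emitting already-drawn fragments (same coordinates, fresh
#' errors) so that `dup_rate` of all pairs are duplicates in expectation.
#' Variant positions carry the individual's genotype: heterozygous sites put
#' the alternate allele on one of the two haplotypes.
#'
#' @param genome named character vector of sequences.
#' @param variants NULL or data.table `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `gt` (0/1/2 alternate dosage).
#' @param cfg a `SimConfig`.
#' @param n_pairs override the pair count (default `depth * total_len / (2 r)`).
#' @param seed override `cfg$seed`.
#' @return list `reads` (data.table `qname`,`seq1`,`qual1`,`seq2`,`qual2`)
#'   and `truth` (data.table `qname`, `seq_name`, `frag_start` 0-based,
#'   `insert`, `hap`, `dup`).
#' @export
simulate_reads <- function(genome, variants = NULL, cfg, n_pairs = NULL,
                           seed = cfg$seed) {
  r <- cfg$read_len
  lens <- nchar(genome)
  if (is.null(n_pairs)) n_pairs <- round(cfg$depth * sum(lens) / (2 * r))
  withr::with_seed(seed, {
    # diploid haplotypes
    hap1 <- genome; hap2 <- genome
    if (!is.null(variants) && nrow(variants)) {
      v <- data.table::as.data.table(variants)
      v[, on_h1 := gt == 2L | (gt == 1L & runif(.N) < 0.5)]
      v[, on_h2 := gt == 2L | (gt == 1L & !on_h1)]
      for (sq in unique(v$chrom)) {
        vv <- v[chrom == sq]
        s1 <- strsplit(hap1[[sq]], "")[[1L]]
        s2 <- strsplit(hap2[[sq]], "")[[1L]]
        s1[vv$pos[vv$on_h1]] <- vv$alt[vv$on_h1]
        s2[vv$pos[vv$on_h2]] <- vv$alt[vv$on_h2]
        hap1[[sq]] <- paste(s1, collapse = "")
        hap2[[sq]] <- paste(s2, collapse = "")
      }
    }
    n_orig <- round(n_pairs * (1 - cfg$dup_rate))
    n_dup <- n_pairs - n_orig
    sq <- sample(seq_along(genome), n_orig, replace = TRUE, prob = lens)
    tlen <- rnorm_trunc(n_orig, cfg$insert_mean, cfg$insert_sd, lo = 2L * r)
    tlen <- pmin(tlen, lens[sq])
    start <- floor(runif(n_orig) * (lens[sq] - tlen + 1))  # 0-based
    hap <- sample(1:2, n_orig, replace = TRUE)
    if (n_dup > 0L) {
      src <- sample.int(n_orig, n_dup, replace = TRUE)
      sq <- c(sq, sq[src]); tlen <- c(tlen, tlen[src])
      start <- c(start, start[src]); hap <- c(hap, hap[src])
      dup <- c(rep(FALSE, n_orig), rep(TRUE, n_dup))
    } else dup <- rep(FALSE, n_orig)
    n <- length(sq)
    hs <- ifelse(hap == 1L, hap1[sq], hap2[sq])
    seq1 <- substr(hs, start + 1L, start + r)
    seq2 <- revcomp(substr(hs, start + tlen - r + 1L, start + tlen))
    # sequencing errors: uniform different base at error_rate; only reads
    # that draw at least one error are rebuilt
    add_errors <- function(s) {
      if (cfg$error_rate <= 0) return(s)
      n_err <- rbinom(length(s), r, cfg$error_rate)
      hit <- which(n_err > 0L)
      if (length(hit) == 0L) return(s)
      m <- codes_matrix(s[hit], r)
      err <- matrix(FALSE, nrow = r, ncol = length(hit))
      err[cbind(unlist(lapply(n_err[hit], sample.int, n = r)), rep(seq_along(hit), n_err[hit]))] <- TRUE
      shift <- sample(1:3, sum(err), replace = TRUE)
      m[err] <- (m[err] + shift) %% 4L
      b <- matrix(.dna_bases[m + 1L], nrow = r)
      s[hit] <- do.call(paste0, lapply(seq_len(r), function(i) b[i, ]))
      s
    }
    seq1 <- add_errors(seq1); seq2 <- add_errors(seq2)
    qv <- if (length(cfg$base_q) == r) cfg$base_q else rep(cfg$base_q[1L], r)
    qual <- intToUtf8(qv + 33L)
    qname <- sprintf("sim%06d", seq_len(n))
    list(reads = data.table::data.table(qname = qname, seq1 = seq1,
                                        qual1 = qual, seq2 = seq2, qual2 = qual),
         truth = data.table::data.table(qname = qname,
                                        seq_name = names(genome)[sq],
                                        frag_start = as.integer(start),
                                        insert = as.integer(tlen),
                                        hap = hap, dup = dup))
  })
}

#' Mix reads from two samples in silico
#'
#' Each pair is drawn from sample B with probability `alpha`, else from
#' sample A; pair order and total count follow A. The realized fraction is
#' recorded as the ground truth.
#'
#' @param readsA,readsB read tables from [simulate_reads()] (`$reads`).
#' @param alpha contamination fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return list `reads` (mixed table, read names re-issued), `alpha_true`
#'   (realized fraction), `from_b` (logical).
#' @export
mix_contamination <- function(readsA, readsB, alpha, seed) {
  stopifnot(alpha >= 0, alpha <= 1)
  n <- nrow(readsA)
  withr::with_seed(seed, {
    from_b <- runif(n) < alpha
    idx_b <- if (any(from_b)) sample.int(nrow(readsB), sum(from_b), replace = TRUE)
             else integer(0)
    out <- data.table::copy(readsA)
    if (any(from_b)) {
      bb <- readsB[idx_b]
      for (col in c("seq1", "qual1", "seq2", "qual2")) {
        data.table::set(out, i = which(from_b), j = col, value = bb[[col]])
      }
    }
    out[, qname := sprintf("mix%06d", .I)]
    list(reads = out[], alpha_true = mean(from_b), from_b = from_b)
  })
}

#' Truncated-normal fragment lengths
#'
#' Inverse-CDF sampling of `round(X)` with `X ~ Normal(mu, sd)` conditioned
#' on `X >= lo` (a true truncation, not a clamp — no point mass at the
#' boundary). The matching CDF of the rounded variable is
#' [trunc_normal_cdf()].
#'
#' @param n sample count.
#' @param mu,sd normal parameters.
#' @param lo lower truncation bound.
#' @return integer vector.
#' @export
rnorm_trunc <- function(n, mu, sd, lo) {
  p0 <- pnorm(lo, mu, sd)
  as.integer(round(qnorm(p0 + runif(n) * (1 - p0), mu, sd)))
}

#' @rdname rnorm_trunc
#' @param t evaluation points.
#' @return `trunc_normal_cdf`: vectorized CDF function values
#'   `P(round(X) <= t | X >= lo)`.
#' @export
trunc_normal_cdf <- function(t, mu, sd, lo) {
  p0 <- pnorm(lo, mu, sd)
  clamp((pnorm(t + 0.5, mu, sd) - p0) / (1 - p0), 0, 1)
}

#' Simulate insert-size tuples around a single contig
#'
#' Pure geometry test bed for the censoring-corrected insert-size estimator:
#' fragments of length `T ~ round(Normal(mu, sd) | T >= 2r)` fall with
#' uniformly distributed start across a neighbourhood of a contig of length
#' `L`; a mate maps only when it lies fully inside the contig. Pairs with
#' both mates inside are fully observed (`t_o = T`); pairs with exactly one
#' mate inside are censored at that mate's maximal insert size; pairs with
#' neither mate inside are never seen (as in the real pipeline).
#'
#' @param n_pairs number of observed tuples to return.
#' @param contig_len contig length L (vector allowed: sampled uniformly).
#' @param read_len read length r.
#' @param insert_mean,insert_sd fragment-length law.
#' @param seed integer seed.
#' @return data.table of tuples (`t_o`, `t_l`, `t_r`).
#' @export
simulate_insert_tuples <- function(n_pairs, contig_len = 501L, read_len = 150L,
                                   insert_mean = 350, insert_sd = 50, seed = 1L) {
  r <- read_len
  withr::with_seed(seed, {
    acc <- list(); got <- 0L; i <- 0L
    while (got < n_pairs && i < 50L) {
      i <- i + 1L
      n <- max(2L * (n_pairs - got), 1000L)
      L <- contig_len[sample.int(length(contig_len), n, replace = TRUE)]
      Tl <- rnorm_trunc(n, insert_mean, insert_sd, lo = 2L * r)
      s <- floor(runif(n, -(insert_mean + 6 * insert_sd), max(L)))
      m1 <- s >= 0L & s + r <= L
      m2 <- s + Tl - r >= 0L & s + Tl <= L
      keep <- m1 | m2
      acc[[i]] <- data.table::data.table(
        t_o = ifelse(m1 & m2, Tl, NA_integer_),
        t_l = ifelse(m1, L - s, NA_integer_),
        t_r = ifelse(m2, s + Tl, NA_integer_))[keep]
      got <- got + sum(keep)
    }
    head(data.table::rbindlist(acc), n_pairs)
  })
}

#' Simulate marker pileups from a contaminated sample
#'
#' Site-level test bed for the contamination/ancestry estimator: genotypes
#' for the intended sample (ancestry `pc`) and a contaminant (`pc2`) are
#' drawn from the panel's individual-specific allele frequencies; each
#' marker receives `Poisson(depth)` reads, each read coming from the
#' contaminant with probability `alpha`; the read's base is a random allele
#' of the source genotype, miscalled to a uniform different base with the
#' error rate implied by `base_q`.
#'
#' @param panel an `SvdPanel`.
#' @param alpha contamination fraction.
#' @param pc,pc2 ancestry coordinates of sample and contaminant (default:
#'   same as `pc`).
#' @param depth mean site depth.
#' @param base_q reported base quality.
#' @param seed integer seed.
#' @return a `PileupSites` aligned to the panel markers (ref/alt taken from
#'   the panel), with truth attributes `alpha`, `pc`, `pc2`.
#' @export
simulate_pileup <- function(panel, alpha, pc, pc2 = pc, depth = 8, base_q = 30L,
                            seed = 1L) {
  m <- panel$markers
  n <- nrow(m)
  e <- phred_to_error(base_q)
  withr::with_seed(seed, {
    g1 <- rbinom(n, 2L, site_af(pc, panel))
    g2 <- rbinom(n, 2L, site_af(pc2, panel))
    dp <- stats::rpois(n, depth)
    site <- rep(seq_len(n), dp)
    from_b <- runif(length(site)) < alpha
    g <- ifelse(from_b, g2[site], g1[site])
    alt_hap <- runif(length(site)) < g / 2
    bclass <- ifelse(alt_hap, 1L, 0L)
    err <- runif(length(site)) < e
    if (any(err)) {
      # uniform different base: 1/3 lands on the other allele, 2/3 elsewhere
      u <- runif(sum(err))
      cur <- bclass[err]
      bclass[err] <- ifelse(u < 1 / 3, 1L - cur, 2L)
    }
    calls <- data.table::data.table(site = site,
                                    base = NA_character_,
                                    qual = as.integer(base_q), bclass = bclass)
    agg <- calls[, .(n_ref = sum(bclass == 0L), n_alt = sum(bclass == 1L),
                     n_other = sum(bclass == 2L)), by = site]
    sites <- data.table::data.table(site = seq_len(n),
                                    name = sprintf("%s:%d:%s:%s", m$chrom, m$pos, m$ref, m$alt),
                                    chrom = m$chrom, pos = m$pos, ref = m$ref,
                                    alt = m$alt, af = m$mu / 2,
                                    n_ref = 0L, n_alt = 0L, n_other = 0L)
    if (nrow(agg)) {
      sites$n_ref[agg$site] <- agg$n_ref
      sites$n_alt[agg$site] <- agg$n_alt
      sites$n_other[agg$site] <- agg$n_other
    }
    sites[, depth := n_ref + n_alt + n_other]
    structure(list(calls = calls[], sites = sites[]), class = "PileupSites",
              alpha = alpha, pc = pc, pc2 = pc2, g1 = g1, g2 = g2)
  })
}
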