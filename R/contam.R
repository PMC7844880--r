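# Likelihood-based joint estimation of DNA contamination fraction and
# genetic ancestry from marker pileups against an SVD allele-frequency panel
# (per-marker mean alternate-allele dosage plus principal-component
# loadings). The individual-specific allele frequency of a sample at
# ancestry coordinates pc is f_i = (mu_i + sum_k L_ik pc_k) / 2; the read
# data at each site are modelled as a two-genotype mixture: a fraction
# (1 - alpha) of reads from the intended sample and alpha from a contaminant.

#' Construct / read / write an SVD allele-frequency panel
#'
#' An `SvdPanel` couples per-marker mean dosage and PC loadings with
#' reference-sample ancestry coordinates (for population assignment). On
#' disk: `prefix.panel.tsv` (chrom, pos, ref, alt, mu, L_1..L_K) and
#' `prefix.coords.tsv` (sample, pop, pc_1..pc_K).
#'
#' @param markers data.table with `chrom`, `pos`, `ref`, `alt`, `mu` and
#'   loading columns `L1..LK`.
#' @param refcoords data.table with `sample`, `pop` and `pc1..pcK`.
#' @return an `SvdPanel` (list `markers`, `refcoords`, `K`).
#' @export
svd_panel <- function(markers, refcoords) {
  m <- data.table::as.data.table(markers)
  rc <- data.table::as.data.table(refcoords)
  K <- sum(grepl("^L[0-9]+$", names(m)))
  stopifnot(K >= 1L, all(paste0("pc", seq_len(K)) %in% names(rc)),
            all(m$mu >= 0 & m$mu <= 2))
  structure(list(markers = m, refcoords = rc, K = K), class = "SvdPanel")
}

#' @rdname svd_panel
#' @param panel an `SvdPanel`.
#' @param prefix file prefix.
#' @export
write_svd_panel <- function(panel, prefix) {
  data.table::fwrite(panel$markers, paste0(prefix, ".panel.tsv"), sep = "\t")
  data.table::fwrite(panel$refcoords, paste0(prefix, ".coords.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname svd_panel
#' @export
read_svd_panel <- function(prefix) {
  svd_panel(data.table::fread(paste0(prefix, ".panel.tsv")),
            data.table::fread(paste0(prefix, ".coords.tsv")))
}

#' Individual-specific allele frequencies at ancestry coordinates
#'
#' `f_i = clamp((mu_i + sum_k L_ik pc_k) / 2, 1e-4, 1 - 1e-4)`.
#'
#' @param pc numeric ancestry coordinate vector (length `panel$K`).
#' @param panel an `SvdPanel`.
#' @param sites optional integer subset of marker rows.
#' @return numeric vector of allele frequencies in (0, 1).
#' @export
site_af <- function(pc, panel, sites = NULL) {
  m <- panel$markers
  if (!is.null(sites)) m <- m[sites]
  L <- as.matrix(m[, paste0("L", seq_len(panel$K)), with = FALSE])
  clamp((m$mu + as.vector(L %*% pc)) / 2, 1e-4, 1 - 1e-4)
}

# Precompute the per-(site, genotype-pair) read-likelihood products once per
# pileup: they do not depend on (alpha, pc). Returns list(site_ids, pb list
# of per-base P(b|g) vectors, site index of each base, n_sites).
.contam_prep <- function(pile, panel) {
  ps <- pile$sites
  key_p <- paste(panel$markers$chrom, panel$markers$pos,
                 panel$markers$ref, panel$markers$alt)
  key_s <- paste(ps$chrom, ps$pos, ps$ref, ps$alt)
  idx <- match(key_s, key_p)           # panel row per pileup site
  use <- which(!is.na(idx))
  if (length(use) == 0L) stop("no pileup sites overlap the SVD panel")
  use_sites <- ps$site[use]
  calls <- pile$calls[site %in% use_sites]
  site_slot <- match(calls$site, use_sites)  # 1..n_used per base
  e <- phred_to_error(calls$qual)
  pref <- ifelse(calls$bclass == 0L, 1 - e, e / 3)
  palt <- ifelse(calls$bclass == 1L, 1 - e, e / 3)
  list(panel_rows = idx[use], n_sites = length(use), site_slot = site_slot,
       pb = list(pref, 0.5 * (pref + palt), palt))
}

#' Mixture log-likelihood of pileup data
#'
#' `loglik = sum_i log sum_{g1,g2} HWE(g1 | f_i(pc)) HWE(g2 | f_i(pc2))
#' prod_b [(1 - alpha) P(b|g1) + alpha P(b|g2)]` with the same per-base error
#' model as the genotype likelihoods. At `alpha = 0` the contaminant
#' genotype marginalizes out and the likelihood reduces to the single-sample
#' genotype mixture; swapping `(alpha, pc, pc2)` for `(1 - alpha, pc2, pc)`
#' leaves it unchanged.
#'
#' @param pile a `PileupSites`.
#' @param alpha contamination fraction in `[0, 1]`.
#' @param pc ancestry coordinates of the intended sample.
#' @param pc2 ancestry coordinates of the contaminant (default `pc`).
#' @param panel an `SvdPanel`.
#' @param prep optional precomputed structure (internal, for the optimizer).
#' @return scalar log-likelihood (natural log).
#' @export
mixture_loglik <- function(pile, alpha, pc, pc2 = pc, panel, prep = NULL) {
  if (is.null(prep)) prep <- .contam_prep(pile, panel)
  f1 <- site_af(pc, panel, prep$panel_rows)
  f2 <- site_af(pc2, panel, prep$panel_rows)
  hwe <- function(f) cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  h1 <- hwe(f1); h2 <- hwe(f2)
  ns <- prep$n_sites
  # per-site log sum over 9 genotype pairs, log-sum-exp stabilized
  lp <- matrix(-Inf, nrow = ns, ncol = 9L)
  w <- matrix(0, nrow = ns, ncol = 9L)
  k <- 0L
  for (g1 in 1:3) {
    for (g2 in 1:3) {
      k <- k + 1L
      w[, k] <- h1[, g1] * h2[, g2]
      mix <- (1 - alpha) * prep$pb[[g1]] + alpha * prep$pb[[g2]]
      lp_k <- rep(0, ns)
      if (length(mix)) {
        s <- rowsum(log(mix), group = prep$site_slot)
        lp_k[as.integer(rownames(s))] <- s
      }
      lp[, k] <- lp_k
    }
  }
  mx <- apply(lp, 1L, max)
  sum(mx + log(rowSums(w * exp(lp - mx))))
}

#' Estimate contamination fraction and ancestry
#'
#' Maximizes [mixture_loglik()] over `(alpha, pc[, pc2])`: a coarse grid over
#' alpha in `{0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5}` crossed with
#' candidate pc points (reference-sample population centroids plus the
#' origin), followed by derivative-free local refinement (Nelder-Mead on a
#' logit-bounded alpha and free pc) from the best grid point. With
#' `share_pc = TRUE` (default) the contaminant shares the sample's ancestry
#' coordinates — better identified at low depth; alpha is capped at 0.5, the
#' label-swap symmetry point.
#'
#' @param pile a `PileupSites`.
#' @param panel an `SvdPanel`.
#' @param share_pc single ancestry for sample and contaminant (default TRUE).
#' @param alpha_grid coarse alpha grid.
#' @return a `ContamEstimate`: list `alpha`, `pc`, `pc2`, `loglik`,
#'   `n_sites`, `converged`, `low_sites` (TRUE when under 100 usable sites),
#'   `population` (nearest reference centroid), `pop_distances`.
#' @export
estimate_contamination <- function(pile, panel, share_pc = TRUE,
                                   alpha_grid = c(0, 0.005, 0.01, 0.02, 0.05,
                                                  0.1, 0.2, 0.35, 0.5)) {
  prep <- .contam_prep(pile, panel)
  low_sites <- prep$n_sites < 100L
  if (low_sites) warning("fewer than 100 usable sites; contamination estimate is unreliable")
  K <- panel$K
  cent <- panel$refcoords[, lapply(.SD, mean), by = pop,
                          .SDcols = paste0("pc", seq_len(K))]
  pc_cands <- rbind(as.matrix(cent[, -1L]), matrix(0, nrow = 1L, ncol = K))
  best <- list(val = -Inf)
  for (a in alpha_grid) {
    for (i in seq_len(nrow(pc_cands))) {
      v <- mixture_loglik(pile, a, pc_cands[i, ], pc_cands[i, ], panel, prep = prep)
      if (v > best$val) best <- list(val = v, alpha = a, pc = pc_cands[i, ])
    }
  }
  # local refinement; alpha through a logit map bounded to [0, 0.5]
  to_alpha <- function(x) 0.5 / (1 + exp(-x))
  from_alpha <- function(a) -log(0.5 / max(a, 1e-6) - 1 + 1e-12)
  obj <- function(par) {
    a <- to_alpha(par[1L])
    pc1 <- par[1L + seq_len(K)]
    pc2 <- if (share_pc) pc1 else par[1L + K + seq_len(K)]
    -mixture_loglik(pile, a, pc1, pc2, panel, prep = prep)
  }
  par0 <- c(from_alpha(max(best$alpha, 1e-4)), best$pc,
            if (!share_pc) best$pc)
  opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                      control = list(maxit = 800L, reltol = 1e-10))
  alpha <- unname(to_alpha(opt$par[1L]))
  pc <- unname(opt$par[1L + seq_len(K)])
  pc2 <- if (share_pc) pc else opt$par[1L + K + seq_len(K)]
  anc <- assign_ancestry(pc, panel)
  structure(list(alpha = alpha, pc = pc, pc2 = pc2, loglik = -opt$value,
                 n_sites = prep$n_sites, converged = opt$convergence == 0L,
                 low_sites = low_sites,
                 population = anc$population, pop_distances = anc$distances),
            class = "ContamEstimate")
}

#' @export
print.ContamEstimate <- function(x, ...) {
  cat(sprintf("ContamEstimate: alpha = %.4f, pc = (%s), population = %s, %d sites%s\n",
              x$alpha, paste(sprintf("%.3f", x$pc), collapse = ", "),
              x$population, x$n_sites,
              if (x$low_sites) " [LOW SITE COUNT]" else ""))
  invisible(x)
}

#' Assign ancestry by nearest population centroid
#'
#' Euclidean distance in PC space to each reference population centroid;
#' ties break alphabetically and are flagged.
#'
#' @param pc ancestry coordinate vector.
#' @param panel an `SvdPanel` with labelled reference coordinates.
#' @return list `population`, `distances` (named, sorted), `tie`.
#' @export
assign_ancestry <- function(pc, panel) {
  rc <- panel$refcoords
  if (nrow(rc) == 0L || !"pop" %in% names(rc)) stop("panel has no labelled reference coordinates")
  K <- panel$K
  cent <- rc[, lapply(.SD, mean), by = pop, .SDcols = paste0("pc", seq_len(K))]
  d <- sqrt(rowSums((as.matrix(cent[, -1L]) -
                       matrix(pc, nrow = nrow(cent), ncol = K, byrow = TRUE))^2))
  names(d) <- cent$pop
  d <- d[order(d, names(d))]
  tie <- length(d) > 1L && isTRUE(all.equal(d[[1L]], d[[2L]]))
  list(population = names(d)[1L], distances = d, tie = tie)
}
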