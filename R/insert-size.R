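# Censoring-corrected insert-size estimation.
#
# On a reduced reference, pairs with large inserts are preferentially lost:
# the mate falling off the contig leaves a single-end-mapped pair whose
# maximal insert size only bounds the fragment length from below. Treating
# observed inserts as events and maximal inserts of single-end-mapped pairs
# as right-censoring times turns the insert-size CDF into a survival problem
# solved by the Kaplan-Meier product-limit estimator.

#' Build insert-size tuples from read pairs
#'
#' For every retained pair this records the tuple `(t_o, t_l, t_r)`:
#' * proper pairs: `t_o` = observed outer distance; `t_l` = distance from the
#'   leftmost base of the left (forward) read to the rightmost base of its
#'   contig, i.e. `contig_len - start_left`; `t_r` = distance from the
#'   rightmost base of the right (reverse) read to the leftmost base of the
#'   contig, i.e. `end_right`.
#' * single-end-mapped pairs: `t_o` missing; the mapped mate contributes its
#'   maximal insert size (`t_l` if it is forward-strand, `t_r` if reverse)
#'   and the other entry is missing.
#' Improper pairs (different contigs, abnormal orientation, low mapping
#' quality) are discarded.
#'
#' @param pairs pairs table from [pair_and_flag()].
#' @param ref `ReducedReference` (for contig lengths).
#' @param mapq_min minimum mapping quality for a single-end-mapped mate to
#'   contribute a censoring time (default 20).
#' @return data.table with columns `t_o`, `t_l`, `t_r` (NA where missing).
#' @export
build_tuples <- function(pairs, ref, mapq_min = 20L) {
  p <- data.table::as.data.table(pairs)
  clen <- ref$contigs$len
  out <- vector("list", 2L)
  # fully observed (proper) pairs
  pr <- p[proper == TRUE]
  if (nrow(pr)) {
    out[[1L]] <- data.table::data.table(
      t_o = pr$end_r - pr$start_l,
      t_l = clen[pr$contig1] - pr$start_l,
      t_r = pr$end_r)
  }
  # single-end mapped pairs: exactly one mate mapped confidently; pairs with
  # both mates mapped but improper (different contig / orientation / low
  # mapq) are discarded outright
  conf1 <- p$mapped1 & !is.na(p$mapq1) & p$mapq1 >= mapq_min
  conf2 <- p$mapped2 & !is.na(p$mapq2) & p$mapq2 >= mapq_min
  se <- p[conf1 + conf2 == 1L & !(p$mapped1 & p$mapped2)]
  if (nrow(se)) {
    m1 <- se$mapped1 & !is.na(se$mapq1) & se$mapq1 >= mapq_min
    contig <- ifelse(m1, se$contig1, se$contig2)
    strand <- ifelse(m1, se$strand1, se$strand2)
    start <- ifelse(m1, se$start1, se$start2)
    end <- ifelse(m1, se$end1, se$end2)
    fwd <- strand == "+"
    out[[2L]] <- data.table::data.table(
      t_o = NA_integer_,
      t_l = ifelse(fwd, clen[contig] - start, NA_integer_),
      t_r = ifelse(fwd, NA_integer_, end))
  }
  tu <- data.table::rbindlist(out, use.names = TRUE)
  if (nrow(tu) == 0L) {
    tu <- data.table::data.table(t_o = integer(0), t_l = integer(0), t_r = integer(0))
  }
  tu[]
}


# Expand tuples into Kaplan-Meier risk units. Each flanking-sequence anchor
# (a non-missing t_l or t_r) is one start point: for a fully observed pair
# both anchors saw the event (two event units, each with an independently
# uniform censoring bound); a single-end-mapped pair is one unit censored at
# its bound. A bare event with no recorded bounds counts once. Counting a
# fully observed pair as a single unit instead makes the estimator
# inconsistent under the pipeline geometry, because the probability that a
# pair is fully observed falls with the insert size while the probability it
# is censored rises, violating independent censoring at the pair level;
# anchor-level units satisfy it exactly (the anchor position is uniform and
# independent of the fragment length).
.km_units <- function(tuples) {
  obs <- !is.na(tuples$t_o)
  n_anchor <- (!is.na(tuples$t_l)) + (!is.na(tuples$t_r))
  events <- rep(tuples$t_o[obs], pmax(n_anchor[obs], 1L))
  cs <- ifelse(is.na(tuples$t_l), tuples$t_r, tuples$t_l)
  censors <- cs[!obs & !is.na(cs)]
  list(events = as.numeric(events), censors = as.numeric(censors))
}

#' Kaplan-Meier estimate of the insert-size distribution
#'
#' Product-limit estimator over insert-size tuples. Each flanking-sequence
#' anchor of a tuple is one risk unit: observed inserts `t_o` are events
#' (a fully observed pair has two anchors, hence enters twice; an abstract
#' event without recorded bounds enters once), and the maximal insert size
#' of each single-end-mapped pair is a right-censoring time. With event
#' times `tau_j`, event counts `o_j`,
#' censor counts `c_j` and risk set `Y(t) = sum_j (o_j + c_j) I[tau_j >= t]`,
#' the survival estimate is `S(t) = prod_{tau_j <= t} (1 - o_j / Y(tau_j))`
#' and the CDF is `F = 1 - S`. At tied times events precede censorings. With
#' zero censoring the estimate equals the empirical CDF exactly. If the
#' largest time is censored the CDF is defective (`S(max) > 0`); summary
#' statistics renormalize it and the curve is flagged.
#'
#' @param tuples data.table from [build_tuples()].
#' @return a `KmCurve`: data.table `tau`, `o`, `c`, `Y`, `S`, `F` over event
#'   times, with attributes `n` (tuples used), `defective`, `S_inf`.
#' @export
km_estimate <- function(tuples) {
  u <- .km_units(tuples)
  ev <- u$events; cs <- u$censors
  if (length(ev) == 0L) stop("no properly paired reads: cannot estimate insert size")
  n <- length(ev) + length(cs)
  tau <- sort(unique(ev))
  o <- as.integer(table(factor(ev, levels = tau)))
  c_at <- as.integer(table(factor(cs[cs %in% tau], levels = tau)))
  all_times <- c(ev, cs)
  # Y(t) = number of tuples with time >= t (events tied at t are at risk;
  # censorings tied at t are at risk too, removed after the event)
  Y <- vapply(tau, function(t) sum(all_times >= t), numeric(1))
  S <- cumprod(1 - o / Y)
  curve <- data.table::data.table(tau = tau, o = o, c = c_at, Y = Y, S = S, F = 1 - S)
  max_cens <- if (length(cs)) max(cs) else -Inf
  defective <- max_cens > max(ev)
  structure(curve[], class = c("KmCurve", class(curve)),
            n = n, defective = defective, S_inf = S[length(S)])
}

#' Naive (uncorrected) insert-size CDF
#'
#' Empirical CDF over fully observed tuples only — the biased estimator the
#' KM correction is compared against.
#'
#' @param tuples data.table from [build_tuples()].
#' @return data.table `tau`, `F` (step CDF), attribute `n`.
#' @export
naive_estimate <- function(tuples) {
  ev <- tuples$t_o[!is.na(tuples$t_o)]
  if (length(ev) == 0L) stop("no properly paired reads: cannot estimate insert size")
  tau <- sort(unique(ev))
  F <- cumsum(as.integer(table(factor(ev, levels = tau)))) / length(ev)
  structure(data.table::data.table(tau = tau, F = F), n = length(ev))
}

#' Inverse-probability-of-censoring cross-check of the KM curve
#'
#' The product-limit estimator can be rewritten as an IPCW average:
#' `F(t) = (1/n) sum_i I[event i, T_i <= t] / G(T_i-)` where `G` is the
#' Kaplan-Meier estimate of the censoring survival (roles of events and
#' censorings swapped, censorings removed after events at ties). This path
#' is algebraically identical to [km_estimate()] and is used as an internal
#' consistency check.
#'
#' @param tuples data.table from [build_tuples()].
#' @return data.table `tau`, `F` over event times.
#' @export
ipcw_estimate <- function(tuples) {
  u <- .km_units(tuples)
  ev <- u$events; cs <- u$censors
  if (length(ev) == 0L) stop("no properly paired reads")
  n <- length(ev) + length(cs)
  # censoring KM: G(t) = prod_{c_j <= t} (1 - cnum_j / Yg(c_j)) where the
  # risk set removes events *before* censorings at tied times
  ctau <- sort(unique(cs))
  if (length(ctau)) {
    cnum <- as.integer(table(factor(cs, levels = ctau)))
    Yg <- vapply(ctau, function(t) sum(ev > t) + sum(cs >= t), numeric(1))
    G <- cumprod(1 - cnum / Yg)
    G_at <- stats::stepfun(ctau, c(1, G), right = TRUE)
  } else {
    G_at <- function(t) rep(1, length(t))
  }
  tau <- sort(unique(ev))
  w <- 1 / G_at(ev - 1e-9)   # G at T_i minus
  F <- vapply(tau, function(t) sum(w[ev <= t]) / n, numeric(1))
  data.table::data.table(tau = tau, F = F)
}

# Evaluate a CDF representation at points x: KmCurve / naive table (step,
# right-continuous) or a function.
.cdf_eval <- function(F, x) {
  if (is.function(F)) return(F(x))
  dt <- data.table::as.data.table(F)
  sf <- stats::stepfun(dt$tau, c(0, dt$F), right = FALSE)
  sf(x)
}

.cdf_knots <- function(F) {
  if (is.function(F)) return(numeric(0))
  data.table::as.data.table(F)$tau
}

#' Distance between two insert-size CDFs
#'
#' Kolmogorov-Smirnov statistic `D = sup_t |F1(t) - F2(t)|` and the
#' Wasserstein-1 distance `W = integral |F1 - F2| dt`, computed on the pooled
#' knot grid (augmented with a dense grid when either argument is a
#' continuous function). Before integrating, the time axis is normalized to
#' `[0, 1]` by the largest grid value, so `W` is scale-free.
#'
#' @param F1,F2 step CDFs (`KmCurve` or a data.table with `tau`,`F`) or
#'   vectorized CDF functions (at least one must supply knots).
#' @param grid_n dense-grid size added when a functional CDF is involved.
#' @return named numeric vector `c(ks_D = , wasserstein_W = )`.
#' @export
distribution_distance <- function(F1, F2, grid_n = 4096L) {
  knots <- sort(unique(c(.cdf_knots(F1), .cdf_knots(F2))))
  if (length(knots) == 0L) stop("at least one CDF must supply a step grid")
  if (is.function(F1) || is.function(F2)) {
    knots <- sort(unique(c(knots, seq(0, max(knots), length.out = grid_n))))
  }
  tmax <- max(knots)
  grid <- sort(unique(c(0, knots)))
  f1 <- .cdf_eval(F1, grid); f2 <- .cdf_eval(F2, grid)
  # also check left limits at knots for the sup (step functions jump there)
  eps <- min(diff(grid)[diff(grid) > 0]) / 2
  f1m <- .cdf_eval(F1, grid - eps); f2m <- .cdf_eval(F2, grid - eps)
  D <- max(abs(f1 - f2), abs(f1m - f2m))
  # exact integral of |F1-F2| over the step grid, normalized time axis
  dx <- diff(c(grid, tmax)) / tmax
  W <- sum(abs(f1 - f2) * dx)
  c(ks_D = D, wasserstein_W = W)
}

#' Summary statistics from an insert-size CDF
#'
#' Median, mode (largest event mass), and 5/95 percentiles read off the step
#' CDF with linear interpolation between grid steps. Defective KM curves
#' (largest time censored) are renormalized first.
#'
#' @param curve a `KmCurve` or naive CDF table.
#' @return list with `median`, `mode`, `q05`, `q95`, `defective`.
#' @export
insert_size_summary <- function(curve) {
  dt <- data.table::as.data.table(curve)
  F <- dt$F
  defective <- isTRUE(attr(curve, "defective"))
  if (max(F) < 1) F <- F / max(F)
  qtl <- function(p) {
    i <- which(F >= p)[1L]
    if (is.na(i)) return(dt$tau[nrow(dt)])
    if (i == 1L) return(dt$tau[1L])
    f0 <- F[i - 1L]; f1 <- F[i]
    dt$tau[i - 1L] + (dt$tau[i] - dt$tau[i - 1L]) * (p - f0) / (f1 - f0)
  }
  mass <- diff(c(0, F))
  list(median = qtl(0.5), mode = dt$tau[which.max(mass)],
       q05 = qtl(0.05), q95 = qtl(0.95), defective = defective)
}

#' Write a KM curve as TSV
#'
#' @param curve a `KmCurve`.
#' @param path output path.
#' @export
write_km_curve <- function(curve, path) {
  data.table::fwrite(data.table::as.data.table(curve), path, sep = "\t")
  invisible(path)
}
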