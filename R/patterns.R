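# Spaced 16-of-32 pattern design and its worst-case mismatch guarantees.
#
# Each 32-mer window is split into four contiguous 8-base blocks; the six
# patterns are the six unordered pairs of blocks. Every position lies in
# exactly 3 patterns, and for any two positions at least one pattern avoids
# both (the two positions occupy at most two blocks; the pattern formed by
# the other two blocks is untouched). That pair-exclusion property is what
# guarantees a 32-mer with <= 2 mismatches still matches >= 1 table.

#' Build the six spaced 16-of-32 probe patterns
#'
#' Partitions positions 0..31 into four contiguous blocks of 8 and returns
#' the six patterns formed by the union of each pair of blocks. Each pattern
#' selects 16 of 32 positions; every position appears in exactly 3 patterns;
#' and for every pair of positions some pattern contains neither, so a 32-mer
#' carrying at most two mismatches always leaves at least one pattern intact.
#'
#' @return list of 6 integer vectors, each 16 sorted 0-based positions in
#'   `[0, 32)`.
#' @export
#' @examples
#' p <- build_patterns()
#' lengths(p)                       # all 16
#' table(unlist(p))                 # every position covered 3 times
build_patterns <- function() {
  blocks <- split(0:31, rep(1:4, each = 8L))
  pairs <- utils::combn(4L, 2L)
  lapply(seq_len(ncol(pairs)), function(i) {
    as.integer(sort(c(blocks[[pairs[1L, i]]], blocks[[pairs[2L, i]]])))
  })
}

#' Probe hits for an explicit set of mismatch positions
#'
#' Brute-force evaluator: given mismatch positions within the first 96 bases
#' of a read otherwise identical to an indexed sequence, count how many of
#' the 18 probes (6 patterns x 3 windows at offsets 0/32/64) still match
#' exactly. A probe survives iff none of its selected positions carries a
#' mismatch. Used as the position-level oracle for
#' [worst_case_min_hits()].
#'
#' @param positions integer vector of 0-based mismatch positions in `[0, 96)`.
#' @param patterns pattern list, by default [build_patterns()].
#' @param n_windows number of 32-mer windows (default 3).
#' @return integer number of surviving probes, in `[0, 6 * n_windows]`.
#' @export
hits_for_mismatch_positions <- function(positions, patterns = build_patterns(),
                                        n_windows = 3L) {
  stopifnot(all(positions >= 0), all(positions < 32L * n_windows))
  hits <- 0L
  for (w in seq_len(n_windows) - 1L) {
    in_win <- positions[positions >= 32L * w & positions < 32L * (w + 1L)] - 32L * w
    for (pat in patterns) {
      if (!any(in_win %in% pat)) hits <- hits + 1L
    }
  }
  hits
}

#' Worst-case probe hits under m adversarial mismatches
#'
#' Exact minimum, over all placements of `m` mismatch positions in the first
#' `32 * n_windows` bases of a read otherwise identical to an indexed
#' sequence, of the number of surviving spaced-hash probes. Because a probe
#' dies as soon as any one of its positions is hit, the hit count depends
#' only on which 8-base blocks contain at least one mismatch, so the search
#' enumerates block-occupancy classes (all subsets of the `4 * n_windows`
#' blocks that m mismatches can exactly occupy) rather than raw positions;
#' equivalence with position-level brute force is asserted in the test
#' suite at small m.
#'
#' With the default design and threshold 3 the minimum m that can defeat the
#' screen is 7 (reads with fewer than 7 mismatches always pass); with
#' threshold 10 it is 3.
#'
#' @param m number of mismatches (>= 0).
#' @param n_windows number of 32-mer windows screened (default 3).
#' @param patterns pattern list, by default [build_patterns()].
#' @return integer: the minimum possible hit count.
#' @export
#' @examples
#' worst_case_min_hits(0)  # 18
#' worst_case_min_hits(2)  # 12
#' worst_case_min_hits(6)  # 3
#' worst_case_min_hits(7)  # 2
worst_case_min_hits <- function(m, n_windows = 3L, patterns = build_patterns()) {
  stopifnot(length(m) == 1L, m >= 0)
  m <- as.integer(m)
  block_size <- 8L
  blocks_per_win <- 4L
  n_blocks <- blocks_per_win * n_windows
  # blocks touched by each pattern (0-based block ids within a window)
  pat_blocks <- lapply(patterns, function(p) unique(p %/% block_size))
  best <- length(patterns) * n_windows
  if (m == 0L) return(as.integer(best))
  bit_weights <- 2^(seq_len(n_blocks) - 1L)
  for (occ in seq_len(2^n_blocks - 1L)) {
    occupied <- bitwAnd(occ, bit_weights) > 0
    k <- sum(occupied)
    # m mismatches can occupy exactly these blocks iff k <= m <= 8k
    if (k > m || m > k * block_size) next
    hits <- 0L
    for (w in seq_len(n_windows)) {
      occ_ids <- which(occupied[(w - 1L) * blocks_per_win + seq_len(blocks_per_win)]) - 1L
      for (pb in pat_blocks) {
        if (!any(pb %in% occ_ids)) hits <- hits + 1L
      }
    }
    if (hits < best) best <- hits
  }
  as.integer(best)
}

#' Smallest mismatch count that can defeat the screen
#'
#' Returns the minimum `m` for which some placement of `m` mismatches drops
#' the worst-case probe hit count below `k_min`, by exhaustive enumeration
#' over `m = 0, 1, 2, ...`.
#'
#' @param k_min screening threshold (hits required to pass).
#' @param n_windows number of 32-mer windows (default 3).
#' @param m_max search bound (default 96, i.e. every base mismatched).
#' @return integer m, or NA if no m up to `m_max` defeats the screen.
#' @export
min_mismatches_to_defeat <- function(k_min, n_windows = 3L, m_max = 32L * n_windows) {
  for (m in 0:m_max) {
    if (worst_case_min_hits(m, n_windows = n_windows) < k_min) return(m)
  }
  NA_integer_
}

#' Minimum surviving tables for a single 32-mer with up to `m_max` mismatches
#'
#' Enumerates every placement of 0.. `m_max` mismatches within one 32-mer and
#' returns the minimum number of the six tables that still match exactly.
#' For the default design and `m_max = 2` the minimum is 1: any two
#' mismatches occupy at most two blocks, and the pattern built from the
#' remaining two blocks survives.
#'
#' @param m_max maximum mismatch count considered (default 2).
#' @param patterns pattern list.
#' @return integer minimum table count.
#' @export
min_tables_single_window <- function(m_max = 2L, patterns = build_patterns()) {
  best <- length(patterns)
  for (m in seq_len(m_max)) {
    placements <- utils::combn(32L, m)
    for (j in seq_len(ncol(placements))) {
      h <- hits_for_mismatch_positions(placements[, j] - 1L, patterns = patterns,
                                       n_windows = 1L)
      if (h < best) best <- h
    }
  }
  as.integer(best)
}
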