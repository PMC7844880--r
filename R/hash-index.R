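# Spaced k-mer hash index over the reduced reference, and batched screening
# of reads against it.
#
# Keys are exact packed 16-mers (2 bits/base, value < 4^16, held exactly in
# doubles); "hit" therefore means a true 16-mer occurrence under the pattern,
# not a lossy hash bucket. Only the forward strand is indexed; reads are
# probed in both orientations and the better orientation is kept.

.key_weights <- 4^(15:0)

#' Build the spaced k-mer hash index of a reduced reference
#'
#' For every contig, every 32-mer window starting at offsets `0, step,
#' 2*step, ...` and each of the six spaced patterns, records the packed
#' 16-mer key together with `(contig, window offset)`. Windows containing an
#' ambiguous base are skipped (their keys are undefined). The forward strand
#' only is indexed; [screen_reads()] and the aligner probe both read
#' orientations, which is equivalent to double-strand indexing at half the
#' memory.
#'
#' @param ref a `ReducedReference`.
#' @param step window stride in bases (default 1: every window).
#' @param patterns pattern list from [build_patterns()].
#' @return a `SpacedHashIndex`: list with `patterns`, per-pattern sorted
#'   location tables (`key`, `contig`, `offset`), per-pattern unique key
#'   vectors (for screening), `step`, and the contig names/lengths.
#' @export
index_reference <- function(ref, step = 1L, patterns = build_patterns()) {
  stopifnot(inherits(ref, "ReducedReference"), step >= 1L)
  contigs <- ref$contigs
  if (nrow(contigs) == 0L) stop("empty reference: no contigs to index")
  np <- length(patterns)
  acc <- replicate(np, vector("list", nrow(contigs)), simplify = FALSE)
  for (ci in seq_len(nrow(contigs))) {
    codes <- seq_codes(contigs$seq[ci])
    len <- length(codes)
    if (len < 32L) next
    ws <- seq.int(0L, len - 32L, by = step)
    for (p in seq_len(np)) {
      pos <- patterns[[p]]
      key <- numeric(length(ws))
      for (i in seq_len(16L)) key <- key + codes[ws + pos[i] + 1L] * .key_weights[i]
      keep <- !is.na(key)
      if (any(keep)) {
        acc[[p]][[ci]] <- list(key = key[keep], contig = rep(ci, sum(keep)),
                               offset = ws[keep])
      }
    }
  }
  tables <- lapply(acc, function(parts) {
    parts <- parts[!vapply(parts, is.null, logical(1))]
    key <- unlist(lapply(parts, `[[`, "key"), use.names = FALSE)
    contig <- unlist(lapply(parts, `[[`, "contig"), use.names = FALSE)
    offset <- unlist(lapply(parts, `[[`, "offset"), use.names = FALSE)
    o <- order(key)
    list(key = key[o], contig = as.integer(contig[o]), offset = as.integer(offset[o]))
  })
  ukeys <- lapply(tables, function(t) t$key[!duplicated(t$key)])
  structure(list(patterns = patterns, tables = tables, ukeys = ukeys,
                 step = as.integer(step),
                 contig_names = contigs$name, contig_len = contigs$len),
            class = "SpacedHashIndex")
}

#' @export
print.SpacedHashIndex <- function(x, ...) {
  cat(sprintf("SpacedHashIndex: %d contigs, %d patterns, %s windows indexed (step %d)\n",
              length(x$contig_names), length(x$patterns),
              format(length(x$tables[[1L]]$key), big.mark = ","), x$step))
  invisible(x)
}

#' Save / load a spaced hash index
#'
#' Runtime sidecar serialization of a `SpacedHashIndex` (RDS container with a
#' magic/version stamp).
#' @param index a `SpacedHashIndex`.
#' @param path file path (conventionally `prefix.shx`).
#' @export
write_hash_index <- function(index, path) {
  stopifnot(inherits(index, "SpacedHashIndex"))
  saveRDS(list(magic = "seqsentry-shx", version = 1L, index = index), path)
  invisible(path)
}

#' @rdname write_hash_index
#' @export
read_hash_index <- function(path) {
  if (!file.exists(path)) stop("hash index not found: ", path)
  x <- readRDS(path)
  if (!identical(x$magic, "seqsentry-shx")) stop("not a seqsentry hash index: ", path)
  x$index
}

#' Extract the spaced probe keys of one read
#'
#' Emits the probes used for screening: 6 keys (one per pattern) from each
#' complete non-overlapping 32-mer window within the first 96 bases — 18
#' probes for reads of 96 bp or longer, 12 or 6 for shorter reads, none for
#' reads under 32 bp (unscreenable). Probes covering an ambiguous base carry
#' an `NA` key, which can never match.
#'
#' @param read_seq read sequence (character).
#' @param patterns pattern list.
#' @return data.table with columns `window` (0-based), `pattern` (0-based),
#'   `key` (packed 16-mer, NA if undefined).
#' @export
extract_probe_keys <- function(read_seq, patterns = build_patterns()) {
  codes <- seq_codes(read_seq)
  nw <- min(length(codes), 96L) %/% 32L
  if (nw == 0L) {
    out <- data.table::data.table(window = integer(0), pattern = integer(0))
    out[, key := numeric(0)]
    return(out[])
  }
  out <- data.table::CJ(window = seq_len(nw) - 1L, pattern = seq_along(patterns) - 1L)
  out[, key := {
    pos <- patterns[[pattern + 1L]]
    sum(codes[32L * window + pos + 1L] * .key_weights)
  }, by = .(window, pattern)]
  out[]
}

# Batched key computation: codes matrix (L x n) -> list over windows/patterns
# of key vectors of length n. Internal.
.probe_keys_matrix <- function(codes, n_windows, patterns) {
  keys <- vector("list", n_windows * length(patterns))
  k <- 0L
  for (w in seq_len(n_windows) - 1L) {
    for (p in seq_along(patterns)) {
      rows <- 32L * w + patterns[[p]] + 1L
      k <- k + 1L
      keys[[k]] <- colSums(.key_weights * codes[rows, , drop = FALSE])
    }
  }
  keys  # order: (w0,p1..p6), (w1,p1..p6), ...
}

#' Screen reads against the spaced hash index
#'
#' Counts, for each read, how many of its 18 spaced probes (6 per 32-mer over
#' the first 96 bases) have an exact key match in the corresponding pattern's
#' table. Both read orientations are probed and the orientation with the
#' higher count is kept. A read passes when its hit count reaches `k_min`
#' (default 3; the design guarantees reads with fewer than 7 mismatches to an
#' indexed 96-mer always pass at that threshold). Reads shorter than 96 bp
#' use 1 or 2 windows with the threshold scaled to
#' `ceiling(k_min * windows / 3)`; reads under 32 bp are unscreenable and
#' counted as filtered.
#'
#' @param reads character vector of read sequences.
#' @param index a `SpacedHashIndex`.
#' @param k_min minimum probe hits to pass (default 3).
#' @return data.table with one row per read: `hit_count` (NA if
#'   unscreenable), `passed`, `n_windows`, `w1`,`w2`,`w3` per-window hit
#'   counts of the winning orientation (NA for absent windows).
#' @export
screen_reads <- function(reads, index, k_min = 3L) {
  stopifnot(inherits(index, "SpacedHashIndex"), k_min >= 1L, k_min <= 18L)
  n <- length(reads)
  out <- data.table::data.table(hit_count = rep(NA_integer_, n),
                                passed = rep(FALSE, n),
                                n_windows = integer(n),
                                w1 = NA_integer_, w2 = NA_integer_, w3 = NA_integer_)
  if (n == 0L) return(out[])
  lens <- nchar(reads)
  np <- length(index$patterns)
  for (L in unique(lens)) {
    sel <- which(lens == L)
    nw <- min(L, 96L) %/% 32L
    out$n_windows[sel] <- nw
    if (nw == 0L) next
    codes <- codes_matrix(reads[sel], L)
    orient_counts <- vector("list", 2L)   # per-window hit matrices
    for (orient in 1:2) {
      oc <- if (orient == 1L) codes else revcomp_codes(codes)
      keys <- .probe_keys_matrix(oc[seq_len(min(L, 96L)), , drop = FALSE], nw,
                                 index$patterns)
      # hits per window: matrix nw x n
      hitw <- matrix(0L, nrow = nw, ncol = length(sel))
      for (p in seq_len(np)) {
        kp <- unlist(keys[(seq_len(nw) - 1L) * np + p], use.names = FALSE)
        hit <- kp %in% index$ukeys[[p]]
        hit[is.na(kp)] <- FALSE
        hitw <- hitw + matrix(as.integer(hit), nrow = nw, byrow = TRUE)
      }
      orient_counts[[orient]] <- hitw
    }
    tot1 <- colSums(orient_counts[[1L]]); tot2 <- colSums(orient_counts[[2L]])
    use2 <- tot2 > tot1
    hitw <- orient_counts[[1L]]
    if (any(use2)) hitw[, use2] <- orient_counts[[2L]][, use2, drop = FALSE]
    total <- pmax(tot1, tot2)
    k_eff <- if (nw == 3L) k_min else as.integer(ceiling(k_min * nw / 3))
    out$hit_count[sel] <- as.integer(total)
    out$passed[sel] <- total >= k_eff
    for (w in seq_len(nw)) data.table::set(out, i = sel, j = paste0("w", w),
                                           value = hitw[w, ])
  }
  out[]
}

#' Screen a single read
#'
#' Convenience wrapper around [screen_reads()] returning a `ScreenResult`.
#'
#' @inheritParams screen_reads
#' @param read_seq read sequence.
#' @return list with `hit_count`, `passed`, `window_hits`.
#' @export
screen_read <- function(read_seq, index, k_min = 3L) {
  r <- screen_reads(read_seq, index, k_min = k_min)
  structure(list(hit_count = r$hit_count, passed = r$passed,
                 window_hits = c(r$w1, r$w2, r$w3)[seq_len(r$n_windows)]),
            class = "ScreenResult")
}

#' Summarize a screening run
#'
#' @param screen data.table from [screen_reads()].
#' @return list: `total_reads`, `passed`, `filtered`, `filtered_fraction`,
#'   `unscreenable`, `hit_histogram` (named counts over hit_count).
#' @export
screen_summary <- function(screen) {
  hc <- screen$hit_count
  hist <- table(factor(hc[!is.na(hc)], levels = 0:18))
  list(total_reads = nrow(screen),
       passed = sum(screen$passed),
       filtered = sum(!screen$passed),
       filtered_fraction = if (nrow(screen)) mean(!screen$passed) else NA_real_,
       unscreenable = sum(is.na(hc)),
       hit_histogram = setNames(as.integer(hist), names(hist)))
}
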