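# Internal helpers: 2-bit DNA coding, batched sequence <-> code conversion,
# FASTQ text I/O, small misc utilities.

# ASCII -> 2-bit code lookup (A=0, C=1, G=2, T=3; anything else NA).
.dna_code_table <- local({
  v <- rep(NA_integer_, 256L)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("a")] <- 0L
  v[utf8ToInt("C")] <- 1L; v[utf8ToInt("c")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("g")] <- 2L
  v[utf8ToInt("T")] <- 3L; v[utf8ToInt("t")] <- 3L
  v
})

.dna_bases <- c("A", "C", "G", "T")

# single sequence -> integer codes (NA for N/ambiguous)
seq_codes <- function(s) {
  .dna_code_table[utf8ToInt(s)]
}

codes_to_seq <- function(codes) {
  b <- .dna_bases[codes + 1L]
  b[is.na(b)] <- "N"
  paste(b, collapse = "")
}

# Batch: equal-length reads -> code matrix (width x n). Reads longer than
# `width` are truncated; all must be at least `width` long.
codes_matrix <- function(reads, width) {
  if (length(reads) == 0L) return(matrix(integer(0), nrow = width, ncol = 0L))
  stopifnot(all(nchar(reads) >= width))
  s <- paste(substr(reads, 1L, width), collapse = "")
  matrix(.dna_code_table[utf8ToInt(s)], nrow = width)
}

# reverse complement at code level: 3 - code, order reversed along rows
revcomp_codes <- function(m) {
  3L - m[rev(seq_len(nrow(m))), , drop = FALSE]
}

# vectorized reverse complement of character sequences
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

phred_to_error <- function(q) 10^(-q / 10)

qual_string_to_phred <- function(qs) {
  utf8ToInt(qs) - 33L
}

phred_to_qual_string <- function(q) {
  intToUtf8(pmin(q, 60L) + 33L)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read a FASTQ file into a data.table
#'
#' Minimal FASTQ reader for the formats the simulator emits and typical
#' Illumina files (4 lines per record, optionally gzipped).
#'
#' @param path path to a FASTQ file (".gz" handled transparently).
#' @return `data.table` with columns `name`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ (line count not a multiple of 4): ", path)
  n <- length(lines) %/% 4L
  if (n == 0L) {
    return(data.table::data.table(name = character(0), seq = character(0), qual = character(0)))
  }
  i <- seq_len(n)
  name <- sub("^@", "", sub("\\s.*$", "", lines[4L * i - 3L]))
  data.table::data.table(name = name, seq = lines[4L * i - 2L], qual = lines[4L * i])
}

#' Write reads to a FASTQ file
#'
#' @param name,seq,qual character vectors of equal length.
#' @param path output path (plain text; ".gz" compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(name, seq, qual, path) {
  stopifnot(length(name) == length(seq), length(seq) == length(qual))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  if (length(name)) {
    writeLines(paste0("@", name, "\n", seq, "\n+\n", qual), con, sep = "\n")
  }
  invisible(path)
}

# 0-based half-open interval data.frame(chrom,start,end) -> GRanges
regions_to_granges <- function(regions) {
  if (is.null(regions)) return(NULL)
  if (methods::is(regions, "GRanges")) return(regions)
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

#' Read a BED file of regions
#'
#' Reads the first three columns of a BED file (0-based half-open), the
#' convention used for exclusion masks and target-region lists.
#'
#' @param path BED file path.
#' @return `data.table` with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, select = 1:3,
                          col.names = c("chrom", "start", "end"))
  dt[, `:=`(chrom = as.character(chrom), start = as.integer(start), end = as.integer(end))]
  dt[]
}
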