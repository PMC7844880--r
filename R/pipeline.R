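# Pipeline orchestration: screen -> align -> pair -> QC -> insert size ->
# genotypes -> contamination, consolidated into a machine-readable report.
# JSON is the canonical report; the HTML rendering is a view of it.

#' Run the full QC pipeline
#'
#' Executes the stages in order on paired (or single-end) FASTQ input against
#' a reduced reference: spaced-hash screening (a pair is retained when either
#' mate passes), alignment, pairing and duplicate marking, base/read-level
#' QC, censoring-corrected insert-size estimation, genotype calls, and —
#' when an SVD panel is supplied — contamination/ancestry estimation.
#' Artifacts (SAM, VCF, KM curve TSV, report JSON) are written under
#' `out_dir` when given. Identical config and inputs reproduce an identical
#' report.
#'
#' @param config list with entries:
#'   `fastq1`, `fastq2` (paths; `fastq2` optional) or `reads` (in-memory
#'   table with `qname`,`seq1`,`qual1`[,`seq2`,`qual2`]); `ref` (a
#'   `ReducedReference`) or `ref_prefix`; `index` (a `SpacedHashIndex`) or
#'   `index_path`; optional `panel` (`SvdPanel`) or `panel_prefix`; optional
#'   `out_dir`; parameters `k_min` (3), `mapq_min` (20), `max_mismatch` (5),
#'   `max_gap` (3), `min_baseq` (13).
#' @return a `RunReport` list (also written as `report.json` under
#'   `out_dir`).
#' @export
run_pipeline <- function(config) {
  cfg <- config
  get_par <- function(name, default) if (is.null(cfg[[name]])) default else cfg[[name]]
  k_min <- get_par("k_min", 3L)
  mapq_min <- get_par("mapq_min", 20L)
  max_mismatch <- get_par("max_mismatch", 5L)
  max_gap <- get_par("max_gap", 3L)
  min_baseq <- get_par("min_baseq", 13L)
  warnings <- character(0)
  if (!is.null(cfg[["out_dir"]])) dir.create(cfg[["out_dir"]], showWarnings = FALSE, recursive = TRUE)

  ref <- cfg[["ref"]]
  if (is.null(ref)) {
    if (is.null(cfg[["ref_prefix"]])) stop("missing reduced reference: supply `ref` or `ref_prefix` (build one with the `index` subcommand)")
    ref <- read_reduced_reference(cfg[["ref_prefix"]])
  }
  index <- cfg[["index"]]
  if (is.null(index)) {
    if (!is.null(cfg[["index_path"]]) && file.exists(cfg[["index_path"]])) {
      index <- read_hash_index(cfg[["index_path"]])
    } else if (!is.null(cfg[["ref_prefix"]]) && file.exists(paste0(cfg[["ref_prefix"]], ".shx"))) {
      index <- read_hash_index(paste0(cfg[["ref_prefix"]], ".shx"))
    } else {
      index <- index_reference(ref)
    }
  }
  panel <- cfg[["panel"]]
  if (is.null(panel) && !is.null(cfg[["panel_prefix"]])) {
    panel <- read_svd_panel(cfg[["panel_prefix"]])
  }

  # ---- input reads --------------------------------------------------------
  if (!is.null(cfg[["reads"]])) {
    reads <- data.table::as.data.table(cfg[["reads"]])
  } else {
    r1 <- read_fastq(cfg[["fastq1"]])
    reads <- data.table::data.table(qname = r1$name, seq1 = r1$seq, qual1 = r1$qual)
    if (!is.null(cfg[["fastq2"]])) {
      r2 <- read_fastq(cfg[["fastq2"]])
      if (nrow(r2) != nrow(r1)) stop("mate FASTQ files have different read counts")
      reads[, `:=`(seq2 = r2$seq, qual2 = r2$qual)]
    }
  }
  paired <- "seq2" %in% names(reads)
  n_pairs_in <- nrow(reads)

  empty_input <- n_pairs_in == 0L
  # ---- screening ----------------------------------------------------------
  if (!empty_input) {
    sc1 <- screen_reads(reads$seq1, index, k_min = k_min)
    sc2 <- if (paired) screen_reads(reads$seq2, index, k_min = k_min) else NULL
    all_screen <- if (paired) rbind(sc1, sc2) else sc1
    keep_pair <- if (paired) sc1$passed | sc2$passed else sc1$passed
  } else {
    all_screen <- screen_reads(character(0), index, k_min = k_min)
    keep_pair <- logical(0)
  }
  scr_sum <- screen_summary(all_screen)
  kept <- reads[keep_pair]

  # ---- alignment ----------------------------------------------------------
  a1 <- align_reads(kept$seq1, index, ref, qname = kept$qname, qual = kept$qual1,
                    mate = 1L, max_mismatch = max_mismatch, max_gap = max_gap)
  if (paired) {
    a2 <- align_reads(kept$seq2, index, ref, qname = kept$qname, qual = kept$qual2,
                      mate = 2L, max_mismatch = max_mismatch, max_gap = max_gap)
    aln <- rbind(a1, a2)
    pairs <- if (nrow(kept)) mark_duplicates(pair_and_flag(aln, mapq_min = mapq_min)) else NULL
  } else {
    aln <- a1
    pairs <- NULL
  }

  # ---- base/read-level QC -------------------------------------------------
  excl <- NULL
  if (!is.null(pairs)) {
    dupq <- pairs$qname[pairs$dup]
    excl <- aln$qname %in% dupq
  }
  tables <- accumulate_base_stats(aln, ref, exclude = excl)
  dd <- depth_distribution(tables)
  gcb <- gc_bias(tables)
  eq <- empirical_quality(tables)
  msum <- mapping_summary(scr_sum, aln, tables = tables, pairs = pairs)

  # ---- insert size --------------------------------------------------------
  insert <- NULL
  if (!paired) {
    warnings <- c(warnings, "single-end input: insert-size and duplicate metrics not computed")
  } else if (!is.null(pairs) && sum(pairs$proper) > 0L) {
    tuples <- build_tuples(pairs[dup == FALSE], ref, mapq_min = mapq_min)
    km <- km_estimate(tuples)
    naive <- naive_estimate(tuples)
    ksum <- insert_size_summary(km)
    insert <- list(n_tuples = nrow(tuples),
                   n_events = sum(!is.na(tuples$t_o)),
                   n_censored = sum(is.na(tuples$t_o)),
                   km_summary = ksum,
                   naive_median = insert_size_summary(naive)$median,
                   defective = isTRUE(attr(km, "defective")))
    if (!is.null(cfg[["out_dir"]])) write_km_curve(km, file.path(cfg[["out_dir"]], "insert_size_km.tsv"))
  } else {
    warnings <- c(warnings, "no proper pairs: insert-size distribution not computed")
  }

  # ---- variant-level ------------------------------------------------------
  dupq <- if (!is.null(pairs)) pairs$qname[pairs$dup] else NULL
  pile <- pileup(aln, ref, min_mapq = mapq_min, min_baseq = min_baseq,
                 dup_qnames = dupq)
  calls <- genotype_calls(pile)
  contam <- NULL
  if (!is.null(panel)) {
    contam <- withCallingHandlers(
      tryCatch(estimate_contamination(pile, panel),
               error = function(e) {
                 warnings <<- c(warnings, conditionMessage(e))
                 NULL
               }),
      warning = function(wn) {
        warnings <<- c(warnings, conditionMessage(wn))
        invokeRestart("muffleWarning")
      })
  }

  # ---- artifacts ----------------------------------------------------------
  if (!is.null(cfg[["out_dir"]])) {
    dir.create(cfg[["out_dir"]], showWarnings = FALSE, recursive = TRUE)
    write_sam(aln, ref, file.path(cfg[["out_dir"]], "aligned.sam"), pairs = pairs)
    write_vcf(calls, file.path(cfg[["out_dir"]], "sample.vcf"))
  }

  report <- list(
    tool = "seqsentry",
    version = as.character(utils::packageVersion("seqsentry")),
    params = list(k_min = k_min, mapq_min = mapq_min, max_mismatch = max_mismatch,
                  max_gap = max_gap, min_baseq = min_baseq),
    screening = scr_sum,
    mapping = unclass(msum),
    base_qc = list(
      cycle_quality = tables$cycle_quality,
      empirical_quality = eq[n_total > 0],
      depth = list(mean = dd$mean, median = dd$median,
                   total_positions = dd$total_positions,
                   histogram = dd$histogram),
      gc_bias = gcb[n_contigs > 0]),
    insert_size = insert,
    variants = list(n_markers = nrow(calls),
                    n_covered = sum(calls$depth > 0L),
                    mean_site_depth = mean(calls$depth)),
    contamination = if (!is.null(contam)) list(
      alpha = contam$alpha, pc = as.numeric(contam$pc),
      population = contam$population, n_sites = contam$n_sites,
      converged = contam$converged, low_sites = contam$low_sites) else NULL,
    warnings = warnings)
  class(report) <- "RunReport"
  if (!is.null(cfg[["out_dir"]])) {
    jsonlite::write_json(unclass(report), file.path(cfg[["out_dir"]], "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", force = TRUE)
  }
  report
}

#' Render a run report as static HTML
#'
#' Content-fidelity rendering of the canonical JSON report: summary tables
#' for every section plus inline SVG plots (quality by cycle, GC bias, depth
#' histogram, insert-size CDF, ancestry scatter) when an SVG graphics device
#' is available; sections missing from the report render as "not computed".
#' Output is deterministic for identical reports (no timestamps).
#'
#' @param report a `RunReport` from [run_pipeline()].
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  esc <- function(x) gsub("<", "&lt;", gsub("&", "&amp;", as.character(x)))
  kv_table <- function(x) {
    rows <- vapply(names(x), function(nm) {
      v <- x[[nm]]
      v <- if (is.null(v)) "—" else if (is.numeric(v) && length(v) == 1L)
        formatC(v, digits = 6, format = "g") else paste(esc(unlist(v)), collapse = ", ")
      sprintf("<tr><th>%s</th><td>%s</td></tr>", esc(nm), v)
    }, character(1))
    paste0("<table>", paste(rows, collapse = ""), "</table>")
  }
  section <- function(title, body) {
    sprintf("<section><h2>%s</h2>%s</section>", esc(title),
            if (is.null(body)) "<p><em>not computed</em></p>" else body)
  }
  svg_plot <- function(draw) {
    if (!capabilities("cairo")) return(NULL)
    tf <- tempfile(fileext = ".svg")
    grDevices::svg(tf, width = 6, height = 4)
    ok <- tryCatch({ draw(); TRUE }, error = function(e) FALSE)
    grDevices::dev.off()
    if (!ok || !file.exists(tf)) return(NULL)
    sv <- readLines(tf, warn = FALSE)
    unlink(tf)
    paste(sv[!grepl("^<\\?xml|^<!DOCTYPE", sv)], collapse = "\n")
  }
  plots <- character(0)
  bq <- report$base_qc
  if (!is.null(bq)) {
    p1 <- svg_plot(function() {
      cq <- bq$cycle_quality
      plot(cq$cycle, cq$mean_q, type = "l", xlab = "cycle",
           ylab = "mean reported quality", main = "Quality by cycle")
    })
    p2 <- svg_plot(function() {
      g <- bq$gc_bias
      plot((g$gc_lo + g$gc_hi) / 2, g$normalized_depth, type = "b",
           xlab = "contig GC", ylab = "normalized mean depth", main = "GC bias")
      abline(h = 1, lty = 2)
    })
    p3 <- svg_plot(function() {
      h <- bq$depth$histogram
      plot(h$depth, h$n_positions, type = "h", xlab = "depth",
           ylab = "callable positions", main = "Depth distribution")
    })
    plots <- c(plots, p1, p2, p3)
  }
  html <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>seqsentry QC report</title>",
    "<style>body{font-family:sans-serif;max-width:70em;margin:auto}table{border-collapse:collapse}th,td{border:1px solid #ccc;padding:2px 8px;text-align:left}</style>",
    "</head><body><h1>seqsentry QC report</h1>",
    section("Run parameters", kv_table(report$params)),
    section("Screening", kv_table(report$screening[c("total_reads", "passed", "filtered",
                                                     "filtered_fraction", "unscreenable")])),
    section("Mapping", kv_table(report$mapping[c("total_reads", "screen_pass_fraction",
                                                 "mapped_fraction_of_screened",
                                                 "duplicate_rate", "mean_callable_depth")])),
    section("Insert size", if (!is.null(report$insert_size))
      kv_table(c(report$insert_size[c("n_tuples", "n_events", "n_censored", "defective")],
                 list(km_median = report$insert_size$km_summary$median,
                      naive_median = report$insert_size$naive_median)))),
    section("Variants", kv_table(report$variants)),
    section("Contamination / ancestry", if (!is.null(report$contamination))
      kv_table(report$contamination)),
    if (length(plots)) sprintf("<section><h2>Plots</h2>%s</section>",
                               paste(plots, collapse = "\n")) else "",
    if (length(report$warnings)) sprintf("<section><h2>Warnings</h2><ul>%s</ul></section>",
                                         paste0("<li>", esc(report$warnings), "</li>",
                                                collapse = "")) else "",
    "</body></html>")
  writeLines(html, path)
  invisible(path)
}
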