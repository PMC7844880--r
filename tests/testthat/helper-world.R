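# Shared fixtures: a small simulated world (genome + panel + reduced
# reference + hash index), built once per test session and memoized.

.world_cache <- new.env(parent = emptyenv())

small_world <- function(n_markers = 60L, genome_len = 2e5, seed = 7L,
                        read_len = 150L) {
  key <- paste(n_markers, genome_len, seed, read_len, sep = "_")
  if (!is.null(.world_cache[[key]])) return(.world_cache[[key]])
  cfg <- sim_config(genome_len = genome_len, n_markers = n_markers, seed = seed,
                    read_len = read_len)
  w <- simulate_reference_and_panel(cfg)
  panel <- select_markers(w$snps, n_target = n_markers, seed = seed + 1L)
  ref <- extract_flanks(w$genome, panel, read_len = read_len)
  idx <- index_reference(ref)
  out <- list(cfg = cfg, sim = w, panel = panel, ref = ref, idx = idx)
  .world_cache[[key]] <- out
  out
}

# random DNA string
rand_dna <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# plant mismatches at 1-based positions in a sequence (cycles to a different base)
mutate_at <- function(s, pos) {
  v <- strsplit(s, "")[[1L]]
  repl <- c(A = "C", C = "G", G = "T", T = "A")
  v[pos] <- repl[v[pos]]
  paste(v, collapse = "")
}
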