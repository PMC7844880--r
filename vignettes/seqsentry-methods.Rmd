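---
title: "seqsentry: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqsentry: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

seqsentry assesses the quality of raw short-read sequencing data without a
full-genome alignment. The central idea is that almost every QC metric a
sequencing core cares about — base quality calibration, depth, GC bias,
duplicate rate, insert-size distribution, sample contamination, genetic
ancestry — can be estimated from the small fraction of reads that align to a
*reduced reference genome*: a collection of short contigs, each the flanking
sequence of a known common SNP. This vignette explains the statistical
machinery behind each stage, the tunable parameters and their defaults, what
the bundled simulator does and does not emulate, and the design decisions
that were genuinely open.

## 1. The reduced reference

`select_markers()` draws a designated number of biallelic SNPs from a
candidate set (a VCF with allele frequencies), keeping only common variants
(minor allele frequency strictly above `maf_min = 0.05`), discarding sites in
an exclusion mask (e.g. hard-to-align regions, supplied as BED), optionally
restricting to target regions for exome-style data, and enforcing a minimum
pairwise spacing. `extract_flanks()` then cuts one contig per marker: the
`2w + 1` genome bases centred on the SNP, with the reference allele at the
centre column.

Parameters and defaults:

* `w_short = 250`, `w_long = 1000` (bases): flank half-widths, giving 501-bp
  and 2001-bp contigs. Short contigs keep the index small; the 10% of long
  contigs (`long_fraction = 0.10`) exist mainly so that large inserts are
  observable at all (Section 4).
* `n_target = 10000` markers by default — enough sites for stable
  contamination and ancestry estimates while keeping the reduced reference
  in the megabase range.
* `min_spacing = 2 * w_long`: no two retained markers closer than this, so no
  two contigs can overlap. The value is a conservative package choice (any
  spacing above `w_i + w_j` prevents overlap for a specific pair); it can be
  lowered for dense designs.
* Markers whose flanks contain an ambiguous base, that lack flank room, or
  whose recorded reference allele disagrees with the genome are dropped with
  a warning rather than patched — the reduced reference must consist of
  well-alignable sequence or every downstream metric inherits the problem.

Every contig records a **callable interval**: only reads that fit entirely
inside a contig can align, so positions within `read_len` of a contig edge
are depleted and would bias base-level metrics. We restrict all base-level
tallies to the central `2(w − r) + 1` bases, the 0-based half-open interval
`[r, 2w + 1 − r)`, which is symmetric about the variant column. (Two other
off-by-one readings of "the fully alignable portion" exist; we use the one
whose width matches the formula above exactly and which is centred on the
variant.)

## 2. The mismatch-tolerant spaced-hash filter

Aligning every read against even a reduced reference is wasteful when the
reference covers well under 1% of the genome — the vast majority of reads
are unalignable by construction. `screen_reads()` filters them with a spaced
k-mer design:

* Positions `0..31` of a 32-mer are partitioned into four contiguous blocks
  of 8; the **six patterns** are the six pairs of blocks, each selecting 16
  of 32 positions (`build_patterns()`).
* Every position lies in exactly 3 patterns, and for any two positions at
  least one pattern contains neither. Hence a 32-mer with ≤ 2 mismatches
  always retains at least one exact 16-mer match — the pattern built from
  the two untouched blocks.
* The index (`index_reference()`) stores, per pattern, the packed 2-bit
  16-mer key of every 32-mer window of every contig (stride `step = 1`).
  Keys are exact, not lossily hashed: a "hit" is a true 16-mer occurrence.
* A read is screened on its first 96 bases: three non-overlapping 32-mers ×
  six patterns = 18 probes. It passes when at least `k_min` probes hit
  (default 3). Both orientations are probed against the forward-strand index
  and the better orientation is kept — equivalent to indexing both strands
  at half the memory.

`worst_case_min_hits(m)` computes, by exhaustive enumeration over
block-occupancy classes (proven equivalent to position-level brute force in
the test suite), the minimum possible hit count after `m` adversarial
mismatches. The resulting guarantee ladder for 96 screened bases is

| m | 0 | 1 | 2 | 3 | 4 | 5 | 6 | 7 | 8 |
|---|---|---|---|---|---|---|---|---|---|
| worst-case hits | 18 | 15 | 12 | 9 | 7 | 5 | 3 | 2 | 1 |

so with `k_min = 3` every read with fewer than 7 mismatches passes, and with
`k_min = 10` every read with fewer than 3 mismatches passes. Reads shorter
than 96 bp are screened on 1 or 2 windows with the threshold scaled to
`ceiling(k_min * windows / 3)`; reads under 32 bp are unscreenable and
treated as filtered. In a read pair, the pair is kept when either mate
passes.

## 3. The mini-aligner

Reads surviving the screen are aligned by seed-and-extend over the same
spaced-hash index (one index, one code path): each probe hit votes for a
(contig, diagonal) candidate; the top candidates are verified by vectorized
ungapped mismatch counting; reads that fail only through indels fall back to
a banded dynamic program with band `max_gap = 3`. An alignment is accepted
at `max_mismatch = 5` or fewer edits; the best candidate wins, ties break
deterministically to the lowest (contig, start, forward) and score mapping
quality 0; a unique best with no runner-up scores 60, otherwise the quality
scales with the edit-distance gap to the runner-up. These three thresholds
are package choices (they admit typical Illumina error rates over 150-bp
reads while rejecting chance 16-mer matches); the original tool's BWT-based
engine and its mapping-quality model are intentionally not reproduced — the
reduced-reference QC semantics, not the alignment algorithm, are the point.

Pairs are proper when both mates map to the same contig, in FR orientation,
with mapping quality ≥ 20 and positive outer distance. Duplicates are pairs
sharing (contig, leftmost start, rightmost end, orientation); the first in
read-name order is kept, the rest flagged.

## 4. Censoring-corrected insert-size estimation

On a reduced reference the observed insert sizes are biased small: a pair
whose fragment extends past a contig edge loses one mate and its insert is
never observed directly. seqsentry treats this as a right-censoring problem.

For each retained pair we record the tuple `(t_o, t_l, t_r)`: the observed
insert `t_o` (proper pairs only), and the *maximal insert sizes* — the
distance from the leftmost base of the left read to the contig's right end
(`t_l = L − s`), and from the rightmost base of the right read to the
contig's left end (`t_r = e`). A single-end-mapped pair yields only the
bound of its mapped mate, which censors the unknown insert from below
(fragment length `T > bound` exactly when the other mate falls off the
contig).

`km_estimate()` is the Kaplan-Meier product-limit estimator on these data:
with event times `τ_j`, event counts `o_j`, censor counts `c_j`, and risk
set `Y(t) = Σ_j (o_j + c_j) I[τ_j ≥ t]`,

S(t) = Π over τ_j ≤ t of (1 − o_j / Y(τ_j)),  F(t) = 1 − S(t).

Conventions and choices:

* **Risk units are flank anchors, not pairs.** Each non-missing bound
  (`t_l`, `t_r`) contributes one unit: a fully observed pair enters twice
  (both anchors saw the event), a single-end pair once (censored). This is
  the only reading under which censoring is independent of the fragment
  length: the probability that a *pair* is fully observed falls linearly in
  `T` while the probability it is censored rises, so pair-level units
  violate random censorship and the estimator does not converge to the true
  distribution (we measured its KS distance to truth *growing* with sample
  size). Anchor positions, by contrast, are uniform on the contig and
  independent of `T`. An abstract event supplied without bounds counts once.
* Ties: events precede censorings at the same time (standard).
* With zero censoring the estimator reduces exactly to the empirical CDF.
* If the largest time is censored, `F` is defective; summary statistics
  (median, mode, 5/95 percentiles, via `insert_size_summary()`) renormalize
  it and the curve carries a `defective` flag.
* `ipcw_estimate()` is the inverse-probability-of-censoring-weighted
  rewriting, `F(t) = (1/n) Σ δ_i I[T_i ≤ t] / G(T_i−)` with `G` the
  censoring-distribution Kaplan-Meier; it is algebraically identical to the
  product-limit form and the tests require agreement to 1e-10. The
  product-limit path is primary.
* `naive_estimate()` (the ECDF of observed inserts only) is retained for
  bias comparison, and `distribution_distance()` reports the two-sample
  Kolmogorov-Smirnov statistic `D = sup |F1 − F2|` and the Wasserstein-1
  distance `W = ∫ |F1 − F2| dt`. For `W` the time axis is normalized to
  `[0, 1]` by the largest grid value, making the number scale-free; this is
  a declared convention, since the scale on which such distances are
  conventionally reported is ambiguous.

## 5. Genotype likelihoods

`pileup()` collects, per marker, the base every covering read carries at the
contig centre column (defaults `min_mapq = 20`, `min_baseq = 13` — the
samtools-tradition values; duplicates excluded). `genotype_calls()` applies
the standard biallelic model: with per-base error `e = 10^(−q/10)`,

GL(g) = Σ_b log10[ (g/2) P(b|alt) + (1 − g/2) P(b|ref) ],
P(b|allele) = 1 − e if b equals the allele, e/3 otherwise,

for alternate-allele dosage `g ∈ {0, 1, 2}`. PL is the min-rescaled integer
Phred likelihood; GP the posterior under a Hardy-Weinberg prior at the panel
allele frequency; GT the argmax posterior (`./.` when uncovered). GL remains
prior-free. The marker column is excluded from the *error-rate* tallies of
Section 6 for the same reason it is the only column used here: real
heterozygous alternate alleles would otherwise masquerade as sequencing
errors.

## 6. Base- and read-level metrics

`accumulate_base_stats()` computes per-cycle mean reported quality over all
reads (pre-alignment, in machine orientation), and — restricted to callable,
non-variant positions of gapless alignments, duplicates excluded — the
match/mismatch counts per reported quality and the per-position depth.
Empirical quality per reported-quality bin is
`−10 log10((mismatches + 1) / (total + 2))`, capped at Q60; the pseudocount
keeps zero-mismatch bins finite, so an error-free bin reads
`10 log10(n + 2)` rather than infinity. GC bias bins contigs by whole-contig
GC (contigs are short enough to act as natural GC strata; bin width 2.5%)
and reports each bin's mean callable depth over the overall mean; bins with
fewer than 5 contigs are flagged low-confidence and empty bins are missing,
not zero. The mapping summary deliberately reports three numbers — fraction
of reads passing the screen, fraction of screened reads mapped, and a
whole-genome proxy equal to the latter with an explicit caveat — rather than
guessing a single extrapolated "% mapped": on a reduced reference the
extrapolation is only sound for whole-genome data.

## 7. Contamination and ancestry

The SVD panel supplies, per marker, the mean alternate-allele dosage `mu_i`
and `K = 2` principal-component loadings `L_ik`, plus labelled reference
sample coordinates. An individual at ancestry coordinates `pc` has
individual-specific allele frequency

f_i(pc) = clamp((mu_i + Σ_k L_ik pc_k) / 2, 1e-4, 1 − 1e-4).

`mixture_loglik()` models each site's reads as a mixture of two unknown
genotypes — the intended sample's `g1 ~ HWE(f_i(pc))` and a contaminant's
`g2 ~ HWE(f_i(pc2))` — with each read drawn from the contaminant with
probability `α`:

loglik = Σ_i log Σ_{g1,g2} HWE(g1|f_i(pc)) HWE(g2|f_i(pc2)) Π_b [(1−α) P(b|g1) + α P(b|g2)].

At `α = 0` the contaminant marginalizes out exactly, and the likelihood is
symmetric under `(α, pc, pc2) → (1−α, pc2, pc)`; both identities are tested
numerically, and the whole function is checked against an explicit 9-term
brute-force oracle to 1e-8. `estimate_contamination()` maximizes over a
coarse grid (α in {0, 0.005, 0.01, 0.02, 0.05, 0.1, 0.2, 0.35, 0.5} ×
population centroids plus the origin) followed by Nelder-Mead refinement
with α logit-bounded to [0, 0.5] — the cap resolves the label-swap symmetry.
`share_pc = TRUE` (contaminant shares the sample's ancestry) is the default:
it is conservative and much better identified at the 5-10× depths the tool
targets; a separate-coordinates mode exists. Fewer than 100 usable sites
triggers a warning but still returns an estimate. `assign_ancestry()` is
nearest population centroid in PC space, alphabetical tie-break, flagged.

## 8. The simulator: what a green test establishes

The bundled generator (`simulate_reference_and_panel()`, `simulate_reads()`,
`simulate_pileup()`, `mix_contamination()`, `simulate_insert_tuples()`) is
the package's test bed and emulates: a uniform-composition genome at a
target GC; well-spaced biallelic common SNPs (MAF > 0.05); an SVD panel with
3 well-separated synthetic populations (centroids on a radius-2 circle,
loadings N(0, 0.12), 20 reference samples per population at jitter 0.08);
diploid fragments uniform over the genome with fragment length
`round(Normal(350, 50))` truncated — by conditioning, not clamping — at
twice the 150-bp read length; FR mate orientation; uniform base-error rates
tied to a constant reported quality (Q30 default; errors substitute a
uniformly chosen different base); PCR duplicates as re-emitted fragments
with fresh errors; contamination as per-pair Bernoulli mixing. Everything is
seeded; identical configurations are byte-identical.

It does **not** emulate: repetitive or homologous sequence (so the ~100%
off-footprint filter rates seen on synthetic genomes are an upper bound on
the >90%/>99% expected with real genomes), indels and structural variation, cycle- and
context-dependent error profiles, quality miscalibration, optical-duplicate
clustering, insert-size multimodality, linkage disequilibrium between
markers, or realistic allele-frequency spectra. A green test therefore
establishes the estimators' correctness under their stated statistical
models, not robustness to every artifact of production data.

The default fragment law on 501-bp contigs censors roughly 70% of observed
pairs — deliberately harsh, the regime where the Kaplan-Meier correction
visibly matters — while 2001-bp contigs observe nearly everything.

## 9. Numerical choices and degenerate inputs

* Packed 16-mer keys live in doubles (< 4^16 ≈ 4.3e9, exactly representable);
  probes touching an N have NA keys that never match; indexing skips windows
  containing N.
* Mixture likelihoods use log-sum-exp stabilization; per-base genotype
  likelihood factors are precomputed once per pileup, so optimizer
  iterations cost only vector arithmetic.
* Empty inputs are values, not crashes: an empty FASTQ yields a zero-count
  report with missing fractions; an unalignable read is an unmapped record;
  an uncovered marker is a `./.` VCF row; a depth histogram with no aligned
  reads puts all mass at 0. Zero observed insert events, by contrast, is an
  explicit error — no distribution exists to estimate.
* The KM curve's `n` attribute counts risk units (anchors), not pairs.
* Ungapped verification treats N-containing read positions as mismatches.

## 10. Known limitations

* The aligner has no soft-clipping or split alignments: reads straddling a
  contig edge are unmapped rather than partially aligned, which is exactly
  the censoring the insert-size machinery models, but it means "% mapped" on
  the reduced reference understates a full-genome aligner.
* Mapping quality is a local convention (unique/tied/score-gap), not a
  calibrated error probability.
* The contamination model assumes a homogeneous contaminant and HWE at panel
  frequencies; sample swaps between close relatives are not modelled.
* GC bias uses whole-contig GC, which is natural for 501-bp contigs but
  coarser than sliding-window estimates on long contigs.
* Filter-rate guarantees are worst-case over mismatch placements; sequencing
  *indels* in the first 96 bases shift all downstream windows and can defeat
  the screen with fewer events.
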