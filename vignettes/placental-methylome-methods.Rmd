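---
title: "Methods: comparative placental methylome analysis with pmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative placental methylome analysis with pmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmeth)
```

# Scope and data model

`pmeth` analyzes per-CpG methylation calls from whole-genome bisulfite
sequencing. The atomic datum is a CpG site with `meth_reads` methylated of
`total_reads` covering reads; public tracks that only carry percentages are
supported as a *fraction dialect* in which read counts are unknown and every
site has weight one. All coordinates are 0-based half-open everywhere
inside the package — a single convention prevents off-by-one drift between
the window, lifting, and masking modules; 1-based inputs must be converted
on read. CpG methylation is strand-symmetric, so calls at positions `p` and
`p + 1` can be merged (read counts summed) into one site at `p`; the merge
is idempotent.

Because public wig exports do not say whether they are read-weighted or
site-averaged, both interpretations are exposed: `global_methylation()` is
the read-weighted pooled ratio (the quantity quoted as a genome's "global
methylation"), while window and feature means are *unweighted* across the
covered CpG sites, which matches how per-window distributions are usually
drawn.

# Window tracks

`window_methylation()` tiles each chromosome into abutting fixed windows
(default 20 kb) and reports the unweighted mean methylation of covered CpGs
per window. Windows with fewer than `min_cpgs` (default 20) informative
sites are kept in the grid but marked missing; downstream smoothing and
segmentation treat missing explicitly rather than imputing. The trailing
partial window of a chromosome is kept if it meets the filter — dropping it
would discard telomeric signal for no benefit.

Distribution summaries (`methylation_density()`) use a Gaussian kernel
density with Silverman's bandwidth on the percent scale, renormalized over
[0, 100]. Bimodality — judged by eye in the literature — is operationalized
as: at least two local maxima whose intervening trough is lower than
`(1 - trough_depth)` times the smaller peak (default `trough_depth = 0.15`),
ignoring peaks below 5% of the global maximum as numerical ripple. Both
knobs are exposed; the defaults were fixed before the acceptance checks and
are deliberately permissive about peak height so that a small secondary
HMD peak still counts as bimodal.

`kernel_smooth()` is a Nadaraya–Watson estimate over window centers
(Gaussian kernel; default bandwidth three window widths, a value the source
analyses leave unstated and which is therefore configurable). Missing
windows contribute to neither numerator nor denominator, and no estimate is
produced where no covered window lies within one bandwidth — smoothing must
not invent signal inside long unmappable gaps, which is how smoothed lifted
tracks acquire spurious excursions below 0% or above 100%.

`running_median()` uses a centered odd window (default 15 windows) that
shrinks *symmetrically* at series ends (half-width `min(h, i-1, n-i)`).
The symmetric-shrink convention was chosen over asymmetric truncation
because it keeps the smoother an exact identity on monotone series — hence
idempotent there, a property the test suite asserts — at the cost of doing
almost no smoothing in the last few windows of a chromosome (see the
differential-region edge policy below).

# Domain segmentation

`fit_domain_hmm()` fits a two-state Gaussian-emission HMM to the covered
window means by Baum–Welch. Choices:

* **Emissions genome-wide, decoding per chromosome.** Whether domain calls
  in comparable analyses pooled emissions across chromosomes is not
  documented; pooling gives every chromosome the same PMD/HMD definition
  and more data per state, so emissions are shared and only the decoding is
  per chromosome.
* **Gaussian emissions** on window means. With state SDs (~0.03 at 20 kb)
  far smaller than the [0, 1] range, a Gaussian is adequate and keeps the
  M-step closed-form.
* **Initialization** is deterministic: state means at the 25th/75th
  percentiles of the window means, both SDs at half the interquartile
  range (floored at 1e-3), self-transition 0.99 reflecting multi-100-kb
  domain persistence, uniform start probabilities. Convergence is declared
  when the relative log-likelihood change drops below `tol = 1e-8`
  (cap `max_iter = 100`); the per-iteration log-likelihood trace is
  returned and is non-decreasing, which the tests assert.
* **Missing data.** Runs of more than `gap_max = 5` missing windows restart
  the chain (domains never bridge long unmappable gaps); shorter gaps are
  skipped within a chain.
* **Minimum domain size.** Decoded same-state runs shorter than
  `min_domain_bp = 1e5` are absorbed into their longer neighbor,
  iteratively from the shortest, since sub-100-kb calls are below the
  domain scale of interest.
* **"No PMD structure."** If the fitted state means differ by less than
  `min_separation = 0.10` (or the track is constant), the result is a
  single HMD per chromosome. PMD is deliberately a *model-relative* label —
  the lower-emission-mean state — not an absolute methylation cutoff, since
  no numeric PMD definition exists that transfers across species.

`boundary_proximity()` takes the median distance from internal domain
boundaries to the nearest feature point (interval starts/ends) and compares
it with boundaries re-placed uniformly within each chromosome's analyzable
span (missing-data gaps excluded, per-chromosome counts preserved). The
p-value is the one-sided `(1 + #{null <= obs}) / (1 + n_perm)`; uniformity
of this p-value under its own null is part of the acceptance suite.

# Cross-species comparison

`lift_cpgs()` maps sites through UCSC chains: a site maps through the
highest-scoring chain block containing it; negative-strand chains reflect
coordinates (`t_end - 1 - offset`); sites in inter-block gaps are unmapped
(a category, not an error); target-position collisions keep the
higher-scoring chain, then the lower source coordinate, making output
deterministic. Lifting is positional only — no sequence-conservation check —
because large-scale methylation patterns, not individual CpGs, are the
object of comparison. The chain parser/writer is implemented in the package
(scores must survive parsing for the tie-break, chains must be *written*
by the generator, and an inverse-chain operation is needed); the test suite
cross-checks the lift against `rtracklayer::liftOver` on rearranged toy
maps.

`clean_by_synteny()` removes lifted sites inside level-2 net fills shorter
than 1 Mb — local translocations/duplications that would contaminate
large-syntenic-region comparisons — and records the removal count;
`mapped + unmapped + removed` always reconciles with the input.

`differential_regions()` smooths both tracks with the width-15 running
median, puts the species track on the reference's mean and SD, and calls
maximal runs of windows where |smoothed difference| exceeds
`z_threshold = 1.5` times σ. Two numerical decisions matter:

* **σ is the SD of the raw (unsmoothed) scaled per-window difference.**
  Thresholding a series at 1.5 times *its own* SD flags ~13% of Gaussian
  windows no matter how much smoothing preceded it, because the threshold
  adapts down to the noise floor; the raw-difference SD measures the
  window-level variability of the comparison and makes an offset-free
  replicate pair genuinely quiet.
* **The scaling affine is fitted on the raw series, not the smoothed one.**
  The running median commutes with affine maps, so this changes only which
  moments set the scale; raw moments remain stable when a track has little
  large-scale structure, where smoothed moments collapse to the noise floor
  and would compress a planted difference several-fold.
* **Chromosome-end margin.** The symmetric-shrink running median leaves the
  outermost `(width-1)/2` windows of each chromosome essentially
  unsmoothed; their variance is that of the raw difference, so they are
  excluded from region eligibility rather than being allowed to fire the
  smoothed-series threshold.

Runs are split at chromosome boundaries, missing windows, and sign changes,
so each region carries one direction; the per-window threshold (rather than
a region-mean threshold, which the sources leave ambiguous) is used, and
region maxima are reported.

`break_enrichment()` compares the fraction of syntenic breaks (junctions
between level-1 fills and level-2 fills > 1 Mb) falling in differential
regions against uniform re-placement, with a two-sided doubled-tail
empirical p.

# Gene-level analyses

Promoters are TSS −1000 bp to +100 bp, strand-aware. Gene bodies are the
full transcribed span including introns; CpGs in the gene's own promoter or
in any CpG island are masked before averaging, and genes with fewer than 20
remaining informative CpGs are omitted (features in `feature_methylation()`
require 10). An exon-only gene-body mode is not implemented — full-span
bodies are the convention the package follows throughout, and `GeneModel`
therefore carries no exon structure (a known limitation for users wanting
exonic means).

Spinogram windows (5 kb, ≥ 10 covered CpGs) are *genic* when their midpoint
falls in any gene body — a midpoint rule rather than any-overlap, so each
window has exactly one class even when it straddles a gene edge. Bins are
5% wide (20 bins) by default. `build_ortholog_matrix()` joins per-species
gene-body tables through pairwise ortholog maps onto a pivot species,
keeping rows with at least two species and resolving duplicate orthologs by
retained-CpG count; values are exported raw (any per-species normalization
is left to the consumer, since whether a normalization preceded published
clusterings is unstated).

# Methylation–expression coupling

`coindependence_test()` transforms expression as `log10(fpkm + 0.01) + 1`.
The transform's base and zero-handling are undocumented in the sources;
log10 with ε = 0.01 makes the conventional 0.56 high/low threshold fall in
the FPKM ≈ 0.35 range and handles zeros, and both knobs are configurable.
Axes are divided into 20 equally spaced bins over the observed range
(rank/equal-count binning available as an option; in rank mode the
permutation p is invariant to monotone transforms of expression, which the
tests assert). Cells with expected count < 1 are pooled into the nearest
eligible cell along the expression axis before the chi-square sum. The
reference distribution is permutation of expression labels by default —
exact under exchangeability with no cell-count assumptions; the classical
chi-square approximation (`mode = "chi2"`, df = (r−1)(c−1) over occupied
margins) is provided for speed but documented as approximate since the
binning of two continuous variables does not follow the textbook
contingency setup exactly. `sector_deviation()` summarizes the
high-methylation × intermediate-expression sector (top third × middle
third of bins by default), whose positive deviation is the qualitative
signature of placental methylation–expression coupling.

# The synthetic-data generator

`simulate_genome()` / `simulate_methylome()` / `simulate_species_pair()` /
`simulate_expression_dataset()` produce every input format the analysis
modules read, deterministically under a seed (the RNG state is saved and
restored, so generators do not disturb the caller's stream).

The default **demo genome** is 2 chromosomes × 10 Mb with ~100,000 CpGs
(background 1/200 bp, 10× enriched in islands), 300 non-overlapping genes
(log-normal lengths, median 30 kb), 400 CpG islands (~1 kb) and
LINE/SINE/LTR repeats — sized so the full pipeline and its planted-truth
checks run in about a minute on one CPU; tests that need more windows (the
spinogram calibration at ~20,000 5-kb windows, the coarse-window
bimodality sweep) scale the chromosome count up, a choice the tests state
explicitly.

The default **methylome** alternates PMD (0.40) and HMD (0.80) baselines in
log-normal blocks with median 180 kb (sdlog 0.5, floored at 100 kb). The
length scale was chosen to reproduce, before anything else was tuned, the
qualitative window-length sensitivity of real placental methylomes: domains
must be long enough that 5–50 kb windows mostly fall inside one domain
(bimodal window distributions) and short enough that 200 kb windows mix
adjacent domains (bimodality lost). Fixed-length blocks
(`len_sdlog = 0`) are used for planted-boundary recovery checks, where the
truth must sit on the window grid. Expressed genes' bodies are elevated by
Δ = 0.10; islands override to 0.10; site noise is truncated-Gaussian
(SD 0.15) — chosen over a Beta so the SD used by the HMM checks is a direct
knob; with negative-binomial coverage (mean 5, size 10) this yields
between-window SDs near 0.03 at 20 kb. Truncation at 1 biases the realized
HMD site mean to ≈ 0.77; tests that assert moment recovery compare against
the analytic truncated-normal mean, not the nominal baseline. Expression
follows the one-knob coupling model P(expressed) =
logistic(κ·(gene-body baseline − mean)), FPKM log-normal (median 10) for
expressed genes and ≈ 0.02 for silent ones; κ = 0 gives exact independence
(the null-calibration path), κ > 0 reproduces the
high-methylation → intermediate-expression excess.

`simulate_species_pair()` applies explicit non-overlapping rearrangements
(inversions, deletions, insertions of novel sequence), emits the chain that
*exactly* describes the constructed correspondence plus its inverse, a
simplified synteny table (aligned spans as level-1 fills; planted level-2
blocks as given), and a second methylome: noise-free fractions carried
through the map, shifted inside planted differential regions, then
re-noised and re-sampled at fresh coverage. The second genome keeps its
source chromosome names — the chain file, not the naming, distinguishes the
coordinate systems.

**What the generator does not emulate:** nucleotide sequence (no FASTA),
read-level bisulfite chemistry or conversion failure, mapping bias,
copy-number variation, correlated coverage along the genome, islands
preferentially located at promoters, and chromosome-scale differences in
PMD density. Passing tests therefore demonstrate correctness of the
*computations* on data carrying the assumed statistical structure, not
robustness to every artifact of real libraries.

# Degenerate inputs and numerical edges

* Constant tracks: density summaries return a point mass (no density
  curve); the HMM returns "no PMD structure"; `scale_track()` refuses zero
  SD.
* Fewer than 3 shared windows fail `correlate_tracks()`; fewer than 30 fail
  `differential_regions()` (difference SD unstable); fewer than 200 matched
  genes warn in `coindependence_test()`.
* Empty feature sets, zero boundaries, or zero breaks produce explicit
  not-applicable results rather than NaNs.
* Emission SDs are floored at 1e-4 and transition rows at 1e-6 to keep
  Baum–Welch finite on near-degenerate segments.
* Viterbi ties resolve to the first (lower-index) state; lift collisions
  resolve by score then source coordinate — all decoding is deterministic
  given the seed.

# Known limitations

Beta emissions and exon-restricted gene bodies are not offered; the
chi-square mode's df is approximate; the co-independence grid uses the
observed range, so extreme outliers widen bins (rank mode is the remedy);
`boundary_proximity` treats feature points, not feature intervals, as
targets; and the generator's independence of gene placement from domain
structure means boundary–gene-end proximity is only testable through
constructed scenarios, not the demo methylome.
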