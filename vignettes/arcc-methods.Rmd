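---
title: "Models and methods behind arcc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind arcc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the statistical models the package implements,
the parameters that matter, the design choices made where the
methodology left room, and what the simulation-based validation does
and does not establish.

## The data and the classification model

Accessible-region conformation capture couples light DNase I digestion
with in-situ ligation, so read pairs concentrate at accessible
chromatin. After alignment, each pair carries two independently mapped
5′ coordinates. `classify_pairs()` applies the standard quality gate —
both ends with mapping quality ≥ 30 and ≤ 2 mismatches, neither end on
a blacklist — and then splits valid pairs by geometry: different
chromosomes (*trans-informative*), same chromosome more than 600 bp
apart (*cis-informative*), or closer (*valid non-informative*, mostly
unligated fragments).

The 600 bp threshold is diagnosable from the data: ordering the two
ends by coordinate and tabulating strand configurations
(`orientation_profile()`), unligated fragments are forward–reverse,
while true ligation junctions have independent uniform strands. Below
~500 bp the FR class dominates; beyond ~600 bp all four classes sit
near 25%. The threshold is strict (601 bp qualifies). Blacklist
overlap is tested on the single 5′ base by default (`"span"` mode uses
alignment lengths when present); duplicate removal keys on both ends
after canonical ordering and keeps the first occurrence.

## Binning

Two binnings are used. Fixed-width bins (1/5/10/50 kb) serve maps and
aggregation. For interaction calling, `make_re_anchored_bins()` builds
a ~500 bp segmentation anchored on annotated regulatory elements:
elements within 100 bp are merged, each is expanded symmetrically
toward 500 bp, and the remaining genome is tiled with 500 bp intervals.
Expansion never splits an element across bins; where two elements
compete for a gap, each may claim at most half of it (an odd leftover
base goes right), which makes the segmentation deterministic without
an order-dependent greedy pass.

## Matrix normalization

Contact matrices are balanced per chromosome with the Knight–Ruiz
algorithm (`kr_balance()`), implemented as the inner–outer Newton
iteration with conjugate-gradient solves; bins without off-diagonal
counts are masked. Convergence is declared when row sums of
diag(x)·A·diag(x) are uniform to `tol = 1e-8` (relative); the test
suite checks the result against an independent Sinkhorn iteration and
verifies idempotence.

Distance-dependent background is modelled by `fit_distance_decay()`:
mean contact value per bin pair (zero cells included; pair counts per
stratum come from coordinate arithmetic, not the stored triplets) over
100 log-spaced distance strata, smoothed by a cubic smoothing spline
in log–log space with knots at every stratum and the penalty chosen by
generalized cross-validation, weighted by stratum pair counts. Fitting
is two-pass: pairs significant under the pass-1 model at FDR 0.05 are
removed and the spline refit, so strong point interactions do not
inflate their own background. `normalize_distance()` divides each cell
by F(d); cells outside the fitted range (including the diagonal) are
masked, and stratum means after normalization are ~1 by construction.

For *domain* analyses the background has a second contamination:
self-interacting domains cover most of the genome, so the plain decay
average absorbs part of the within-domain enrichment and dampens the
measured TAD strength. `fit_distance_decay(..., exclude_domains =)`
therefore fits the background from cross-domain cells only — the same
logic as the two-pass loop exclusion, applied to the structure being
measured. The compartment contrast (same-type versus cross-type
centres) is a ratio of cells at matched distances, so it is insensitive
to this choice; the TAD centre-versus-flank contrast is not.

## Interaction calling

For every retained interval pair at midpoint distance 1 kb–1 Mb the
observed count is tested against `Binomial(N, f_ij)` with
`f_ij = v_i v_j F(d_ij) / N`, one-sided. Ingredients and choices:

* **Visibility.** `v_i = (c_offpeak,i / median)^0.87`, where off-peak
  coverage excludes contacts whose partner is a top-decile-coverage
  "peak" interval — high coverage at an open interval is partly true
  signal from contacts with other open intervals, and correcting on
  raw coverage would normalize that signal away. Bottom-decile
  intervals are removed entirely. The exponent 0.87 ships as the
  default because reciprocal coverage to that power best approximates
  matrix-balancing correction factors on real accessible-chromatin
  data; `estimate_correction_exponent()` reproduces that estimation on
  any dataset, and on simulated data with purely multiplicative bin
  bias it returns ~1.0, as theory predicts.
* **Calibration.** Median-normalized visibilities have mean ≠ 1, so
  expected frequencies are computed with mean-normalized visibilities
  and one global per-chromosome constant that matches the summed
  expected count to the summed observed count over testable pairs
  (zero cells entering through stratum pair counts). Without this
  moment matching the binomial null would be off by a constant factor.
* **Multiplicity.** BH within chromosome (the model is per-chromosome
  through N, the quantiles and the median; `pool_chromosomes = TRUE`
  pools), with the number of tests equal to all testable pairs —
  zero-count pairs carry p = 1 implicitly. Calls require q < 0.05 and
  strictly more than five supporting reads. Expected frequencies are
  clipped to (1e-15, 1 − 1e-15).

On simulations matching this model (d^−1 decay, lognormal per-bin
biases, 200 planted 8-fold interactions in 2 million pairs over 5 Mb)
the realized false-discovery proportion averages well under the
nominal 0.05 (`benchmark_fdr()`), with ~30% sensitivity at that depth
— power is concentrated below ~20 kb, where expected counts clear the
five-read floor.

**Known limitation.** When accessibility bias is strongly bimodal
(e.g. a sharp element/background fold on top of lognormal noise), the
concave exponent under-corrects the very highest-coverage intervals
and pairs of them can reach significance without planted structure.
The exponent is a data-derived compromise, not a law; for a new
dataset, check `estimate_correction_exponent()` and consider its
estimate in place of the default.

## Aggregated contact analysis

`sample_site_contacts()` enumerates cis site pairs at 20 kb–1 Mb and
caps them at 50,000; `aca()` averages 21×21-bin windows (1 kb bins)
centred on each contact in the balanced, decay-normalized map and
reports log2(centre / mean of the other 440 cells). Significance comes
from `matched_null_test()`: 1000 random contact sets of the same size,
each pair matched to the corresponding observed pair's distance
stratum (20 log-spaced strata) and both ends' accessibility strata
(deciles; accessibility defaults to the site bin's cis coverage, the
assay's own accessibility readout), with
`p = (1 + #{null ≥ obs}) / (n_sets + 1)`. Empty matching strata widen
to distance-only with a message. Under a null simulation the p-values
are uniform (`benchmark_null_calibration()`, KS test). The long-range
variant (10 kb bins, 100 kb–4 Mb) is the same contract with different
parameters. HOT filtering removes the top 20% of the merged peak
universe by factor count (ties broken by genomic order; `floor` rule)
and drops factors left with fewer than 300 peaks.

Domain aggregation extracts each qualifying on-diagonal domain square
(≥ 5 kb) plus up to 25 kb of opposite-type flank (truncated to the
neighbour's extent, absent at chromosome ends), rescales domain → 9
bins and flank → 5 bins by area-weighted averaging (each target cell
averages source cells in proportion to overlap, so constant maps stay
constant), and aggregates. The strength statistic contrasts the
central 9×9 mean with four 5×10 side rectangles laid flush against the
core (top: rows 1–5 × columns 6–15, and symmetrically), a layout that
keeps side cells strictly outside the domain square;
percent difference = 100·(centre − side)/side, with a two-sided t-test
across per-domain log2 ratios. Compartment strength compares central
signal between same-type and cross-type domain pairs at 50 kb–2 Mb and
strain effects are reported as fold changes of percent differences,
flagged undefined when the mutant difference is ≤ 0 (qualitative
loss). The X chromosome is excluded from domain analyses by default
(reference domain calls do not cover it). Mark stratification takes
the top 25% of domains by signal, ties by genomic order.

Differential ACA between genotypes regresses mutant per-factor
statistics on wild-type ones (absorbing global accessibility
differences), and assesses each factor's residual against 10,000
resamples of the residual distribution, two-sided, BH-corrected.

## Expression correlation

Per linked promoter pair, Pearson correlation of expression across
cell types; for bidirectional promoters the candidate gene pair with
the highest correlation is kept. CV (sd/mean across cell types) is
computed over all genes in the matrix; "wide expression" pairs have
both genes in the bottom 30% of CV, "regulated" pairs both in the top
70% (complementary half-open cut, rank ties broken by gene order).
Controls draw the same number of random pairs from the same gene set,
matched per observed pair's distance stratum (distance between gene 5′
ends, the promoter proxy), compared by two-sided t-test. Gene marking
uses a strict 1.5×-median threshold.

## The simulator

`simulate_pairs()` draws pairs from
`P(i, j) ∝ b_i · b_j · F(|m_i − m_j|) · boost(i, j)` over 500 bp bins:
`b` is lognormal (sdlog 0.4) times an accessibility fold of 2.9 inside
regulatory elements, `F(d) = d^−γ` with γ = 1, and boosts plant loops,
within-domain enrichment and same-type compartment preference. The
factorization mirrors the calling model, so parameter recovery is
well-posed: planted boosts are implemented as additional mixture
components carrying `(boost − 1)` times the background weight of their
cells, which makes the marginal enrichment of a planted cell exactly
its boost. Sampling is exact, per chromosome: the gap distribution
comes from the decay-weighted bias autocorrelation (FFT), endpoints
per gap from the bias product (alias sampling). Strands are
independent uniform; duplicates are appended exact copies.

Defaults are the reference desk-scale conditions: two 5 Mb chromosomes,
2 million pairs, elements covering 21.1% of the genome with fold 2.9 —
chosen so that elements capture ~44% of read ends, the regime reported
for the real assay. Elements default to single simulation bins aligned
to the grid (so the fold translates exactly into that read-end share);
domain boundaries snap to a 5 kb grid, as real domain tracks are
quantized to the maps they were called on. Benchmark problem sizes —
100,000 pairs for orientation, ten 2-million-pair simulations for FDR
control, 2–4 million pairs for decay/domain/compartment/loop recovery,
200 factors × 99 permutation sets for calibration — are the package's
reference experiment definitions in `benchmark_*()`.

What the simulator does **not** emulate: sequence-level reads (no
FASTQ, no mapping artefacts), polymer physics (no loop extrusion, no
TAD corner peaks), trans contacts, copy-number structure, or
sub-bin positional bias. Passing the validation suite therefore shows
that the implementation recovers known structure generated under its
own statistical assumptions — it does not certify performance on real
libraries, where bias is not exactly multiplicative and the decay is
not a clean power law.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open throughout; pair distance is the
  absolute 5′ difference; bin-pair distance is midpoint distance
  (needed for variable-width element-anchored bins).
* Knight–Ruiz runs on the mean-rowsum-scaled matrix for conditioning,
  errors with iteration diagnostics on non-convergence, and refuses
  all-zero rows (they are masked beforehand).
* "Top/bottom fraction" rules use `floor` counts with genomic-order
  tie-breaks; quantile-threshold rules (visibility deciles) use type-7
  quantiles with ≥ / ≤ comparisons.
* Empty orientation strata report NA, not 0. Zero-variance genes and
  genes missing from the expression matrix are dropped with counts.
  Constant coverage makes the exponent scan error (correlation
  undefined). Degenerate visibility (everything peak or removed)
  errors rather than returning an empty model.
* All stochastic steps take explicit seeds and restore the caller's
  RNG state, so pipelines are reproducible end to end.
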