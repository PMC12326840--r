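---
title: "Measuring TAD conservation in syntenic blocks: models and methods"
author: "tadevolve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring TAD conservation in syntenic blocks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadevolve)
```

## The problem

Topologically associating domains partition chromosomes into contact
neighbourhoods whose borders constrain enhancer–promoter communication.
Whether that partition is an evolutionarily maintained trait or a
by-product of local sequence features is best asked inside syntenic
blocks — segments where orthologous gene order is preserved across
species — because there the borders of different genomes can be placed on
one comparable coordinate scale without liftover. `tadevolve` implements
four complementary views of conservation (TAD counts, border positions,
gene-to-TAD assignment, border edit distance) and one evolutionary model
(Ornstein–Uhlenbeck on the phylogeny) that asks *why* counts are conserved.

## Coordinates, profiles, and orientation

All internal coordinates are 0-based half-open (BED-native); the
Cyntenator-style importer converts 1-based inclusive input on read. For
each block and species, a *profile* holds

* `tad_count` — TADs overlapping the segment by ≥ 1 bp (the
  `bedtools intersect` default; a minimum-overlap fraction is available via
  `min_overlap` for sensitivity analyses);
* `borders` — every start/end of a counted TAD strictly inside the
  segment, mapped to `(p − start)/(end − start)`; inverted segments are
  reflected (`x → 1 − x`, re-sorted) so the scale always runs in the
  block's shared gene order. With contiguous TAD tilings this yields
  `tad_count − 1` internal borders; when counted TADs do not tile the
  segment, every interior endpoint is kept as a border.
* `gene_to_tad` — each gene assigned by its midpoint to the covering
  counted TAD, indexed 0-based in oriented block order. A midpoint falling
  between counted TADs leaves the gene unassigned; such genes are excluded
  from gene-level metrics (and logged). Midpoint assignment is
  deterministic and independent of gene order, at the cost of ignoring
  genes straddling a border — acceptable at TAD-scale (hundreds of kb)
  versus gene-scale (tens of kb) lengths.

Normalized borders are invariant under affine shifts of the coordinate
system, and reflecting a segment twice restores the original border set;
both properties are regression-tested.

## TAD-number conservation

The relative difference in counts uses the symmetric mean denominator,
`RD = |T_i − T_j| / ((T_i + T_j)/2)`, bounded by 2, zero for equal counts,
and defined as 0 when both counts are 0. The ARD is the unweighted mean of
`RD` over shared blocks — unweighted because each block is one evolutionary
observation regardless of its length; a length-weighted variant would
conflate the count statistic with the rate normalisation that the
regression below handles explicitly.

The permutation null permutes one species' per-block count vector across
blocks while holding the other fixed — equivalent to shuffling block order
for one species — and recomputes the ARD each time. Conservation means
*small* observed ARD, so the empirical p-value is the lower-tail add-one
estimator `(1 + #{null ≤ obs})/(N + 1)`, never exactly zero, with minimum
`1/(N+1)` at `N` permutations. The companion `fold_vs_null`
(observed/mean-null) tends to 1 when the two species' counts are
independent, a calibration property checked by simulation.

The rate of change per pair is the mean over blocks of
`|T_i/L_i − T_j/L_j|` with each species' own segment length in Mbp —
lengths differ between genomes, so a shared denominator would bias pairs
with asymmetric assemblies. The slope of these pair means against
divergence time (OLS) is reported in TADs·Mbp⁻¹·Myr⁻¹, with the usual
caveat that a linear trend is only a summary of a saturating process.

## Border positions

Only blocks where both species hold the same number of TADs (≥ 2) enter the
border comparison: equal counts make rank matching well-defined — the k-th
smallest normalized border of one species pairs with the k-th of the other.
Rank inversions between species are still paired by rank; the mean absolute
difference then counts the inversion's displacement rather than attempting
a combinatorial re-matching. Pair-level summaries are the pooled mean
absolute difference (a fraction of block length), its divergence-normalised
variant (per Myr), and the coefficient of determination of `y ~ x` on the
pooled scatter. R² is computed on pairs pooled across blocks — per-block R²
would be dominated by blocks with one or two borders — and is symmetric in
the two species by the correlation-squared identity of simple regression.
A constant-`x` pool leaves R² undefined; it is returned as `NA` with a
warning rather than silently dropped.

## Gene–TAD conformation and the edit distance

The canonical encoding of "which genes share a TAD" is the *cut set*: over
the block's ordered shared ortholog list `g_1 … g_n`, cut `c` is present
when `g_c` and `g_{c+1}` lie in different TADs. A gene is *conserved* when
its oriented TAD index is equal in both species — no partial credit for
adjacent TADs, since the biological question is co-residence, not distance.
The same-TAD count is normalised per Mbp (mean of the two segment lengths)
and per Myr of divergence.

The null reassigns each shared gene of one species an independent uniform
TAD index in `[0, tad_count)`, exactly preserving the number of genes per
block and the block's TAD count, and uses the upper-tail add-one p-value
(conservation = more same-TAD genes than chance). The null's expected
same-TAD count has the closed form `Σ_blocks n_genes/tad_count`, which the
test suite verifies at 10⁴ permutations. An order-preserving shuffle would
preserve more structure but is not uniquely implied by the preserved
marginals; the uniform model is the default and the property the acceptance
checks rely on.

The border edit distance between two conformations is the minimal number of
single-border insertions or deletions converting one gene partition into
the other. Because one edit changes exactly one cut, the minimum is the
symmetric difference of the two cut sets — proven minimal by that
observation and verified exhaustively against breadth-first search over
single-edit moves for all partition pairs of up to six genes. It is a
metric on partitions (symmetry, identity, triangle inequality tested
exhaustively). No equal-count requirement applies; the distance is reported
per Mbp using the mean of the two segment lengths.

## The Ornstein–Uhlenbeck model

Per-block TAD counts across the tips of the phylogeny are modelled as an OU
process `dX_t = −α(X_t − ϑ)dt + σ dB_t`: α (Myr⁻¹) is the strength of the
pull toward the optimum — stabilising selection — and σ the intensity of
stochastic change — drift. Integer counts are modelled as continuous. On an
ultrametric tree the tip covariance is

$$V_{ij} = \frac{\sigma^2}{2\alpha} e^{-\alpha t_{ij}}\left(1 - e^{-2\alpha t_{ra}}\right),$$

where `t_ij` is the time separating tips i and j and `t_ra` the time from
the root to their most recent common ancestor (so the diagonal is
`σ²/(2α)(1 − e^{−2αT})` with tree height `T`, and the α → 0 limit is the
Brownian covariance `σ² t_ra`, verified numerically at α = 10⁻⁶). The
expected tip values are `Cϑ` with `C_i = (e^{−α t_ia}, 1 − e^{−α t_ia})`
and `ϑ = (ancestral state, optimum)`; rows of C sum to 1.

**Identifiability on ultrametric trees.** Every `t_ia` equals the tree
height, so the two columns of C are proportional and `CᵀV⁻¹C` has rank 1
for *every* α — only the scalar mean `C_i·ϑ` is identified, never the
ancestral state and optimum separately. `gls_theta()` therefore returns the
minimum-norm ϑ via the SVD pseudoinverse and flags the fit degenerate; the
profile likelihood, which depends on ϑ only through `Cϑ`, is unaffected.
On non-ultrametric designs (used in tests) the full 2-vector is estimable
and GLS reduces to OLS when `V = I`.

**Fitting.** ϑ is profiled out by GLS at each lattice point and the
Gaussian log-likelihood
`−½[n log 2π + log|V| + (y − Cϑ)ᵀV⁻¹(y − Cϑ)]` is maximised over a
100 × 100 lattice on [0.01, 10] for both α and σ. The lattice is *linear*
by default: α and σ are reported at two-decimal granularity and, in the
large-α regime where the likelihood constrains only the stationary variance
`σ²/(2α)` (see below), the lattice's sampling measure determines where
along that ridge the arg-max lands, so evenly spaced values give evenly
spaced reporting; `ou_grid(scale = "log")` is available. Because
`V = σ²M(α)`, the GLS mean and quadratic form are computed once per α
(one Cholesky of `M`, shared across all blocks) and the σ axis is evaluated
in closed form — 200 blocks × 10⁴ lattice points fit in well under a
second. Ties are broken toward the smallest α, then smallest σ.

**What the fit can and cannot resolve.** With tree height ~100 Myr,
`e^{−α t}` is numerically zero for α ≳ 1 at any realistic divergence, so
data simulated (or evolved) at large α constrain α only through "large":
the likelihood is flat along the ridge `σ²/(2α) = const`. Per-block
arg-maxima therefore scatter along that ridge, a sizeable minority of
blocks overfit low-α phylogenetic correlation (≈ one third at 10 tips), and
per-block point estimates of α should be read as regime indicators —
drift-floor versus away-from-floor — not as calibrated rates. This is why
block classification uses the threshold "α̂ at the lattice floor"
(`alpha_threshold = 0.01`, inclusive): no fitted α can be strictly below
the floor, and the floor is exactly where Brownian-like blocks accumulate
(> 50 % of BM-simulated blocks in the acceptance checks; ~80 % on the
mammal-like fixture). Conversely, blocks with little or no cross-species
count variance carry almost no information; their fits collapse toward the
smallest-σ lattice edge and can dominate the *modal* (α, σ) combination
even when the classification fractions are unambiguous — the modal cell is
reported for completeness but is the most fragile summary the model
produces. Some truly-OU blocks with low variance also land on the drift
floor, so the drift percentage is an upper bound on genuinely neutral
blocks. OU fitting is complete-case: blocks missing any tip of the chosen
clade are excluded rather than imputed.

## The synthetic-data generator

`simulate_dataset()` emulates the data a cross-species TAD study produces,
so that every stage runs and is validated without external data:

* **Tree** — either a supplied phylogeny, the fixed synthetic mammal-like
  fixture `mammal_tree()` (10 tips, height 100 Myr, TimeTree-style nested
  splits from 6 to 100 Myr), or a rescaled random coalescent topology.
* **Traits** — per block, one *exact* multivariate-normal draw of tip
  values from the OU mean/covariance above (or BM), with no time-stepping
  and hence no discretisation error; values are rounded to non-negative
  integers because they are TAD counts. Defaults: α = 5, σ = 2, optimum 6.
  By default the optimum scales with block length
  (`theta_scale = "length"`), so TAD *density* is the conserved quantity —
  without this, all blocks share one optimum and, under strong selection,
  cross-species block-level correlation vanishes, which is not how synteny
  data behave.
* **Blocks** — lognormal lengths (median 5 Mbp, sdlog 0.4, ±5 %
  per-species variation), 2 + Poisson(6) genes placed at shared relative
  positions (identical ortholog order; optional inverted orientation per
  species), laid end to end on one simulated chromosome per species.
* **Borders** — descend from shared ancestral fractions, receive Gaussian
  jitter (sd 0.04–0.05 of block length by default, matching the ~9–14 %
  matched-border displacement scale typical of mammal-to-vertebrate
  comparisons) and Poisson insertion/deletion events at 0.004 events/Mbp
  per Myr of root-to-tip time (matching the ~0.4–1 edits/Mbp scale), then
  are reconciled — uniformly random additions/removals — so the realized
  TAD count always equals the simulated trait, including after
  base-pair-rounding collisions. Traits below 1 are clamped to 1 and
  logged.

What the generator does *not* emulate: assembly errors and missing
orthologs, TAD-caller resolution effects, nested/overlapping domain
hierarchies, genome rearrangements within blocks, and any sequence-level
realism. Passing tests therefore demonstrate that the statistics measure
what they claim on data with the assumed structure — not that real Hi-C
TAD calls satisfy those assumptions.

## Numerical and design choices

* Borders are realized on integer base-pair coordinates; since species'
  segment lengths differ, "identical" border fractions agree only to
  sub-bp quantisation (~10⁻⁷ of a 5-Mbp block). Zero-noise regression
  tests assert `< 10⁻⁶` rather than exact zero for this reason; all other
  degenerate limits (ARD 0, edit distance 0, 100 % same-TAD) are exact.
* Empirical p-values use the add-one estimator on both tails; they are
  never 0 and are reported raw per species pair, with a Benjamini–Hochberg
  column added in the pipeline table as a labelled extension.
* One master seed drives a deterministic sub-stream per stage, so adding
  permutations to one analysis never shifts another's draws; identical
  configurations give byte-identical outputs (tested by digest).
* Degenerate GLS systems are resolved minimum-norm with a warning, never
  silently; unfittable lattice blocks (no finite point) are flagged, not
  dropped quietly.
* Problem sizes in the shipped checks — 200-block datasets, 300-block
  recovery runs, 50 × 500-block null-calibration replicates, 1000
  permutations in the acceptance script — were chosen so the entire suite
  and script complete in about a minute while leaving Monte-Carlo error
  well inside every asserted tolerance.

## Known limitations

* Border correspondence is by rank within equal-count blocks; blocks whose
  counts differ contribute no border pairs, so border summaries condition
  on count conservation.
* The per-Myr normalisations divide by pairwise divergence time per pair
  and then average; other orderings of that normalisation exist in the
  literature and give numbers on different scales.
* The OU machinery assumes an ultrametric, error-free tree; divergence-time
  misspecification propagates directly into α and σ.
* Integer counts are treated as Gaussian; for blocks with very few TADs a
  count model (e.g. phylogenetic Poisson) would be more faithful than
  rounding.
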