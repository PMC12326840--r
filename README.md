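# tadevolve

Quantifying the evolutionary conservation of topologically associating
domains (TADs) within syntenic blocks across a time-calibrated phylogeny.

Topologically associating domains are chromatin segments with elevated
internal Hi-C contact frequency, delimited by borders that constrain
regulatory interactions. Syntenic blocks — genomic segments with preserved
orthologous gene order across species — provide the coordinate system in
which TAD organisation can be compared between genomes without liftover.
`tadevolve` takes per-species TAD calls (BED), syntenic blocks with ordered
ortholog lists (TSV), and an ultrametric phylogeny with divergence times in
Myr (Newick), and asks: are TAD numbers, border positions, and gene-to-TAD
assignments conserved beyond chance, and where they are, is that
conservation maintained by stabilising selection or merely by shared
ancestry and drift?

## The statistics

**TAD-number conservation (ARD).** For species *i*, *j* and block *k* with
TAD counts `T_i,k`, `T_j,k`, the symmetric relative difference is

    RD_ij^k = |T_i,k − T_j,k| / ((T_i,k + T_j,k)/2)

and the ARD is its unweighted mean over blocks. Significance comes from a
permutation null that shuffles one species' count vector across blocks
(1000 permutations, add-one lower-tail empirical p): conserved pairs show
ARD well below the null (fold &lt; 1). The rate of TAD-number change is the
OLS slope of per-pair mean |ΔT per Mbp| against divergence time
(TADs·Mbp⁻¹·Myr⁻¹).

**Border-position conservation.** Within blocks where both species carry the
same number of TADs (≥ 2), border positions are normalised to the (0, 1)
scale of the block (orientation-corrected for inverted segments), matched by
rank, pooled across blocks, and summarised as the mean absolute difference
of matched positions and the R² of one species' positions regressed on the
other's.

**Gene–TAD conformation.** A gene "stays" when its oriented TAD index is
equal in the two species; a uniform-reassignment null (preserving gene
counts and TAD counts) calibrates the same-TAD count. Between any two
conformations, the border **edit distance** is the minimal number of
single-border insertions/deletions converting one gene partition into the
other — realised exactly as the symmetric difference of the partitions' cut
sets — reported per Mbp.

**Ornstein–Uhlenbeck model.** Per-block TAD counts evolve along the tree as
`dX_t = −α(X_t − ϑ)dt + σ dB_t`. Tip covariance
`V_ij = σ²/(2α)·e^(−α t_ij)(1 − e^(−2α t_ra))` (with `t_ij` the time
separating tips and `t_ra` the root-to-MRCA time) and design matrix
`C_i = (e^(−α t_ia), 1 − e^(−α t_ia))` give the GLS estimate
`ϑ = (CᵀV⁻¹C)⁻¹CᵀV⁻¹y`, profiled into a Gaussian log-likelihood maximised
on a 100 × 100 (α, σ) lattice over [0.01, 10]. Blocks whose fitted α sits at
the lattice floor are indistinguishable from Brownian drift; the rest carry
a signature of stabilising selection on TAD number.

A seeded synthetic-data generator (`simulate_dataset()`) produces
phylogenies, blocks, gene annotations and TAD tracks with controllable
jitter, border indel rates and OU/BM trait regimes, so the whole pipeline is
testable end to end without any external data.

## Worked example

```r
library(tadevolve)

tree <- mammal_tree()                      # fixed 10-tip, 100-Myr fixture
cfg  <- sim_config(seed = 42, tree = tree, n_blocks = 120)
ds   <- simulate_dataset(cfg)              # blocks + TAD tracks + genes

profiles <- build_block_profiles(ds$blocks, ds$tracks)

ard_null(profiles, "human", "mouse", n_permutations = 1000, seed = 42)
#> <ARD human vs mouse: 0.1304 (0.30-fold vs null, p = 0.000999, 120 blocks)>

cmp <- compare_borders(profiles, "human", "mouse", tree = tree)
#> border MAD: 0.120 over 46 equal-count blocks (R^2 = 0.65)

counts <- profile_counts(profiles)
fit <- fit_ou_grid(counts[complete.cases(counts), ], tree)
classify_blocks(fit)
#> <ou_classification: 120 blocks, 88.33% selection / 11.67% drift
#>  (alpha <= 0.01); modal (alpha, sigma) = (0.01, 0.111)>
```

Reading: human–mouse TAD counts differ by 13% on average across blocks —
0.30-fold of what block shuffling produces, so TAD numbers are strongly
conserved (p ≈ 0.001). Matched borders sit ~0.12 block-lengths apart. The
per-block OU fits place 88% of blocks away from the drift floor,
i.e. their TAD counts are pulled toward an optimum rather than wandering.
(The modal lattice cell here sits at the drift corner because many small
simulated blocks have zero cross-species count variance; see the methods
vignette.)

File-based inputs work identically through `run_config()`/`run_all()`, which
also write one TSV per analysis plus a JSON run manifest.

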