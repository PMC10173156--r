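---
title: "Methods: dosage-based curation of a polyploid genebank collection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dosage-based curation of a polyploid genebank collection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`polycore` implements the analysis chain used to curate clonal potato
genebank collections genotyped with biallelic SNP dosages: quality
control, ploidy inference, diversity and structure statistics, and
genetic-distance-optimized core collection selection with phenotypic
validation. This vignette documents the models, the parameters that
matter, the numerical choices, and what the synthetic-data tests do and
do not establish.

## The dosage model

All genotypes are consumed on the tetraploid scale: a call at a biallelic
marker is the count 0–4 of the alternate allele (AAAA … BBBB). Diploid
accessions genotyped on this scale yield (almost) only 0, 2 and 4,
because their two alleles are each reported twice. Every downstream
statistic treats a call as a within-individual allele frequency
`p = dosage / 4`, regardless of the sample's true ploidy — this is how
the data are coded, and it keeps diploids and tetraploids in one matrix
without re-scaling. Missing calls are `NA` (`.` alleles in VCF input).

## QC filtering

`filter_dosage()` removes markers with minor allele frequency below
`maf_min = 0.03` or missingness above `missing_max = 0.05`, then samples
with missingness above the same threshold — the standard array-QC
thresholds for this kind of panel. Allele frequencies use the tetraploid
denominator (4 per call) throughout.

One contract decision deserves a note: the filter is *idempotent*.
Removing samples can push a marker's recomputed missingness or MAF past
a threshold, so a literal single pass does not guarantee that the output
would survive re-filtering. `filter_dosage()` therefore repeats the
marker-then-sample pass until a fixed point; on realistic panels
(hundreds of samples, a few percent missingness) the first pass is the
only one that removes anything, and the removal report remains
deterministic.

## Ploidy inference

The classifier is the frequency of simplex and triplex calls (dosage 1
or 3) among a sample's non-missing calls. Its defaults encode the
published windows: ≤ 15% → diploid, > 20% → tetraploid, the 15–20% grey
area → unknown. Boundary conventions are deterministic choices the
ranges themselves leave open: a frequency exactly at `dip_max` is
diploid (closed lower class), exactly at `tet_min` is unknown (open
upper class). The method cannot discriminate triploids, which land in
intermediate frequencies; `classify_ploidy()` never emits "triploid",
and reference triploids are excluded from the accuracy denominators of
the other classes in `concordance()`.

`calibrate_thresholds()` proposes panel-specific thresholds as the
trimmed extremes of the reference classes (top/bottom 5% treated as
off-types — reference panels demonstrably contain admixed samples at
24–41% among cytological diploids). When the trimmed ranges overlap it
falls back to the defaults with a warning rather than inventing a
boundary inside overlapping distributions.

## Diversity statistics

**Observed heterozygosity** counts dosages 1–3 as heterozygous — on the
tetraploid scale these are exactly the calls carrying both alleles.

**Modified Rogers distance** between samples i and j is the root mean
squared difference of within-individual allele frequencies over the
markers non-missing in *both* samples (`L_ij` pairwise-complete
normalization). For biallelic loci this equals the classical
`(1/sqrt(2L)) * sqrt(ΣΣ Δp²)` form and is bounded in [0, 1].
Pairwise-complete handling avoids imputation bias at the ~5% missingness
the QC admits; the cost is that with missing data the matrix is not
exactly Euclidean, which is why the AMOVA operates on squared distances
directly rather than on an embedding.

**F_ST** is a Nei-style gene-diversity ratio per group pair:
per-locus `H_S` (mean within-group `2p(1−p)`) and `H_T`
(`2·p̄(1−p̄)` at the unweighted mean frequency), with
`(H_T − H_S)/H_T` averaged over loci with `H_T > 0`. The mean-of-ratios
aggregation follows the module contract; a ratio-of-sums G_ST would
differ slightly. The estimator is deliberately simple and documented so
its values are *comparable*, not identical, to other packages'
F_ST implementations. Significance comes from permuting group labels.

**AMOVA** is the one-level distance-based decomposition: total and
within-group sums of squares from squared distances
(`SS = Σ_{i<j} d²/n`), among-group SS by difference, variance components
from the mean squares with the standard coefficient
`n0 = (N − Σ n_g²/N)/(K−1)`, and `Phi = σ²_a/(σ²_a + σ²_w)`. Negative
among-group components are truncated at zero and flagged — standard
practice for near-null data. The permutation p-value uses the +1
correction, so with the default 999 permutations the smallest attainable
p is 0.001; reported percent-among and percent-within sum to 100
exactly.

## Structure

PCA mean-imputes missing calls per marker, centers columns, and takes an
SVD. Markers are *not* variance-scaled: dosages share one scale, and
scaling would up-weight near-monomorphic markers; this changes
percent-variance values and is therefore stated. The number of groups is
chosen by fitting seeded k-means (best of ≥ 10 restarts) on the first
three components for each candidate K and taking the majority vote of
mean silhouette width and the Calinski–Harabasz index; on disagreement
the smaller K wins and the result is flagged low-confidence. The
Bayesian admixture model and ΔK of external structure software are out
of scope; the two indices used are the most widely validated of the
usual index suite.

## Core selection

The objective is the average Accession-to-Nearest-Entry distance: each
accession is represented by its closest selected entry, and entries
represent themselves at distance 0, so A-NE = 0 iff everything is
selected and minimizing A-NE yields cores that cover the collection
uniformly. Entry counts are `round(fraction × n)` with halves up — the
only rounding consistent with the published 39/129/194/258 at
3/10/15/20% of 1,291.

The optimizer is a seeded multi-start steepest-improvement swap local
search: a greedy start (medoid, then repeatedly the accession whose
addition most lowers A-NE) plus random starts; each iteration applies
the single entry/non-entry swap with the largest improvement, using
cached nearest/second-nearest entry distances. Scan order and
tie-breaks follow ascending accession position, so runs are exactly
reproducible for a seed. A parallel-tempering engine à la Core Hunter is
*not* reproduced — the contract is the objective, and on exhaustively
solvable instances (n ≤ 12, k ≤ 4) the search attains the global
optimum on ≥ 95 of 100 seeded random instances in the acceptance suite,
which bounds the optimality gap at test scale. E-NE and E-E are reported
for evaluation only; they are maximization-flavored metrics that a
uniform-coverage core is expected to score lower on.

Mini-core nesting replaces each 3%-entry missing from the 10% core with
its nearest unused core entry, processing replacements in ascending
order of replacement distance (ties by id) so collisions resolve
deterministically: the nearer competitor wins, the other takes its
next-nearest unused entry. Only the single-entry case is externally
specified; the collision rule is this package's.

## Phenotypic validation

Gower distances over the three tuber traits reduce, for all-numeric
traits, to the range-normalized mean absolute difference over the traits
non-missing in both accessions (computed via `cluster::daisy`). Trait
ranges are always taken from the *full* phenotype table, not per subset,
so whole-collection and core distances are comparable — the alternative
(subset-local ranges) would silently re-scale every comparison.
Zero-range traits are dropped with a warning; a pair sharing no
non-missing trait is an error rather than a silent hole. Summary
statistics use the sample (n−1) standard deviation and CV = 100·sd/mean.

## The simulator: what it emulates, what it does not

`simulate_panel()` draws, per marker, an ancestral frequency from
U(0.05, 0.95) and per group a Balding–Nichols frequency
`Beta(p(1−F)/F, (1−p)(1−F)/F)` — the simplest divergence model with one
interpretable parameter per group. Calls are Binomial(ploidy, p) mapped
to the tetraploid scale: diploid genotypes are doubled ({0,2,4}),
triploid genotypes g map to round(4g/3) ({0,1,3,4}), a pragmatic
stand-in that lands triploids in intermediate simplex/triplex
frequencies and exercises the "unknown" class. Dosage errors are ±1
shifts with probability `miscall_rate` (neighboring-cluster miscalls
dominate array dosage errors; arbitrary recalls would be unrealistically
harsh). Missingness is uniform. Replicate pairs re-apply error and
missingness to the same underlying genotype. Defaults describe a
two-group panel of 60 diploids and 120 tetraploids, F = 0.25, 1,000
markers, 1% miscalls, 2% missing, 5 replicate pairs — a desk-scale
stand-in for a mixed-ploidy Andean collection.

Reference evidence is simulated as exact chromosome counts (12 ×
ploidy) and Normal chloroplast counts with the published diploid and
tetraploid means (7.6 ± 0.83 and 13.2 ± 1.06 per guard cell); triploids
get Normal(10, 1), a documented midpoint choice. Phenotypes are group
means plus Normal noise clamped at zero; at the default
`effect_size = 1` the between-group variance of the means equals the
within-group noise variance (detectable but not degenerate), and
`effect_size` scales the separation for experiments needing strongly
group-determined traits.

The simulator deliberately omits: linkage between markers, pedigree
structure, admixed individuals, intensity-level array artifacts, and
genotype–phenotype association beyond group membership. A green test on
synthetic panels therefore establishes that the *algorithms* recover a
known generative truth — not that the thresholds or statistics are
optimal for any particular real collection.

## Numerical and testing choices

- All randomized routines take explicit seeds, save and restore the
  caller's RNG state, and are reproducible to the byte.
- Permutation p-values use the +1 correction with floor
  `1/(n_perm + 1)`.
- The AMOVA null-calibration check ("non-significant in ≥ 95% of null
  replicates") sits exactly at the test's type-I rate and is therefore
  intrinsically borderline: the permutation test was verified to reject
  at ≈ 4–5% under the null over hundreds of replicates, and the
  acceptance suite pins one deterministic seeded configuration (fresh
  simulated panel per replicate, 999 permutations).
- The published headline values from the full 1,291-sample collection
  (Φ = 0.359, group Ho 0.14/0.37/0.53, PC1 = 19.94%) depend on an
  undeposited dataset and are *not* claimed by any test; the worked
  examples that are recomputable from printed counts (accuracies 92.8%
  and 96.3%, the 89.2% chloroplast window, the 39/129/194/258 core
  sizes, the 90.9% and 94.3% ratios) are pinned exactly.

## Known limitations

Single-level AMOVA only; no LD, kinship or admixture estimation; the
F_ST estimator is a comparability-oriented simplification; core
selection optimizes the single A-NE objective (no multi-objective
weighting or stratified selection); phenotype validation assumes
per-accession trait means from multi-year data are supplied as such.
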