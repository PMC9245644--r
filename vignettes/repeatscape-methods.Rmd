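---
title: "Methods and design of repeatscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of repeatscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscape)
```

# Scope and model

`repeatscape` compares transposable-element (TE) landscapes — repeatomes
— across genome assemblies. It takes RepeatMasker-style annotation
tables, repeat consensus libraries, gene annotations, genome indices and
a time-calibrated phylogeny, and produces five kinds of results:

1. a partition of the consensus library into clusters at a fixed
   sequence-identity threshold;
2. per-genome occupancy matrices (proportion of assembly covered, by
   class taxonomy or by cluster) and fixed-width windowed density
   tracks;
3. principal-components ordination of genomes in repeat space plus
   rank-abundance distributions (RADs) of clusters;
4. resampling-based tests for repeat enrichment in the flanking
   vicinity of focal gene families, with empirical p-values and
   Benjamini–Hochberg (BH) FDR control across repeat categories;
5. phylogenetic generalized least squares (PGLS) regression of repeat
   proportion on assembly size under Brownian motion.

Every coordinate inside the package is 0-based half-open; `.out` and
GFF3 files (1-based inclusive) are converted exactly once, at the I/O
boundary. Overlap-flagged `.out` records are retained by the parser —
de-duplication is a quantification concern, handled by interval
merging, never by the parser.

# Sequence identity and greedy clustering

The library clustering emulates classic centroid clustering at a fixed
identity threshold θ (default 0.80). Identity between two sequences is
defined on a global alignment under unit edit costs (match 0,
mismatch 1, gap 1) as

$$\mathrm{id}(a,b) = \frac{\#\text{matching columns}}
{\#\text{alignment columns (gaps included)}},$$

with a deterministic traceback (diagonal preferred over vertical over
horizontal on cost ties) so the value is identical across platforms and
against the test suite's independent dynamic-programming oracle. Two
identical sequences score 1; a 10-mer with two substitutions scores
0.8. This "matches over columns" definition is the common
clustering-tool default; the threshold, not the fine definition, is the
scientifically meaningful parameter.

The greedy rule: sequences are processed in length-descending order
(ties broken by name); each sequence joins the *first* centroid, in
centroid-creation order, with identity ≥ θ, otherwise it founds a new
centroid. This is first-match assignment, not single linkage: a chain
A–B (0.88), B–C (0.88), A–C (0.76) yields clusters {A, B} and {C}. A
shared-k-mer prefilter (k = 8, minimum shared fraction 0.05) skips
hopeless centroid comparisons; it is an optimization only and can be
disabled (`min_kmer_fraction = 0`), which is how the oracle-equivalence
tests run. Reverse-complement comparison is off by default because
library consensus orientation is normally consistent; a flag enables
it.

# Occupancy, windows, and the union convention

Occupancy is merged base pairs per category divided by assembly size.
Within a category, overlapping hits are merged — the only convention
that keeps cells ≤ 1. Across categories, overlap counts once toward the
genome-level total (`total_repeat_proportion` is computed on the union
of all hits), so the total is bounded by the sum of the per-category
cells with equality exactly when categories never overlap. Strand is
ignored throughout. Window tracks tile each sequence with fixed windows
(default 100 kb); the trailing partial window uses its true length as
denominator, which makes per-window occupied base pairs sum exactly to
the per-sequence merged totals (a conservation law the tests assert).

Class-level ordination runs on *within-repeatome relative frequencies*
(each genome's class vector rescaled to sum to 1) — the compositional
view; cluster-level ordination runs on proportions of assembly size.
PCA is centered and unscaled by default since both inputs are
commensurate proportions; `scale = TRUE` is available because the
choice is not settled in comparative practice. Loading columns are
sign-fixed (largest-magnitude element positive) for backend-independent
determinism. RADs sort cluster abundances in decreasing order with ties
broken by cluster id and truncate to the top 100 by default.

# The resampling enrichment test

For a focal gene family of size *m*, the observed statistic is the
pooled repeat density of the merged regions obtained by extending each
gene span by 1 kb on both sides (clipped to its sequence): occupied
bp / region bp. The null distribution comes from N = 499 random
*m*-gene groups drawn from the genome's gene complement, each processed
identically. We report

- fold enrichment = observed / mean(null densities), and
- a one-sided add-one empirical p-value
  $p = (\#\{d_{null} \ge d_{obs}\} + 1)/(N + 1)$,

whose smallest attainable value at N = 499 is exactly 1/500 = 0.002.
The pooled-density statistic (rather than a per-gene distribution
comparison) is the form that makes "x-fold enriched" well defined.
`scan_categories()` tests many repeat categories against the *same*
null group draws, which removes between-category Monte-Carlo variation,
then applies BH step-up across the family at level 0.1 by default.
Length-matched null sampling (decile stratification on gene length) is
available but off by default — the plain design resamples genes
uniformly.

## Exclusion of focal genes, exchangeability, and calibration

By default the focal genes are excluded from the null pool
(`exclude_focal = TRUE`), which prevents the planted/true signal from
contaminating the null mean and therefore stabilizes the fold estimate.
The cost is exactness of the p-value: with exclusion, the focal set and
the null groups are no longer draws from one pool, joint
exchangeability fails, and the empirical p-value is valid only
asymptotically in the number of genes. The effect is invisible at
realistic gene counts (m of order 10 against tens of thousands of
genes) but measurable in miniature worlds: with m/|G| = 8/40 we
observed rejection rates of ~0.11 at nominal 0.05. The calibration
property test therefore runs with `exclude_focal = FALSE`, the regime
in which the p-value is exactly super-uniform by exchangeability; the
FDR benchmark does the same because BH control presupposes valid
p-values. Fold estimation keeps the default exclusion.

# PGLS under Brownian motion

For traits on the tips of an ultrametric, time-calibrated tree, the
Brownian expectation gives trait covariance proportional to shared
branch length: $V_{ij}$ is the root-to-MRCA path length of tips *i*,
*j*. `pgls_fit()` estimates $y = a + bx$ by generalized least squares,
$\hat\beta = (X^\top V^{-1}X)^{-1}X^\top V^{-1}y$, computed through the
Cholesky factor of V (the model is whitened, never explicitly
inverted), with $\hat\sigma^2 = r^\top V^{-1} r/(n-2)$ and a Student-t
test on n − 2 degrees of freedom — for 16 taxa, 14 df, matching the
convention of reporting $t_{16,14}$. No Pagel's-λ or other branch
transform is applied. Two exact limits anchor the implementation: on a
star phylogeny PGLS coincides with OLS (to 1e−10 in the tests), and
multiplying all branch lengths by a constant leaves estimates, t and p
unchanged. Perfect fits are reported with an overflow-safe p floor
rather than p = 0. Assembly size is expressed in Mb so a slope of
around 5 × 10⁻⁴ (repeat proportion per Mb) is well scaled.

# The synthetic-data generator

`plant_genome()` builds a fully synthetic annotated genome that states
its truth: a consensus library over a class taxonomy (defaults carry
the classes prominent in teleost repeatomes — BovB and Rex-Babar
LINEs, Tc1/Tigger/Charlie DNA transposons, and unclassifiable
repeats), repeat copies placed as a Poisson process, non-overlapping
uniformly placed gene models, and optional planted regional
enrichments. Two numerical choices matter:

- **Overlap correction.** A merged-density target d is realized with
  raw Poisson coverage $c = -\log(1-d)$, so planted folds are folds of
  *merged* (observable) density rather than raw copy mass; without
  this, planted folds would be biased low by copy overlap (about 8% at
  the strong-fold settings).
- **Edge-uniform enrichment placement.** Extra copies for an enriched
  region are drawn with start positions in [region start − copy
  length, region end) and clipped to the region, which makes expected
  extra coverage uniform across the region rather than sagging at the
  edges.

The truth record stores planted *and realized* quantities (realized
region density, realized background density, realized fold), so tests
can separate estimator error from generator sampling noise. Everything
is a pure function of (config, seed).

What the generator does *not* emulate: insertion bursts and age
structure, nested insertions, target-site preference, GC or gene-density
covariation, and sequence-level alignability (emitted FASTA is
table-faithful, not alignment-faithful). A green recovery test
establishes that the estimators recover planted truth under the model's
assumptions — not that those assumptions hold in real genomes.

# Benchmark worlds (fixed designs)

The acceptance benchmarks in `R/benchmarks.R` state their worlds once:

- **Fold recovery** (`benchmark_fold_recovery()`): a 10-Mb
  two-chromosome genome, 500 genes of 4 kb, background merged densities
  0.10 (BovB-like, ~100-bp copies) and 0.18 (Tc1-like, ~120-bp copies).
  The strong design plants fold 4.24 around a 9-gene family; the weak
  design plants fold 1.39 around a 60-gene family. Region totals
  (~45 kb and ~300 kb) were sized a priori so the Monte-Carlo sd of the
  realized fold is ~5–8%, comfortably inside the ±15% recovery band.
- **FDR** (`benchmark_fdr()`): 200 independent 2-Mb genomes, 20
  categories at density 0.012, two planted at fold 3 around one
  12-gene family; scan at N = 499, BH level 0.1. The theoretical FDR is
  q·m₀/m = 0.09; the mean realized false-discovery proportion over 200
  replicates carries a Monte-Carlo se of roughly 0.012, so single runs
  can graze the 0.1 bound even though control holds in expectation.
- **PGLS recovery** (`benchmark_pgls_recovery()`): a random 16-tip
  ultrametric tree of depth 1, assembly sizes 300–1400 Mb on a fixed
  grid, slope 4.8 × 10⁻⁴, Brownian rate set so the regression R² is
  about 0.6; 500 replicate trait sets.

# Degenerate inputs and numerical conventions

- Empty `.out` bodies parse to empty hit tables; malformed records are
  rejected with their line number.
- Bookended intervals (zero gap) merge; all totals are computed on
  merged sets.
- Zero-variance columns are dropped (with a warning) before scaled PCA.
- A null mean of zero reports fold as `Inf` with the p-value still
  valid; empty region sets and undersized null pools are errors.
- Ties in rank-abundance and in clustering order are broken by
  identifier, making every output deterministic.
- All stochastic stages take explicit integer seeds; sub-seeds are
  derived from one master seed so stages never share RNG streams.

# Known limitations

- The clustering is an algorithmic analog of fixed-identity centroid
  clustering, not a byte-level reproduction of any specific external
  tool.
- The enrichment test measures pooled density; per-gene distributional
  comparisons (and depletion tests) are out of scope.
- PGLS is single-predictor Brownian only; no λ/OU transforms,
  no ancestral-state machinery.
- Divergence-binned repeat landscapes (Kimura plots) and per-copy age
  estimation are out of scope.
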