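# repeatscape

Comparative repeatome analysis for genome assemblies: quantify where
transposable elements (TEs) sit in a genome, how repeat content differs
among species, and whether particular repeat classes are enriched
around gene families of interest.

The package is aimed at comparative genomicists who already have repeat
annotations (RepeatMasker-style `.out` tables plus a consensus library)
and gene annotations (GFF3) for one or more assemblies and want a
tested, deterministic pipeline for the downstream comparative
statistics, together with a synthetic-data generator that plants known
truth so every estimator can be validated end to end.

## What it computes

- **Library clustering** — greedy centroid clustering of repeat
  consensus sequences at a fixed identity threshold (default 80%):
  sequences are processed longest-first and join the first centroid
  with alignment identity ≥ θ, where identity = matching columns /
  alignment columns of a unit-cost global alignment.
- **Occupancy and windows** — per-genome matrices of merged base-pair
  occupancy as proportions of assembly size, by repeat class or by
  cluster, with the genome-level total computed on the union of all
  hits; 100-kb windowed density tracks for chromosome heatmaps.
- **Ordination and rank-abundance** — centered PCA of genomes in
  repeat space (class-level on within-repeatome relative frequencies,
  cluster-level on proportions of genome length) with biplot-ready
  loadings; rank-abundance distributions of the top 100 clusters and
  cross-genome rank tables.
- **Regional enrichment** — the resampling test: observed repeat
  density of the merged 1-kb-flank regions of a focal gene family
  versus N = 499 equally sized random gene groups; reports fold
  enrichment (observed / null mean) and one-sided add-one empirical
  p-values, `p = (b + 1)/(N + 1)` with floor 1/500 = 0.002, plus
  Benjamini–Hochberg FDR control (level 0.1) across repeat categories.
- **PGLS** — regression of repeat proportion on assembly size (Mb)
  under a Brownian-motion phylogenetic covariance, solved via Cholesky
  whitening, with Student-t inference on n − 2 df:
  `β̂ = (XᵀV⁻¹X)⁻¹XᵀV⁻¹y`, `V[i,j]` = shared root-to-MRCA branch
  length.
- **Synthetic genomes** — `plant_genome()` emits `.out`/GFF3/index
  fixtures with Poisson-placed repeat copies at class-specific density
  targets, planted regional enrichments at chosen fold factors, and a
  truth record holding both planted and realized quantities;
  `simulate_bm_traits()` produces Brownian trait sets on any tree.

## Worked example

Generate a 5-Mb synthetic genome with a BovB enrichment planted at
4.24× background in the 1-kb flanks of a 9-gene family, then recover
it:

```r
library(repeatscape)

cfg <- simulation_config(
  seed = 7, seq_lengths = c(chr1 = 4e6, chr2 = 1e6),
  n_genes = 400, gene_length = 3000,
  enrichments = list(list(gene_set_id = "copb2", m = 9,
                          category = "LINE/BovB", fold = 4.24,
                          flank = 1000)))
pg <- plant_genome(cfg)

occ <- category_occupancy(pg$hits, pg$index, "class")
round(occ$occupancy, 3)
#>  DNA/hAT-Charlie    DNA/TcMar-Tc1 DNA/TcMar-Tigger        LINE/BovB
#>            0.021            0.181            0.050            0.102
#>   LINE/Rex-Babar          Unknown
#>            0.029            0.082
occ$total_repeat_proportion
#> [1] 0.391

focal <- subset(pg$genes, family_id == "copb2")
enrichment_test(focal, pg$hits, pg$genes, pg$index, "LINE/BovB",
                enrichment_params(seed = 99), gene_set_id = "copb2")
#> enrichment_result 'copb2' / LINE/BovB: m = 9, obs = 0.3926, null mean = 0.09865,
#>   fold = 3.98, p_emp = 0.002

pg$truth$enrichments[[1]]$realized_fold
#> [1] 3.94
```

Reading the output: each class occupies its planted share of the
genome (BovB 0.102 against a 0.10 target); the union of all repeats
covers 39.1% of the assembly. The focal family's flank regions are
39.3% BovB against a resampled null mean of 9.9%, a 3.98-fold
enrichment — matching the realized planted truth of 3.94 (sampling
noise moves individual realizations around the 4.24 expectation) — with
the minimum attainable empirical p of 0.002, i.e. the observed density
exceeded all 499 resampled gene groups.

## Command line

A thin dispatcher covers each stage
(`parse`, `cluster`, `quantify`, `windows`, `ordinate`, `rad`,
`enrich`, `pgls`, `simulate`, `full-run`), e.g.:

```sh
Rscript -e 'repeatscape::rs_cli()' cluster \
  --library lib.fasta --identity 0.8 --out clusters.tsv
Rscript -e 'repeatscape::rs_cli()' full-run \
  --config run.json --outdir results/
```

`full_run()` orchestrates every stage from one JSON config and writes
a manifest; identical config + seed reproduces byte-identical outputs.

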