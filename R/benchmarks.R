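# Fixed simulation designs used by the acceptance tests and the
# acceptance report. The worlds are stated once, here, and are not
# tuning knobs: region sizes were chosen a priori so the Monte-Carlo sd
# of a realized fold is well inside the +/-15% recovery band (see the
# methods vignette).

#' Fold-enrichment recovery benchmark
#'
#' Plants a regional enrichment of one repeat class at `fold` times
#' background in the 1-kb gene-flank regions of an `m`-gene focal family
#' on a ~10-Mb synthetic genome, then re-estimates the fold with
#' [enrichment_test()] at N = 499. The defaults mirror a compact
#' teleost-like repeat landscape; `m = 9` matches a small expanded gene
#' family, `m >= 30` gives the low-variance design for weak folds.
#'
#' @param fold Planted fold (expected merged density ratio).
#' @param m Focal family size.
#' @param category Repeat class carrying the enrichment.
#' @param seed Integer seed driving both the generator and the test.
#' @return List: `fold_estimate`, `p_emp`, `realized_fold`,
#'   `planted_fold`, `m`, `n_hits`, `assembly_size`.
#' @export
benchmark_fold_recovery <- function(fold, m, category = "LINE/BovB",
                                    seed = 1L) {
  seeds <- .derive_seeds(seed, 2)
  cfg <- simulation_config(
    seed = seeds[1],
    seq_lengths = c(chr1 = 8e6, chr2 = 2e6),
    n_genes = 500L, gene_length = 4000L,
    enrichments = list(list(gene_set_id = "focal", m = m,
                            category = category, fold = fold,
                            flank = 1000L)))
  pg <- plant_genome(cfg)
  focal <- pg$genes[!is.na(pg$genes$family_id) &
                      pg$genes$family_id == "focal", , drop = FALSE]
  res <- enrichment_test(focal, pg$hits, pg$genes, pg$index, category,
                         enrichment_params(flank = 1000L,
                                           n_resamples = 499L,
                                           seed = seeds[2]))
  tr <- pg$truth$enrichments[[1]]
  list(fold_estimate = res$fold_enrichment, p_emp = res$p_emp,
       realized_fold = tr$realized_fold, planted_fold = fold, m = m,
       n_hits = nrow(pg$hits), assembly_size = pg$index$assembly_size)
}

#' False-discovery-rate benchmark for the category scan
#'
#' Simulates `n_reps` independent 2-Mb genomes carrying 20 repeat
#' categories, two of which are enriched (fold 3) around one 12-gene
#' focal family, runs [scan_categories()] with N = 499 and
#' Benjamini-Hochberg control at `fdr_level`, and returns the mean
#' realized false-discovery proportion (false discoveries / discoveries,
#' 0 when nothing is discovered) together with the mean true-positive
#' rate.
#'
#' @param seed Integer seed.
#' @param n_reps Number of replicate datasets.
#' @param fdr_level BH control level.
#' @return List: `mean_fdp`, `mean_power`, `n_reps`, `n_categories`.
#' @export
benchmark_fdr <- function(seed = 1L, n_reps = 200L, fdr_level = 0.1) {
  seeds <- .derive_seeds(seed, 2L * n_reps)
  cats <- sprintf("SIM/cat%02d", 1:20)
  enriched <- cats[1:2]
  class_tab <- data.frame(class = cats, density = 0.012,
                          copy_length = 100L, stringsAsFactors = FALSE)
  fdp <- power <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- simulation_config(
      seed = seeds[i], seq_lengths = c(chr1 = 2e6),
      classes = class_tab, n_genes = 150L, gene_length = 1000L,
      enrichments = lapply(enriched, function(cat)
        list(gene_set_id = "focal", m = 12L, category = cat, fold = 3,
             flank = 1000L)))
    pg <- plant_genome(cfg)
    focal <- pg$genes[!is.na(pg$genes$family_id), , drop = FALSE]
    # exclude_focal = FALSE: same-pool resampling keeps the empirical
    # p-values valid at this small gene count (see methods vignette),
    # which BH control presupposes
    sc <- scan_categories(focal, pg$hits, pg$genes, pg$index, cats,
                          enrichment_params(flank = 1000L,
                                            n_resamples = 499L,
                                            fdr_level = fdr_level,
                                            seed = seeds[n_reps + i],
                                            exclude_focal = FALSE))
    disc <- sc$category[sc$discovery]
    fdp[i] <- if (length(disc) == 0) 0 else
      sum(!disc %in% enriched) / length(disc)
    power[i] <- mean(enriched %in% disc)
  }
  list(mean_fdp = mean(fdp), mean_power = mean(power),
       n_reps = n_reps, n_categories = length(cats))
}

#' Slope-recovery benchmark for phylogenetic regression
#'
#' Simulates `n_reps` trait sets under Brownian motion on a random
#' 16-tip ultrametric tree with a planted linear effect `b` of assembly
#' size (Mb, spanning 300-1400) on repeat proportion, the Brownian rate
#' chosen so the expected regression R^2 is about `r2`, and returns the
#' mean [pgls_fit()] slope estimate.
#'
#' @param seed Integer seed.
#' @param b Planted slope (repeat proportion per Mb).
#' @param n_reps Number of replicate trait sets.
#' @param r2 Approximate target R^2 controlling the noise level.
#' @return List: `mean_slope`, `sd_slope`, `planted_slope`, `n_tips`,
#'   `n_reps`, `sigma2`.
#' @export
benchmark_pgls_recovery <- function(seed = 1L, b = 0.00048,
                                    n_reps = 500L, r2 = 0.6) {
  seeds <- .derive_seeds(seed, n_reps + 1L)
  tree <- sim_ultrametric_tree(16L, seeds[1])
  x <- seq(300, 1400, length.out = 16)
  V <- tree_vcv(tree)
  sigma2 <- (1 - r2) / r2 * b^2 * stats::var(x) / mean(diag(V))
  est <- vapply(seq_len(n_reps), function(i) {
    traits <- simulate_bm_traits(tree, a = 0.15, b = b, sigma2 = sigma2,
                                 x = x, seed = seeds[i + 1L])
    pgls_fit(traits, tree)$slope
  }, numeric(1))
  list(mean_slope = mean(est), sd_slope = sd(est), planted_slope = b,
       n_tips = 16L, n_reps = n_reps, sigma2 = sigma2)
}
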