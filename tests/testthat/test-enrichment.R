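simple_hits <- function(start, end, class = "A", seq_id = "chrT") {
  data.frame(seq_id = seq_id, start = as.integer(start),
             end = as.integer(end), strand = "+", repeat_name = "f",
             repeat_class = class, divergence_pct = 0, score = 1,
             cluster_id = NA_character_, stringsAsFactors = FALSE)
}

simple_genes <- function(start, end, seq_id = "chrT") {
  data.frame(gene_id = sprintf("g%03d", seq_along(start)), seq_id = seq_id,
             start = as.integer(start), end = as.integer(end), strand = "+",
             family_id = NA_character_, stringsAsFactors = FALSE)
}

test_that("flank regions: extension, clipping and merging", {
  idx <- genome_index(c(chrT = 100000), "g")
  r <- flank_regions(simple_genes(5000, 6000), 1000, idx)
  expect_equal(r$start, 4000)
  expect_equal(r$end, 7000)

  r2 <- flank_regions(simple_genes(200, 900), 1000, idx)
  expect_equal(r2$start, 0)
  expect_equal(r2$end, 1900)

  # two genes 500 bp apart with 1-kb flanks merge into one region
  r3 <- flank_regions(simple_genes(c(10000, 12500), c(12000, 13500)), 1000,
                      idx)
  expect_equal(nrow(r3), 1L)
  expect_equal(attr(r3, "total_bp"), 5500)
})

test_that("region density: extremes and bitmask oracle", {
  reg <- data.frame(seq_id = "chrT", start = c(100L, 400L),
                    end = c(200L, 600L))
  expect_equal(region_density(reg, simple_hits(0, 1000)), 1.0)
  expect_equal(region_density(reg, simple_hits(700, 900)), 0.0)

  set.seed(12)
  hs <- sample.int(9000, 300, TRUE) - 1L
  hits <- simple_hits(hs, hs + sample.int(80, 300, TRUE))
  rs <- sample.int(9000, 10, TRUE) - 1L
  reg2 <- data.frame(seq_id = "chrT", start = rs, end = rs + 500L)
  expect_equal(region_density(reg2, hits),
               bitmask_region_density(reg2$start, reg2$end,
                                      hits$start, hits$end, 10000))
})

test_that("empirical p-value conventions: floor and all-ties", {
  idx <- genome_index(c(chrT = 1000000), "g")
  genes <- simple_genes(seq(0, 999000, by = 10000) + 4000,
                        seq(0, 999000, by = 10000) + 5000)
  focal <- genes[1, ]
  # repeats exactly covering the focal flank region, none elsewhere
  hits <- simple_hits(3000, 6000)
  res <- enrichment_test(focal, hits, genes, idx, "A",
                         enrichment_params(seed = 42))
  expect_equal(res$p_emp, 1 / 500)
  expect_equal(res$p_emp, 0.002)
  expect_equal(res$observed_density, 1.0)

  # observed equal to every null density -> p = 1 (ties count as >=)
  hits_all <- simple_hits(0, 1000000)
  res2 <- enrichment_test(focal, hits_all, genes, idx, "A",
                          enrichment_params(seed = 42))
  expect_equal(res2$observed_density, 1.0)
  expect_equal(res2$p_emp, 1.0)
})

test_that("N=3 toy genome matches exhaustive enumeration", {
  # 4 genes; focal = g1,g2; with exclude_focal the null pool is {g3,g4},
  # so every resampled group must equal that one enumerable group.
  idx <- genome_index(c(chrT = 40000), "g")
  genes <- simple_genes(c(2000, 12000, 22000, 32000),
                        c(3000, 13000, 23000, 33000))
  hits <- rbind(simple_hits(1000, 3000),    # in g1 region [1000,4000)
                simple_hits(21500, 22500),  # in g3 region [21000,24000)
                simple_hits(33500, 35500))  # overlaps g4 region by 500 bp
  params <- enrichment_params(flank = 1000, n_resamples = 3, seed = 7)
  res <- enrichment_test(genes[1:2, ], hits, genes, idx, "A", params)

  region_bp <- 3000 * 2           # two merged 3-kb regions per group
  obs_expected <- 2000 / region_bp        # hits [1000,3000) in g1's region
  null_expected <- (1000 + 500) / region_bp  # g3: 1 kb; g4: 500 bp
  expect_equal(res$observed_density, obs_expected)
  expect_equal(res$null_densities, rep(null_expected, 3))
  expect_equal(res$fold_enrichment, obs_expected / null_expected)
  expect_equal(res$p_emp, (0 + 1) / (3 + 1))

  # null_mean = 0 -> infinite fold sentinel, p still valid
  res0 <- enrichment_test(genes[1:2, ], simple_hits(1000, 3000), genes, idx,
                          "A", params)
  expect_true(is.infinite(res0$fold_enrichment))
  expect_equal(res0$p_emp, 0.25)

  # pool smaller than m -> error
  expect_error(enrichment_test(genes[1:3, ], hits, genes, idx, "A", params),
               "pool")
})

test_that("seed determinism and monotonicity of the observed side", {
  set.seed(99)
  idx <- genome_index(c(chrT = 200000), "g")
  gs <- seq(0, 199000, by = 4000)
  genes <- simple_genes(gs + 1000, gs + 2000)
  hits <- make_random_hits(500, 200000, c("A", "B"), seed = 15)
  focal <- genes[3:7, ]
  p <- enrichment_params(n_resamples = 49, seed = 11)
  r1 <- enrichment_test(focal, hits, genes, idx, "A", p)
  r2 <- enrichment_test(focal, hits, genes, idx, "A", p)
  expect_identical(r1$null_densities, r2$null_densities)
  expect_identical(r1$p_emp, r2$p_emp)

  extra <- simple_hits(focal$start[1], focal$end[1])
  r3 <- enrichment_test(focal, rbind(hits, extra), genes, idx, "A", p)
  expect_gte(r3$observed_density, r1$observed_density)
  expect_gte(r3$fold_enrichment, r1$fold_enrichment)
})

test_that("scan_categories shares null draws and applies BH", {
  cfg <- simulation_config(
    seed = 21, seq_lengths = c(chr1 = 1e6), n_genes = 120,
    gene_length = 1500,
    enrichments = list(list(gene_set_id = "fam", m = 10,
                            category = "LINE/BovB", fold = 4, flank = 1000)))
  pg <- plant_genome(cfg)
  focal <- pg$genes[!is.na(pg$genes$family_id), ]
  params <- enrichment_params(n_resamples = 199, seed = 5)
  cats <- c("LINE/BovB", "DNA/TcMar-Tc1", "Unknown")
  sc <- scan_categories(focal, pg$hits, pg$genes, pg$index, cats, params,
                        include_total = TRUE)
  expect_equal(sc$category, c(cats, "total"))
  expect_equal(sc$q_bh, p.adjust(sc$p_emp, "BH"))
  expect_equal(sc$discovery, sc$q_bh <= 0.1)
  expect_true(sc$discovery[sc$category == "LINE/BovB"])

  # same seed -> same null groups as a standalone test of one category
  single <- enrichment_test(focal, pg$hits, pg$genes, pg$index,
                            "DNA/TcMar-Tc1", params)
  expect_equal(attr(sc, "null_densities")[, "DNA/TcMar-Tc1"],
               single$null_densities)

  # BH on one category degenerates to the raw comparison
  sc1 <- scan_categories(focal, pg$hits, pg$genes, pg$index, "LINE/BovB",
                         params)
  expect_equal(sc1$q_bh, sc1$p_emp)
})

test_that("region_set_test is consistent with the gene-flank route", {
  cfg <- simulation_config(seed = 33, seq_lengths = c(chr1 = 5e5),
                           n_genes = 80, gene_length = 1500)
  pg <- plant_genome(cfg)
  focal <- pg$genes[11:15, ]
  params <- enrichment_params(n_resamples = 49, seed = 3)
  viaf <- enrichment_test(focal, pg$hits, pg$genes, pg$index, "total",
                          params)
  regions <- flank_regions(focal, params$flank, pg$index)
  viar <- region_set_test(regions, pg$hits, pg$genes, pg$index, "total",
                          params)
  expect_equal(viar$observed_density, viaf$observed_density)
  expect_equal(viar$m, nrow(regions))
  expect_error(region_set_test(regions[0, ], pg$hits, pg$genes, pg$index,
                               "total", params), "empty")
})

test_that("null calibration: empirical p is uniform without enrichment", {
  # A fresh unenriched genome per dataset; the focal set is itself a
  # background draw, so p should be uniform on {1/(N+1), ..., 1}.
  n_datasets <- 500
  N <- 59
  pvals <- numeric(n_datasets)
  set.seed(2024)
  seeds <- sample.int(1e6, n_datasets)
  for (i in seq_len(n_datasets)) {
    pg <- plant_genome(simulation_config(
      seed = seeds[i], seq_lengths = c(chr1 = 15e4), n_genes = 40,
      gene_length = 1000,
      classes = data.frame(class = c("A", "B"), density = c(0.1, 0.05),
                           copy_length = c(150L, 200L))))
    set.seed(seeds[i] + 1L)
    focal <- pg$genes[sample(nrow(pg$genes), 8), ]
    # exclude_focal = FALSE: focal and null groups are draws from the
    # SAME pool, the joint-exchangeability condition for exact
    # calibration (with exclusion, validity is only asymptotic in the
    # gene count; see the methods vignette)
    res <- enrichment_test(focal, pg$hits, pg$genes, pg$index, "A",
                           enrichment_params(n_resamples = N,
                                             seed = seeds[i] + 2L,
                                             exclude_focal = FALSE))
    pvals[i] <- res$p_emp
  }
  expect_true(all(pvals >= 1 / (N + 1) & pvals <= 1))
  # rejection rate at alpha is <= alpha + Monte-Carlo slack
  for (alpha in c(0.05, 0.1, 0.25)) {
    eps <- 3 * sqrt(alpha * (1 - alpha) / n_datasets)
    expect_lte(mean(pvals <= alpha), alpha + eps)
  }
  expect_gt(mean(pvals), 0.40)  # not wildly conservative either
})
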