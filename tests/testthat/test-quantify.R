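iv <- function(start, end, seq_id = "chrT")
  data.frame(seq_id = rep_len(seq_id, length(start)), start = start,
             end = end, stringsAsFactors = FALSE)

test_that("merge_intervals: union arithmetic and bitmask oracle", {
  m <- merge_intervals(iv(c(10, 15), c(20, 30)))
  expect_equal(m$start, 10)
  expect_equal(m$end, 30)
  expect_equal(attr(m, "total_bp"), 20)

  m2 <- merge_intervals(iv(c(0, 10), c(5, 15)))
  expect_equal(attr(m2, "total_bp"), 10)

  # bookended intervals merge (zero gap)
  m3 <- merge_intervals(iv(c(0, 5), c(5, 9)))
  expect_equal(nrow(m3), 1L)

  expect_equal(attr(merge_intervals(iv(integer(0), integer(0))), "total_bp"),
               0)

  set.seed(4)
  st <- sample.int(5000, 1000, replace = TRUE) - 1L
  en <- st + sample.int(60, 1000, replace = TRUE)
  m4 <- merge_intervals(iv(st, en))
  expect_equal(attr(m4, "total_bp"), bitmask_bp(st, en, 6000))
  # result is disjoint and sorted
  expect_true(all(diff(m4$start) > 0))
  expect_true(all(m4$start[-1] > m4$end[-nrow(m4)]))
})

test_that("category occupancy: proportions, union total, oracle", {
  idx <- genome_index(c(chrT = 1e6), "g")
  one <- data.frame(seq_id = "chrT", start = 0L, end = 100000L,
                    strand = "+", repeat_name = "f",
                    repeat_class = "LINE/BovB",
                    divergence_pct = 1, score = 1,
                    cluster_id = "c1", stringsAsFactors = FALSE)
  occ <- category_occupancy(one, idx, "class")
  expect_equal(unname(occ$occupancy["LINE/BovB"]), 0.10)

  # two classes fully overlapping: cells 0.10 each, union total 0.10
  two <- rbind(one, transform(one, repeat_class = "DNA/TcMar-Tc1",
                              cluster_id = "c2"))
  occ2 <- category_occupancy(two, idx, "class")
  expect_equal(unname(occ2$occupancy), c(0.10, 0.10))
  expect_equal(occ2$total_repeat_proportion, 0.10)

  # random fixture vs bitmask oracle, class and cluster grouping
  hits <- make_random_hits(400, 50000, c("A", "B", "C"), seed = 8)
  idx2 <- genome_index(c(chrT = 50000), "g2")
  for (grp in c("class", "cluster")) {
    occ3 <- category_occupancy(hits, idx2, grp)
    key <- if (grp == "class") hits$repeat_class else hits$cluster_id
    for (cat in unique(key)) {
      h <- hits[key == cat, ]
      expect_equal(unname(occ3$occupancy[cat]),
                   bitmask_bp(h$start, h$end, 50000) / 50000,
                   info = paste(grp, cat))
    }
    expect_equal(occ3$total_repeat_proportion,
                 bitmask_bp(hits$start, hits$end, 50000) / 50000)
    # union bound
    expect_lte(occ3$total_repeat_proportion, sum(occ3$occupancy) + 1e-12)
    expect_gte(occ3$total_repeat_proportion, max(occ3$occupancy) - 1e-12)
  }
})

test_that("occupancy is monotone under added hits", {
  idx <- genome_index(c(chrT = 50000), "g")
  hits <- make_random_hits(100, 50000, c("A", "B"), seed = 3)
  before <- category_occupancy(hits, idx, "class")
  extra <- make_random_hits(50, 50000, c("A", "B"), seed = 4)
  after <- category_occupancy(rbind(hits, extra), idx, "class")
  expect_true(all(after$occupancy[names(before$occupancy)] >=
                    before$occupancy))
  expect_gte(after$total_repeat_proportion, before$total_repeat_proportion)
})

test_that("relative class frequencies normalize within the repeatome", {
  mat <- rbind(g1 = c(A = 30, B = 10, C = 20) / 1000,
               g2 = c(A = 0.4, B = 0, C = 0))
  rel <- relative_class_frequencies(mat)
  expect_equal(unname(rel["g1", ]), c(0.5, 1 / 6, 1 / 3))
  expect_equal(unname(rel["g2", "A"]), 1.0)
  set.seed(2)
  rnd <- matrix(runif(40, 0.01, 0.3), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  expect_equal(unname(rowSums(relative_class_frequencies(rnd))), rep(1, 8),
               tolerance = 1e-12)
})

test_that("window density: splits, partial windows, conservation", {
  idx <- genome_index(c(chrT = 200), "g")
  hits <- iv(50, 150)
  hits <- data.frame(hits, strand = "+", repeat_name = "f",
                     repeat_class = "A", divergence_pct = 0, score = 1,
                     cluster_id = NA_character_)
  w <- window_density(hits, idx, window_size = 100)
  expect_equal(w$occupied_proportion, c(0.5, 0.5))

  # trailing 40-kb partial window with 10 kb occupied -> 0.25
  idx2 <- genome_index(c(chrT = 140000), "g")
  h2 <- transform(hits[1, ], start = 100000L, end = 110000L)
  w2 <- window_density(h2, idx2, window_size = 100000)
  expect_equal(w2$end - w2$start, c(100000, 40000))
  expect_equal(w2$occupied_proportion, c(0, 0.25))

  # fully covered and empty windows
  h3 <- transform(hits[1, ], start = 0L, end = 100L)
  w3 <- window_density(h3, idx, window_size = 100)
  expect_equal(w3$occupied_proportion, c(1, 0))

  # conservation: sum of per-window occupied bp equals merged totals
  idx3 <- genome_index(c(chrT = 50000), "g")
  hits4 <- make_random_hits(300, 50000, c("A", "B"), seed = 6)
  for (cat in c(NA, "A")) {
    w4 <- window_density(hits4, idx3, window_size = 7000,
                         category = if (is.na(cat)) NULL else cat)
    h <- if (is.na(cat)) hits4 else hits4[hits4$repeat_class == cat, ]
    expect_equal(sum(w4$occupied_proportion * (w4$end - w4$start)),
                 attr(merge_intervals(h), "total_bp"))
  }
  # windows tile without overlap
  expect_equal(w4$start[-1], w4$end[-nrow(w4)])
})

test_that("multi-genome occupancy table aligns categories", {
  idxA <- genome_index(c(chrT = 10000), "A")
  idxB <- genome_index(c(chrT = 20000), "B")
  hA <- make_random_hits(50, 10000, c("X", "Y"), seed = 1, max_w = 50)
  hB <- make_random_hits(50, 20000, c("Y", "Z"), seed = 2, max_w = 50)
  tab <- occupancy_table(list(A = hA, B = hB), list(A = idxA, B = idxB))
  expect_equal(rownames(tab$matrix), c("A", "B"))
  expect_setequal(colnames(tab$matrix), c("X", "Y", "Z"))
  expect_equal(tab$matrix["A", "Z"], 0)
  expect_true(all(tab$matrix >= 0 & tab$matrix <= 1))
})
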