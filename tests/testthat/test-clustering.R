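test_that("pairwise identity: fixed cases and symmetry", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = "")
  expect_equal(pairwise_identity(s, s), 1.0)

  a <- "ACGTACGTAC"
  b <- "ACGAACGAAC"  # two substitutions
  expect_equal(pairwise_identity(a, b), 0.8)
  expect_equal(pairwise_identity(b, a), 0.8)

  expect_error(pairwise_identity("", "ACGT"), "nonempty")
})

test_that("pairwise identity matches the brute-force DP oracle", {
  set.seed(71)
  for (i in 1:20) {
    la <- sample(40:60, 1)
    lb <- sample(40:60, 1)
    a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
    expect_equal(pairwise_identity(a, b), nw_oracle(a, b),
                 info = sprintf("case %d", i))
  }
  # related pairs too, not just random noise
  for (i in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = "")
    b <- strsplit(a, "")[[1]]
    at <- sample(60, 8)
    b[at] <- sample(c("A", "C", "G", "T"), 8, TRUE)
    b <- paste(b[-sample(60, 2)], collapse = "")  # plus two deletions
    expect_equal(pairwise_identity(a, b), nw_oracle(a, b))
  }
})

test_that("greedy clustering: threshold, first-match and chain behaviour", {
  set.seed(5)
  base <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  unrelated <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  lib <- data.frame(name = c("s1", "s2", "s3", "s4"),
                    sequence = c(base, base, base, unrelated),
                    stringsAsFactors = FALSE)
  cl <- greedy_cluster(lib, clustering_params())
  expect_equal(length(cl$centroids), 2L)
  expect_equal(cl$members$cluster_id[1], cl$members$cluster_id[2])
  expect_equal(cl$members$cluster_id[1], cl$members$cluster_id[3])

  # chain: A-B ~0.88, B-C ~0.88, A-C ~0.76 with theta 0.8 -> {A,B}, {C}:
  # greedy first-match, not single linkage
  A <- strsplit(base, "")[[1]]
  mutate_at <- function(x, at) {
    x[at] <- vapply(x[at], function(ch)
      sample(setdiff(c("A", "C", "G", "T"), ch), 1), character(1))
    x
  }
  B <- mutate_at(A, 1:12)
  C <- mutate_at(B, 41:52)
  expect_gte(nw_oracle(paste(A, collapse = ""), paste(B, collapse = "")), 0.8)
  expect_gte(nw_oracle(paste(B, collapse = ""), paste(C, collapse = "")), 0.8)
  expect_lt(nw_oracle(paste(A, collapse = ""), paste(C, collapse = "")), 0.8)
  chain <- data.frame(name = c("A", "B", "C"),
                      sequence = c(paste(A, collapse = ""),
                                   paste(B, collapse = ""),
                                   paste(C, collapse = "")),
                      stringsAsFactors = FALSE)
  cl2 <- greedy_cluster(chain, clustering_params())
  m <- setNames(cl2$members$cluster_id, cl2$members$sequence_name)
  expect_equal(m[["A"]], m[["B"]])
  expect_false(m[["C"]] == m[["A"]])
})

test_that("greedy clustering equals the oracle with the prefilter off", {
  lib <- make_test_library(n_ancestors = 6, per_family = 6, len = 70,
                           mut = 0.12, seed = 31)
  params <- clustering_params(min_kmer_fraction = 0)
  got <- greedy_cluster(lib, params)
  want <- greedy_oracle(lib, 0.8)
  centroid_of <- setNames(got$members$centroid_name,
                          got$members$sequence_name)
  expect_equal(centroid_of[names(want)], want)

  # the k-mer prefilter is an optimization only on this fixture
  got_pf <- greedy_cluster(lib, clustering_params())
  expect_identical(got_pf$members, got$members)
})

test_that("partition, threshold and determinism invariants hold", {
  lib <- make_test_library(n_ancestors = 5, per_family = 8, len = 90,
                           mut = 0.1, seed = 77)
  cl <- greedy_cluster(lib, clustering_params())
  # partition: every sequence exactly once
  expect_setequal(cl$members$sequence_name, lib$name)
  expect_equal(anyDuplicated(cl$members$sequence_name), 0L)
  # centroids are members of their own cluster at identity 1
  cent <- cl$members[cl$members$sequence_name == cl$members$centroid_name, ]
  expect_setequal(cent$sequence_name, unname(cl$centroids))
  expect_true(all(cent$identity == 1))
  # threshold: every member >= theta to its centroid
  expect_true(all(cl$members$identity >= 0.8))
  # stored identity is the true pairwise identity
  idx <- sample(nrow(cl$members), 5)
  seqs <- setNames(lib$sequence, lib$name)
  for (i in idx)
    expect_equal(cl$members$identity[i],
                 pairwise_identity(seqs[[cl$members$sequence_name[i]]],
                                   seqs[[cl$members$centroid_name[i]]]))
  # determinism: byte-identical tables
  expect_identical(greedy_cluster(lib, clustering_params())$members,
                   cl$members)
})

test_that("reverse-complement matching is opt-in", {
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 80, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA",
               paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  lib <- data.frame(name = c("fwd", "rev"), sequence = c(s, rc),
                    stringsAsFactors = FALSE)
  expect_equal(length(greedy_cluster(lib)$centroids), 2L)
  expect_equal(length(greedy_cluster(
    lib, clustering_params(both_strands = TRUE))$centroids), 1L)
})

test_that("empty library yields an empty assignment", {
  cl <- greedy_cluster(data.frame(name = character(0),
                                  sequence = character(0)))
  expect_equal(nrow(cl$members), 0L)
  expect_equal(length(cl$centroids), 0L)
})
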