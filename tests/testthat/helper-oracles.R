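# Independent oracles, deliberately naive and separate from the package
# implementations they check.

# Full-matrix unit-cost global alignment with diagonal>up>left traceback;
# returns matching columns / alignment columns.
nw_oracle <- function(a, b) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(A); lb <- length(B)
  D <- matrix(0L, la + 1, lb + 1)
  D[, 1] <- 0:la
  D[1, ] <- 0:lb
  for (i in seq_len(la))
    for (j in seq_len(lb))
      D[i + 1, j + 1] <- min(D[i, j] + (A[i] != B[j]),
                             D[i, j + 1] + 1L, D[i + 1, j] + 1L)
  i <- la; j <- lb; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && D[i + 1, j + 1] == D[i, j] + (A[i] != B[j])) {
      matches <- matches + (A[i] == B[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] + 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Reference greedy centroid clustering: length-descending order, name
# tie-break, first centroid (creation order) at identity >= theta wins.
greedy_oracle <- function(library, theta) {
  ord <- order(-nchar(library$sequence), library$name, method = "radix")
  nm <- library$name[ord]
  sq <- library$sequence[ord]
  cent <- integer(0)
  assign <- integer(length(sq))
  for (i in seq_along(sq)) {
    hit <- 0L
    for (ci in cent) {
      if (nw_oracle(sq[i], sq[ci]) >= theta) { hit <- ci; break }
    }
    if (hit == 0L) { cent <- c(cent, i); hit <- i }
    assign[i] <- hit
  }
  setNames(nm[assign], nm)  # member -> centroid name
}

# Per-base bitmask coverage of 0-based half-open intervals on one sequence.
bitmask_bp <- function(start, end, len) {
  cov <- logical(len)
  for (k in seq_along(start))
    if (end[k] > start[k]) cov[(start[k] + 1):end[k]] <- TRUE
  sum(cov)
}

# Bitmask density of a region set against hit intervals (same sequence).
bitmask_region_density <- function(reg_start, reg_end, hit_start, hit_end,
                                   len) {
  cov <- logical(len)
  for (k in seq_along(hit_start))
    if (hit_end[k] > hit_start[k]) cov[(hit_start[k] + 1):hit_end[k]] <- TRUE
  inreg <- logical(len)
  for (k in seq_along(reg_start))
    if (reg_end[k] > reg_start[k]) inreg[(reg_start[k] + 1):reg_end[k]] <- TRUE
  sum(cov & inreg) / sum(inreg)
}

# Random mutated-descendant library: families of related sequences, so
# clustering fixtures have realistic structure.
make_test_library <- function(n_ancestors, per_family, len, mut, seed) {
  set.seed(seed)
  rows <- list()
  for (a in seq_len(n_ancestors)) {
    anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    for (k in seq_len(per_family)) {
      s <- anc
      nmut <- rpois(1, mut * len)
      if (nmut > 0) {
        at <- sample.int(len, min(nmut, len))
        s[at] <- sample(c("A", "C", "G", "T"), length(at), replace = TRUE)
      }
      rows[[length(rows) + 1]] <- data.frame(
        name = sprintf("anc%02d_seq%02d", a, k),
        class = "Unknown",
        sequence = paste(s, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Random hit table on one small sequence.
make_random_hits <- function(n, len, classes, seed, max_w = 200) {
  set.seed(seed)
  st <- sample.int(len - max_w, n, replace = TRUE) - 1L
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(seq_id = rep("chrT", n), start = st, end = st + w,
             strand = sample(c("+", "-"), n, TRUE),
             repeat_name = paste0("f", sample(5, n, TRUE)),
             repeat_class = sample(classes, n, TRUE),
             divergence_pct = round(runif(n, 0, 30), 1),
             score = as.numeric(sample(100:999, n, TRUE)),
             cluster_id = paste0("c", sample(4, n, TRUE)),
             stringsAsFactors = FALSE)
}
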