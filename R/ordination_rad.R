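#' Principal components ordination of genomes in repeat space
#'
#' Centered (optionally unit-variance scaled) PCA of a genomes x
#' categories matrix, returning scores, loadings for biplot arrows and
#' the fraction of variance per component. Two presets are conventional:
#' class-level ordination runs on within-repeatome relative frequencies
#' (see [relative_class_frequencies()]); cluster-level ordination runs on
#' proportions of assembly size. The default is centered and unscaled
#' because both inputs are commensurate proportions.
#'
#' Loading columns are sign-fixed (largest-magnitude element positive)
#' so results are deterministic across linear-algebra backends.
#'
#' @param mat Numeric matrix, >= 2 rows (genomes) and >= 2 columns.
#' @param scale Scale columns to unit variance; zero-variance columns
#'   are dropped with a warning when scaling.
#' @return A `pca_result`: list with `scores`, `loadings`,
#'   `variance_explained`, `center`, `scaled`.
#' @export
repeat_pca <- function(mat, scale = FALSE) {
  .rs_assert(is.matrix(mat) && nrow(mat) >= 2 && ncol(mat) >= 2,
             "need a matrix with >= 2 rows and >= 2 columns")
  .rs_assert(!anyNA(mat), "matrix must not contain missing values")
  if (scale) {
    v <- apply(mat, 2, sd)
    if (any(v == 0)) {
      warning(sprintf("dropping %d zero-variance column(s) before scaling",
                      sum(v == 0)))
      mat <- mat[, v > 0, drop = FALSE]
      .rs_assert(ncol(mat) >= 2, "fewer than 2 columns left after dropping")
    }
  }
  fit <- prcomp(mat, center = TRUE, scale. = scale)
  flip <- apply(fit$rotation, 2, function(col) {
    s <- sign(col[which.max(abs(col))])
    if (s == 0) 1 else s
  })
  scores <- sweep(fit$x, 2, flip, "*")
  loadings <- sweep(fit$rotation, 2, flip, "*")
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 variance_explained = ve, center = fit$center,
                 scaled = scale),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d genomes, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$variance_explained[1],
              100 * x$variance_explained[2]))
  invisible(x)
}

#' Rank-abundance distribution of repeat clusters
#'
#' Sorts a genome's per-cluster occupancy in decreasing order of
#' abundance — the ecology view of a repeatome as a community — and
#' truncates to the top `top_n` clusters. Ties are broken by cluster id
#' so ranks are deterministic.
#'
#' @param occupancy Named numeric vector: cluster id -> proportion of
#'   genome length occupied.
#' @param top_n Number of leading ranks to keep (default 100).
#' @param genome_id Genome identifier carried into the result.
#' @return A `data.frame`: `rank`, `cluster_id`, `abundance`.
#' @export
rank_abundance <- function(occupancy, top_n = 100L, genome_id = "genome") {
  ord <- order(-occupancy, names(occupancy), method = "radix")
  n <- min(length(ord), top_n)
  out <- data.frame(rank = seq_len(n),
                    cluster_id = names(occupancy)[ord][seq_len(n)],
                    abundance = unname(occupancy[ord])[seq_len(n)],
                    stringsAsFactors = FALSE)
  attr(out, "genome_id") <- genome_id
  out
}

#' Cross-genome rank table for a reference genome's top clusters
#'
#' Takes the top `k` clusters of a reference genome and reports, for
#' every other genome, the rank those clusters hold there (`NA` when the
#' cluster is absent), mirroring the boxed top-cluster comparisons in
#' rank-abundance figures.
#'
#' @param rads Named list of full (untruncated) rank-abundance tables,
#'   one per genome, as returned by [rank_abundance()].
#' @param reference Name of the reference genome in `rads`.
#' @param k Number of top reference clusters to report.
#' @return A `data.frame` with `cluster_id`, `rank_<reference>` and one
#'   `rank_<genome>` column per other genome.
#' @export
cross_genome_rank_table <- function(rads, reference, k = 15L) {
  .rs_assert(reference %in% names(rads), "reference genome not in rads")
  ref <- rads[[reference]]
  k <- min(k, nrow(ref))
  top <- ref$cluster_id[seq_len(k)]
  out <- data.frame(cluster_id = top, stringsAsFactors = FALSE)
  out[[paste0("rank_", reference)]] <- seq_len(k)
  for (g in setdiff(names(rads), reference)) {
    r <- rads[[g]]
    out[[paste0("rank_", g)]] <- r$rank[match(top, r$cluster_id)]
  }
  out
}
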