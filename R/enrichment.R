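#' Parameters for resampling-based regional enrichment tests
#'
#' @param flank Flank in bp added to both sides of every focal gene
#'   (default 1000, i.e. the 1-kb vicinity used for the focal-family
#'   tests).
#' @param n_resamples Number of resampled null gene groups N (default
#'   499, which makes the smallest attainable empirical p exactly
#'   1/(N+1) = 0.002).
#' @param fdr_level Benjamini-Hochberg control level across a family of
#'   categories (default 0.1).
#' @param seed Integer seed; every null draw is a deterministic function
#'   of it.
#' @param exclude_focal Drop the focal genes from the null pool (default
#'   TRUE, preventing self-contamination of the null).
#' @param length_matched Match null groups to the focal set's gene-length
#'   decile composition (default FALSE: plain uniform sampling of gene
#'   groups).
#' @return An `enrichment_params` list.
#' @export
enrichment_params <- function(flank = 1000L, n_resamples = 499L,
                              fdr_level = 0.1, seed = 1L,
                              exclude_focal = TRUE,
                              length_matched = FALSE) {
  .rs_assert(flank >= 0, "flank must be >= 0")
  .rs_assert(n_resamples >= 1, "n_resamples must be >= 1")
  .rs_assert(fdr_level > 0 && fdr_level < 1, "fdr_level must be in (0, 1)")
  structure(list(flank = as.integer(flank),
                 n_resamples = as.integer(n_resamples),
                 fdr_level = fdr_level, seed = as.integer(seed),
                 exclude_focal = exclude_focal,
                 length_matched = length_matched),
            class = "enrichment_params")
}

#' Flanked, merged regions around a gene set
#'
#' Extends every gene span by `flank` bp on both sides, clips to the
#' containing sequence and merges the extended spans into a disjoint
#' region set.
#'
#' @param genes Gene `data.frame` (`seq_id`, `start`, `end`).
#' @param flank Flank in bp.
#' @param index A `genome_index` (for clipping).
#' @return Merged region `data.frame` with attribute `total_bp`.
#' @export
flank_regions <- function(genes, flank, index) {
  .rs_assert(nrow(genes) > 0, "empty gene set")
  len <- index$lengths[genes$seq_id]
  .rs_assert(!anyNA(len), "gene on a sequence absent from the index")
  ext <- data.frame(seq_id = genes$seq_id,
                    start = pmax(0, genes$start - flank),
                    end = pmin(unname(len), genes$end + flank),
                    stringsAsFactors = FALSE)
  merge_intervals(ext)
}

#' Repeat density of a region set
#'
#' Fraction of region base pairs covered by (category-filtered, merged)
#' repeat hits.
#'
#' @param regions Region `data.frame` (`seq_id`, `start`, `end`);
#'   overlapping regions are merged before measuring.
#' @param hits Repeat hits `data.frame`.
#' @param category Repeat category or `"total"`/`NULL` for all repeats.
#' @param group_by Whether `category` names a class or a cluster.
#' @return Density fraction in `[0, 1]`.
#' @export
region_density <- function(regions, hits, category = NULL,
                           group_by = c("class", "cluster")) {
  group_by <- match.arg(group_by)
  regions <- merge_intervals(regions)
  .rs_assert(nrow(regions) > 0, "empty region set")
  merged <- merge_intervals(.filter_category(hits, category, group_by))
  d <- .group_densities(list(regions), merged)
  d[[1]]
}

#' @noRd
.filter_category <- function(hits, category, group_by) {
  if (is.null(category) || identical(category, "total")) return(hits)
  key <- if (group_by == "class") hits$repeat_class else hits$cluster_id
  hits[!is.na(key) & key == category, , drop = FALSE]
}

# Densities of many merged region sets against one merged hit set, via a
# single findOverlaps per sequence. region_list: list of data.frames.
#' @noRd
.group_densities <- function(region_list, merged_hits) {
  ng <- length(region_list)
  grp <- rep.int(seq_len(ng), vapply(region_list, nrow, integer(1)))
  all_reg <- do.call(rbind, region_list)
  tot <- vapply(split(all_reg$end - all_reg$start, factor(grp, seq_len(ng))),
                sum, numeric(1))
  occ <- numeric(ng)
  for (s in unique(all_reg$seq_id)) {
    ri <- which(all_reg$seq_id == s)
    hi <- merged_hits[merged_hits$seq_id == s, , drop = FALSE]
    if (nrow(hi) == 0L) next
    qr <- .to_iranges(all_reg$start[ri], all_reg$end[ri])
    hr <- .to_iranges(hi$start, hi$end)
    ov <- IRanges::findOverlaps(qr, hr)
    if (length(ov) == 0L) next
    q <- S4Vectors::queryHits(ov)
    h <- S4Vectors::subjectHits(ov)
    w <- pmin(all_reg$end[ri][q], hi$end[h]) -
      pmax(all_reg$start[ri][q], hi$start[h])
    add <- tapply(w, factor(grp[ri][q], seq_len(ng)), sum, default = 0)
    occ <- occ + as.numeric(add)
  }
  unname(occ / tot)
}

# Deterministic null group draws: N groups of m gene indices, sampled
# without replacement within a group, independently across groups.
# Optional length matching stratifies the pool into deciles of gene
# length and matches the focal composition.
#' @noRd
.draw_null_groups <- function(pool, m, N, seed, focal_lengths = NULL,
                              pool_lengths = NULL, length_matched = FALSE) {
  .rs_assert(length(pool) >= m,
             "null pool (%d genes) smaller than focal set (m = %d)",
             length(pool), m)
  set.seed(seed)
  if (!length_matched)
    return(lapply(seq_len(N), function(i) sample(pool, m)))
  br <- unique(stats::quantile(pool_lengths, probs = seq(0, 1, 0.1)))
  bin <- function(x) findInterval(x, br, rightmost.closed = TRUE,
                                  all.inside = TRUE)
  need <- table(bin(focal_lengths))
  pool_bins <- split(pool, bin(pool_lengths))
  lapply(seq_len(N), function(i) {
    unlist(lapply(names(need), function(b) {
      p <- pool_bins[[b]]
      .rs_assert(length(p) >= need[[b]],
                 "length-matched pool stratum too small")
      sample(p, need[[b]])
    }), use.names = FALSE)
  })
}

#' @noRd
.null_regions <- function(groups, genes, flank, index) {
  lapply(groups, function(idx)
    flank_regions(genes[idx, , drop = FALSE], flank, index))
}

#' @noRd
.new_enrichment_result <- function(gene_set_id, category, m, obs, nulls) {
  null_mean <- mean(nulls)
  structure(list(gene_set_id = gene_set_id, category = category, m = m,
                 observed_density = obs,
                 null_densities = nulls,
                 null_mean = null_mean,
                 fold_enrichment = if (null_mean == 0) Inf else obs / null_mean,
                 p_emp = (sum(nulls >= obs) + 1) / (length(nulls) + 1),
                 q_bh = NA_real_),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result '%s' / %s: m = %d, obs = %.4g, null mean = %.4g,\n  fold = %.3g, p_emp = %.4g%s\n",
    x$gene_set_id, x$category, x$m, x$observed_density, x$null_mean,
    x$fold_enrichment, x$p_emp,
    if (is.na(x$q_bh)) "" else sprintf(", q_bh = %.4g", x$q_bh)))
  invisible(x)
}

#' Resampling test for repeat enrichment around a focal gene set
#'
#' Measures the repeat density (occupied bp / region bp) of the merged
#' flank regions of a focal gene family and compares it with the same
#' statistic for `N` random gene groups of the same size drawn from the
#' genome's gene complement. Reports fold enrichment (observed / null
#' mean) and a one-sided add-one empirical p-value
#' `(#\{null >= observed\} + 1) / (N + 1)`, whose smallest attainable
#' value with the default N = 499 is 0.002.
#'
#' @param focal Gene `data.frame` of the focal set (subset of
#'   `all_genes`, matched by `gene_id`).
#' @param hits Repeat hits `data.frame`.
#' @param all_genes Gene `data.frame` for the whole genome.
#' @param index A `genome_index`.
#' @param category Repeat category to test (`"total"` for all repeats).
#' @param params An [enrichment_params()] list.
#' @param group_by Whether `category` names a class or a cluster.
#' @param gene_set_id Label for the focal set.
#' @return An `enrichment_result` (see [enrichment_params()] for the
#'   conventions); `q_bh` is `NA` for a single test — use
#'   [scan_categories()] for a BH-adjusted family.
#' @export
enrichment_test <- function(focal, hits, all_genes, index,
                            category = "total",
                            params = enrichment_params(),
                            group_by = c("class", "cluster"),
                            gene_set_id = "focal") {
  group_by <- match.arg(group_by)
  .rs_assert(nrow(focal) > 0, "empty focal gene set")
  .rs_assert(nrow(all_genes) > nrow(focal),
             "all_genes must be larger than the focal set")
  m <- nrow(focal)
  pool <- if (params$exclude_focal)
    which(!all_genes$gene_id %in% focal$gene_id) else seq_len(nrow(all_genes))
  groups <- .draw_null_groups(pool, m, params$n_resamples, params$seed,
                              focal_lengths = focal$end - focal$start,
                              pool_lengths = all_genes$end - all_genes$start,
                              length_matched = params$length_matched)
  merged <- merge_intervals(.filter_category(hits, category, group_by))
  obs_regions <- flank_regions(focal, params$flank, index)
  region_list <- c(list(obs_regions),
                   .null_regions(groups, all_genes, params$flank, index))
  d <- .group_densities(region_list, merged)
  .new_enrichment_result(gene_set_id, category, m, d[1], d[-1])
}

#' Scan many repeat categories with shared null draws and BH FDR
#'
#' Runs [enrichment_test()] for each category in `categories` (plus
#' `"total"` if requested) against the SAME resampled null gene groups,
#' so Monte-Carlo variation is shared and categories are comparable,
#' then applies Benjamini-Hochberg step-up across the family at
#' `params$fdr_level`.
#'
#' @inheritParams enrichment_test
#' @param categories Character vector of category labels.
#' @param include_total Also test the pooled density of all repeats.
#' @return A `data.frame` with one row per category: `gene_set`,
#'   `category`, `m`, `observed`, `null_mean`, `fold`, `p_emp`, `q_bh`,
#'   `discovery`; the N x categories matrix of null densities is
#'   attached as attribute `null_densities`.
#' @export
scan_categories <- function(focal, hits, all_genes, index, categories,
                            params = enrichment_params(),
                            group_by = c("class", "cluster"),
                            include_total = FALSE,
                            gene_set_id = "focal") {
  group_by <- match.arg(group_by)
  .rs_assert(length(categories) >= 1, "need at least one category")
  m <- nrow(focal)
  .rs_assert(nrow(all_genes) > m, "all_genes must be larger than the focal set")
  pool <- if (params$exclude_focal)
    which(!all_genes$gene_id %in% focal$gene_id) else seq_len(nrow(all_genes))
  groups <- .draw_null_groups(pool, m, params$n_resamples, params$seed,
                              focal_lengths = focal$end - focal$start,
                              pool_lengths = all_genes$end - all_genes$start,
                              length_matched = params$length_matched)
  obs_regions <- flank_regions(focal, params$flank, index)
  region_list <- c(list(obs_regions),
                   .null_regions(groups, all_genes, params$flank, index))
  cats <- if (include_total) c(categories, "total") else categories
  res <- lapply(cats, function(cat) {
    merged <- merge_intervals(.filter_category(hits, cat, group_by))
    d <- .group_densities(region_list, merged)
    .new_enrichment_result(gene_set_id, cat, m, d[1], d[-1])
  })
  p <- vapply(res, `[[`, numeric(1), "p_emp")
  q <- p.adjust(p, method = "BH")
  out <- data.frame(gene_set = gene_set_id, category = cats, m = m,
                    observed = vapply(res, `[[`, numeric(1), "observed_density"),
                    null_mean = vapply(res, `[[`, numeric(1), "null_mean"),
                    fold = vapply(res, `[[`, numeric(1), "fold_enrichment"),
                    p_emp = p, q_bh = q,
                    discovery = q <= params$fdr_level,
                    stringsAsFactors = FALSE)
  attr(out, "null_densities") <-
    do.call(cbind, setNames(lapply(res, `[[`, "null_densities"), cats))
  out
}

#' Enrichment test for an explicit region set
#'
#' Same machinery as [enrichment_test()] but the observed side is a
#' user-supplied interval list (e.g. loci of interest such as regions of
#' gene loss) rather than gene flanks; null gene groups are sized to
#' match the number of supplied regions.
#'
#' @param regions Region `data.frame` (`seq_id`, `start`, `end`).
#' @inheritParams enrichment_test
#' @export
region_set_test <- function(regions, hits, all_genes, index,
                            category = "total",
                            params = enrichment_params(),
                            group_by = c("class", "cluster"),
                            gene_set_id = "regions") {
  group_by <- match.arg(group_by)
  .rs_assert(nrow(regions) > 0, "empty region list")
  m <- nrow(regions)
  .rs_assert(nrow(all_genes) > m,
             "all_genes must be larger than the region count")
  groups <- .draw_null_groups(seq_len(nrow(all_genes)), m,
                              params$n_resamples, params$seed)
  merged <- merge_intervals(.filter_category(hits, category, group_by))
  region_list <- c(list(merge_intervals(regions)),
                   .null_regions(groups, all_genes, params$flank, index))
  d <- .group_densities(region_list, merged)
  .new_enrichment_result(gene_set_id, category, m, d[1], d[-1])
}
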