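#' Merge genomic intervals into a disjoint set
#'
#' Sorts intervals per sequence and merges overlapping or bookended
#' (zero-gap) intervals, so downstream base-pair totals never double
#' count. Strand is ignored.
#'
#' @param intervals A `data.frame` with columns `seq_id`, `start`, `end`
#'   (0-based half-open), e.g. repeat hits or region sets.
#' @return A `data.frame` (`seq_id`, `start`, `end`) of disjoint sorted
#'   intervals with attribute `total_bp` = sum of widths.
#' @export
merge_intervals <- function(intervals) {
  if (nrow(intervals) == 0L) {
    out <- data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE)
    attr(out, "total_bp") <- 0
    return(out)
  }
  by_seq <- split(intervals[c("start", "end")], intervals$seq_id)
  pieces <- lapply(names(by_seq), function(s) {
    ir <- IRanges::reduce(.to_iranges(by_seq[[s]]$start, by_seq[[s]]$end))
    cbind(seq_id = s, .from_iranges(ir))
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}

#' Per-category repeat occupancy for one genome
#'
#' Computes, for each repeat category (class taxonomy string or cluster
#' label), the merged base pairs it occupies as a proportion of assembly
#' size, plus the total repeat proportion taken on the union of all hits
#' so overlap between categories is counted once at the genome level.
#'
#' @param hits Repeat hits `data.frame`.
#' @param index A `genome_index`.
#' @param group_by `"class"` or `"cluster"`.
#' @param chromosomes_only Optional character vector of sequence names to
#'   restrict to (e.g. placed chromosomes); the assembly size denominator
#'   is restricted accordingly.
#' @return A list with `occupancy` (named numeric, proportion of assembly
#'   size per category) and `total_repeat_proportion`.
#' @export
category_occupancy <- function(hits, index, group_by = c("class", "cluster"),
                               chromosomes_only = NULL) {
  group_by <- match.arg(group_by)
  .rs_assert(index$assembly_size > 0, "assembly size must be positive")
  denom <- index$assembly_size
  if (!is.null(chromosomes_only)) {
    hits <- hits[hits$seq_id %in% chromosomes_only, , drop = FALSE]
    denom <- sum(index$lengths[names(index$lengths) %in% chromosomes_only])
    .rs_assert(denom > 0, "chromosomes_only matches no sequence")
  }
  key <- if (group_by == "class") hits$repeat_class else hits$cluster_id
  if (group_by == "cluster")
    .rs_assert(!anyNA(key) || nrow(hits) == 0L,
               "hits must carry cluster_id for group_by = 'cluster'")
  bp <- vapply(split(hits, key),
               function(h) attr(merge_intervals(h), "total_bp"), numeric(1))
  total <- attr(merge_intervals(hits), "total_bp")
  list(occupancy = bp / denom,
       total_repeat_proportion = total / denom)
}

#' Genomes-by-categories occupancy table
#'
#' Stacks [category_occupancy()] rows for many genomes into one matrix,
#' filling categories absent from a genome with 0.
#'
#' @param hits_list Named list of hits tables (names = genome ids).
#' @param index_list Named list of matching `genome_index` objects.
#' @inheritParams category_occupancy
#' @return A list with `matrix` (genomes x categories, proportions of
#'   assembly size) and `total_repeat_proportion` (named vector).
#' @export
occupancy_table <- function(hits_list, index_list,
                            group_by = c("class", "cluster")) {
  group_by <- match.arg(group_by)
  .rs_assert(identical(names(hits_list), names(index_list)),
             "hits_list and index_list must have identical names")
  rows <- lapply(names(hits_list), function(g)
    category_occupancy(hits_list[[g]], index_list[[g]], group_by))
  cats <- sort(unique(unlist(lapply(rows, function(r) names(r$occupancy)))))
  mat <- matrix(0, nrow = length(rows), ncol = length(cats),
                dimnames = list(names(hits_list), cats))
  for (i in seq_along(rows))
    mat[i, names(rows[[i]]$occupancy)] <- rows[[i]]$occupancy
  list(matrix = mat,
       total_repeat_proportion = setNames(
         vapply(rows, `[[`, numeric(1), "total_repeat_proportion"),
         names(hits_list)))
}

#' Within-repeatome relative class frequencies
#'
#' Rescales each genome's occupancy vector to sum to one, turning
#' proportions of assembly size into proportions of the repeatome — the
#' compositional view used for class-level ordination.
#'
#' @param mat Occupancy matrix (genomes x categories).
#' @return Matrix of the same shape with unit row sums.
#' @export
relative_class_frequencies <- function(mat) {
  rs <- rowSums(mat)
  .rs_assert(all(rs > 0), "a genome with zero repeat occupancy cannot be rescaled")
  sweep(mat, 1, rs, "/")
}

#' Windowed repeat density track
#'
#' Tiles every sequence with fixed-size windows (the final partial window
#' keeps its true length as the denominator) and reports the merged
#' repeat base-pair occupation of each window as a proportion.
#'
#' @param hits Repeat hits `data.frame`.
#' @param index A `genome_index`.
#' @param window_size Window size in bp; default 100 kb.
#' @param category Optional repeat class (or, with `group_by =
#'   "cluster"`, cluster id) to restrict to; `NULL` means all repeats.
#' @param group_by How `category` is interpreted.
#' @return A `data.frame`: `seq_id`, `start`, `end`,
#'   `occupied_proportion`, with attributes `genome_id`, `window_size`.
#' @export
window_density <- function(hits, index, window_size = 100000L,
                           category = NULL,
                           group_by = c("class", "cluster")) {
  group_by <- match.arg(group_by)
  .rs_assert(window_size >= 1, "window_size must be >= 1")
  if (!is.null(category)) {
    key <- if (group_by == "class") hits$repeat_class else hits$cluster_id
    hits <- hits[!is.na(key) & key == category, , drop = FALSE]
  }
  merged <- merge_intervals(hits)
  tracks <- lapply(names(index$lengths), function(s) {
    len <- index$lengths[[s]]
    starts <- seq(0, len - 1, by = window_size)
    ends <- pmin(starts + window_size, len)
    occ <- numeric(length(starts))
    mi <- merged[merged$seq_id == s, , drop = FALSE]
    if (nrow(mi) > 0) {
      ir <- .to_iranges(mi$start, mi$end)
      wr <- .to_iranges(starts, ends)
      ov <- IRanges::findOverlaps(wr, ir)
      if (length(ov)) {
        qs <- S4Vectors::queryHits(ov)
        inter <- pmin(ends[qs], mi$end[S4Vectors::subjectHits(ov)]) -
          pmax(starts[qs], mi$start[S4Vectors::subjectHits(ov)])
        occ <- occ + as.numeric(tapply(inter, factor(qs, seq_along(starts)),
                                       sum, default = 0))
      }
    }
    data.frame(seq_id = s, start = starts, end = ends,
               occupied_proportion = occ / (ends - starts),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, tracks)
  rownames(out) <- NULL
  attr(out, "genome_id") <- index$genome_id
  attr(out, "window_size") <- window_size
  out
}
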