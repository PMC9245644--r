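#' Global-alignment sequence identity
#'
#' Identity between two DNA sequences, defined as the number of matching
#' columns divided by the total number of columns (gap columns included)
#' of a global alignment under unit match/mismatch/gap costs. The
#' traceback is deterministic (diagonal preferred over vertical over
#' horizontal moves on cost ties) so the value is reproducible. The
#' measure is symmetric.
#'
#' @param a,b Nonempty uppercase DNA sequences (character scalars).
#' @return Identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  .rs_assert(is.character(a) && is.character(b) &&
               length(a) == 1L && length(b) == 1L,
             "a and b must be single character strings")
  .rs_assert(nzchar(a) && nzchar(b), "sequences must be nonempty")
  .nw_identity_cpp(a, b)
}

#' Clustering parameters
#'
#' @param identity_threshold Minimum member-to-centroid identity
#'   (fraction in (0, 1]); default 0.80, the level used throughout the
#'   cluster-based repeatome analyses.
#' @param kmer_size k-mer length for the candidate prefilter; >= 4.
#' @param min_kmer_fraction Minimum fraction of a query's k-mers that a
#'   centroid must share before a full alignment is attempted. Set to 0
#'   to disable the prefilter (every centroid is aligned), which makes
#'   the greedy rule exact and is how the oracle tests run.
#' @param both_strands Also compare against the reverse complement and
#'   keep the better identity. Off by default: library consensus
#'   orientation is assumed consistent.
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(identity_threshold = 0.80, kmer_size = 8L,
                              min_kmer_fraction = 0.05,
                              both_strands = FALSE) {
  .rs_assert(identity_threshold > 0 && identity_threshold <= 1,
             "identity_threshold must be in (0, 1]")
  .rs_assert(kmer_size >= 4, "kmer_size must be >= 4")
  .rs_assert(min_kmer_fraction >= 0 && min_kmer_fraction <= 1,
             "min_kmer_fraction must be in [0, 1]")
  structure(list(identity_threshold = identity_threshold,
                 kmer_size = as.integer(kmer_size),
                 min_kmer_fraction = min_kmer_fraction,
                 both_strands = both_strands),
            class = "clustering_params")
}

#' @noRd
.kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(seq)
  unique(substring(seq, 1:(n - k + 1), k:n))
}

#' @noRd
.revcomp <- function(seq) {
  chartr("ACGTN", "TGCAN",
         paste(rev(strsplit(seq, "", fixed = TRUE)[[1]]), collapse = ""))
}

#' Greedy centroid clustering at a fixed identity threshold
#'
#' Groups repeat consensus sequences the way the classic centroid
#' clustering tools do: sequences are processed in length-descending
#' order (ties broken lexicographically by name); each sequence is
#' compared against existing centroids in centroid-creation order and
#' joins the FIRST centroid whose identity meets the threshold,
#' otherwise it founds a new centroid. A shared-k-mer prefilter skips
#' obviously unrelated centroids; it is an optimization only and can be
#' disabled via `min_kmer_fraction = 0`.
#'
#' @param library A `data.frame` with columns `name` and `sequence`
#'   (e.g. from [read_library_fasta()]); names must be unique.
#' @param params A [clustering_params()] list.
#' @return A `cluster_assignment`: list with `members` (`data.frame`:
#'   `sequence_name`, `cluster_id`, `centroid_name`, `identity`) and
#'   `centroids` (named character vector cluster_id -> centroid name).
#'   Centroids belong to their own cluster with identity 1.
#' @export
greedy_cluster <- function(library, params = clustering_params()) {
  if (nrow(library) == 0L)
    return(structure(list(members = data.frame(sequence_name = character(0),
                                               cluster_id = character(0),
                                               centroid_name = character(0),
                                               identity = numeric(0),
                                               stringsAsFactors = FALSE),
                          centroids = character(0),
                          params = params),
                     class = "cluster_assignment"))
  .rs_assert(!anyDuplicated(library$name), "library names must be unique")
  ord <- order(-nchar(library$sequence), library$name, method = "radix")
  nm <- library$name[ord]
  sq <- library$sequence[ord]
  theta <- params$identity_threshold
  k <- params$kmer_size

  cent_seq <- character(0)
  cent_name <- character(0)
  cent_kmers <- list()
  assigned_cluster <- integer(length(sq))
  identity <- numeric(length(sq))

  for (i in seq_along(sq)) {
    q <- sq[i]
    qk <- .kmer_set(q, k)
    # with both-strand comparison the prefilter must see both strands too
    if (params$both_strands)
      qk <- unique(c(qk, .kmer_set(.revcomp(q), k)))
    need <- params$min_kmer_fraction * length(qk) /
      (if (params$both_strands) 2 else 1)
    hit <- 0L
    hit_id <- 1.0
    for (ci in seq_along(cent_seq)) {
      if (need > 0) {
        shared <- sum(qk %in% cent_kmers[[ci]])
        if (shared < need) next
      }
      id <- .nw_identity_cpp(q, cent_seq[ci])
      if (params$both_strands)
        id <- max(id, .nw_identity_cpp(q, .revcomp(cent_seq[ci])))
      if (id >= theta) {
        hit <- ci
        hit_id <- id
        break
      }
    }
    if (hit == 0L) {
      cent_seq <- c(cent_seq, q)
      cent_name <- c(cent_name, nm[i])
      cent_kmers[[length(cent_seq)]] <- qk
      assigned_cluster[i] <- length(cent_seq)
      identity[i] <- 1.0
    } else {
      assigned_cluster[i] <- hit
      identity[i] <- hit_id
    }
  }

  cluster_id <- sprintf("c%04d", assigned_cluster)
  members <- data.frame(sequence_name = nm,
                        cluster_id = cluster_id,
                        centroid_name = cent_name[assigned_cluster],
                        identity = identity,
                        stringsAsFactors = FALSE)
  members <- members[order(match(members$sequence_name, library$name)), ,
                     drop = FALSE]
  rownames(members) <- NULL
  structure(list(members = members,
                 centroids = setNames(cent_name,
                                      sprintf("c%04d", seq_along(cent_name))),
                 params = params),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: %d sequences in %d clusters (theta = %.2f)\n",
              nrow(x$members), length(x$centroids),
              x$params$identity_threshold))
  invisible(x)
}
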