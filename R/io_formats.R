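#' Read a RepeatMasker-style .out annotation table
#'
#' Parses the standard `.out` dialect: three header lines followed by
#' whitespace-delimited records with score, percent divergence, query
#' sequence, 1-based inclusive begin/end, orientation (`+` or `C`),
#' repeat name and repeat class/family. Coordinates are converted to
#' 0-based half-open on input; orientation `C` becomes `-`. Records
#' flagged with a trailing `*` (overlapping a higher-scoring hit) are
#' retained: overlap resolution is the job of the quantification stage,
#' not the parser.
#'
#' @param path Path to a `.out` file.
#' @param genome_id Genome identifier attached to the result; defaults
#'   to the file name without extension.
#' @param index Optional genome index (see [read_genome_index()]); when
#'   supplied, every interval is validated against sequence lengths.
#' @return A `data.frame` of repeat hits with columns `seq_id`, `start`,
#'   `end` (0-based half-open), `strand`, `repeat_name`, `repeat_class`,
#'   `divergence_pct`, `score`, `cluster_id` (NA until clusters are
#'   attached), carrying attribute `genome_id`.
#' @export
read_repeat_annotation <- function(path, genome_id = NULL, index = NULL) {
  .rs_assert(file.exists(path), "no such file: %s", path)
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  lines <- readLines(path)
  body <- if (length(lines) > 3L) lines[-(1:3)] else character(0)
  keep <- nzchar(trimws(body))
  body <- body[keep]
  lineno <- which(keep) + 3L
  if (length(body) == 0L)
    return(.empty_hits(genome_id))
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad))
    stop(sprintf("malformed .out record at line %d of %s (%d fields, need >= 11)",
                 lineno[bad[1]], path, nf[bad[1]]), call. = FALSE)
  m <- t(vapply(fields, function(f) f[c(1, 2, 5, 6, 7, 9, 10, 11)],
                character(8)))
  begin <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  score <- suppressWarnings(as.numeric(m[, 1]))
  div <- suppressWarnings(as.numeric(m[, 2]))
  bad <- which(is.na(begin) | is.na(end) | is.na(score) | is.na(div))
  if (length(bad))
    stop(sprintf("malformed .out record at line %d of %s (non-numeric field)",
                 lineno[bad[1]], path), call. = FALSE)
  bad <- which(begin > end)
  if (length(bad))
    stop(sprintf("malformed .out record at line %d of %s (begin > end)",
                 lineno[bad[1]], path), call. = FALSE)
  strand <- ifelse(m[, 6] == "C", "-", ifelse(m[, 6] == "+", "+", "?"))
  cls <- m[, 8]
  cls[!nzchar(cls)] <- "Unknown"
  hits <- data.frame(seq_id = m[, 3],
                     start = begin - 1L,
                     end = end,
                     strand = strand,
                     repeat_name = m[, 7],
                     repeat_class = cls,
                     divergence_pct = div,
                     score = score,
                     cluster_id = NA_character_,
                     stringsAsFactors = FALSE)
  .rs_assert(all(hits$divergence_pct >= 0 & hits$divergence_pct <= 100),
             "divergence outside [0,100] in %s", path)
  if (!is.null(index)) .validate_intervals(hits, index, path)
  attr(hits, "genome_id") <- genome_id
  hits
}

#' @noRd
.empty_hits <- function(genome_id) {
  hits <- data.frame(seq_id = character(0), start = integer(0),
                     end = integer(0), strand = character(0),
                     repeat_name = character(0), repeat_class = character(0),
                     divergence_pct = numeric(0), score = numeric(0),
                     cluster_id = character(0), stringsAsFactors = FALSE)
  attr(hits, "genome_id") <- genome_id
  hits
}

#' @noRd
.validate_intervals <- function(df, index, what) {
  len <- index$lengths[df$seq_id]
  .rs_assert(!anyNA(len), "%s: sequence absent from genome index", what)
  .rs_assert(all(df$start >= 0 & df$start < df$end & df$end <= len),
             "%s: interval outside [0, sequence length)", what)
}

#' Write repeat hits back to the .out dialect
#'
#' Inverse of [read_repeat_annotation()]: coordinates are re-expressed as
#' 1-based inclusive and strand `-` as `C`. Fields not represented in the
#' hits table (deletion/insertion percentages, remaining-bp columns, hit
#' ID) are written as zeros/placeholders.
#'
#' @param hits Repeat hits `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repeat_annotation <- function(hits, path) {
  header <- c(
    "   SW   perc perc perc  query                 position in query     matching          repeat                position in repeat",
    "score   div. del. ins.  sequence              begin  end   (left)   repeat            class/family       begin  end    (left)  ID",
    "")
  rec <- sprintf("%6.0f %6.2f  0.0  0.0  %s %d %d (0) %s %s %s 1 %d (0) %d",
                 hits$score, hits$divergence_pct, hits$seq_id,
                 hits$start + 1L, hits$end,
                 ifelse(hits$strand == "-", "C", "+"),
                 hits$repeat_name, hits$repeat_class,
                 hits$end - hits$start, seq_len(nrow(hits)))
  writeLines(c(header, rec), path)
  invisible(path)
}

#' Read gene features from a GFF3 file
#'
#' Retains only `gene` features; all other feature types are skipped.
#' Coordinates are converted from 1-based inclusive to 0-based
#' half-open. The `ID` attribute becomes `gene_id` (required, unique);
#' an optional `family` attribute becomes `family_id`.
#'
#' @param path Path to a GFF3 file.
#' @param index Optional genome index used to validate intervals.
#' @return A `data.frame` with columns `gene_id`, `seq_id`, `start`,
#'   `end`, `strand`, `family_id`.
#' @export
read_gene_annotation <- function(path, index = NULL) {
  .rs_assert(file.exists(path), "no such file: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(data.frame(gene_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), family_id = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  .rs_assert(all(lengths(f) == 9L), "%s: GFF3 records must have 9 columns", path)
  m <- do.call(rbind, f)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  attr_field <- m[, 9]
  get_attr <- function(s, key) {
    hit <- regmatches(s, regexec(paste0("(?:^|;)", key, "=([^;]+)"), s))
    vapply(hit, function(h) if (length(h) == 2L) h[2] else NA_character_,
           character(1))
  }
  gene_id <- get_attr(attr_field, "ID")
  .rs_assert(!anyNA(gene_id), "%s: gene feature without ID attribute", path)
  .rs_assert(!anyDuplicated(gene_id), "%s: duplicate gene IDs", path)
  genes <- data.frame(gene_id = gene_id,
                      seq_id = m[, 1],
                      start = as.integer(m[, 4]) - 1L,
                      end = as.integer(m[, 5]),
                      strand = m[, 7],
                      family_id = get_attr(attr_field, "family"),
                      stringsAsFactors = FALSE)
  .rs_assert(all(genes$start >= 0 & genes$start < genes$end),
             "%s: invalid gene coordinates", path)
  if (!is.null(index)) .validate_intervals(genes, index, path)
  genes
}

#' Write gene records as GFF3
#' @param genes Gene `data.frame` as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  attrs <- ifelse(is.na(genes$family_id),
                  paste0("ID=", genes$gene_id),
                  paste0("ID=", genes$gene_id, ";family=", genes$family_id))
  rec <- sprintf("%s\trepeatscape\tgene\t%d\t%d\t.\t%s\t.\t%s",
                 genes$seq_id, genes$start + 1L, genes$end,
                 genes$strand, attrs)
  writeLines(c("##gff-version 3", rec), path)
  invisible(path)
}

#' Read a repeat consensus library from FASTA
#'
#' Headers follow repeat-library practice: `name#Class/Family`. A header
#' without `#` gets class `"Unknown"`. Symbols outside `ACGTN` trigger a
#' warning but sequences are kept verbatim.
#'
#' @param path Path to a FASTA file.
#' @return A `data.frame` with columns `name`, `class`, `sequence`.
#' @export
read_library_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  has_class <- grepl("#", headers, fixed = TRUE)
  name <- ifelse(has_class, sub("#.*$", "", headers), headers)
  cls <- ifelse(has_class, sub("^[^#]*#", "", headers), "Unknown")
  sq <- unname(as.character(seqs))
  if (any(grepl("[^ACGTN]", sq)))
    warning("library contains symbols outside ACGTN; kept verbatim")
  data.frame(name = unname(name), class = unname(cls), sequence = sq,
             stringsAsFactors = FALSE)
}

#' Write a repeat consensus library as FASTA with `name#class` headers
#' @param lib Library `data.frame` (`name`, `class`, `sequence`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(lib, path) {
  x <- Biostrings::DNAStringSet(lib$sequence)
  names(x) <- paste0(lib$name, "#", lib$class)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a rooted phylogenetic tree from Newick
#'
#' Wraps [ape::read.tree()] and enforces the contracts downstream stages
#' rely on: labelled, unique tips and branch lengths present and
#' nonnegative.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  .rs_assert(inherits(tree, "phylo"), "%s: not a Newick tree", path)
  .rs_assert(!is.null(tree$tip.label) && all(nzchar(tree$tip.label)),
             "%s: tree has unlabeled tips", path)
  .rs_assert(!anyDuplicated(tree$tip.label), "%s: duplicate tip labels", path)
  .rs_assert(!is.null(tree$edge.length), "%s: branch lengths required", path)
  .rs_assert(all(tree$edge.length >= 0), "%s: negative branch length", path)
  tree
}

#' Build or read a genome index (sequence name to length)
#'
#' `read_genome_index()` accepts a two-or-more-column TSV in `.fai`
#' layout (name, length, ...); `genome_index()` builds one from named
#' lengths. `assembly_size` is the exact sum of sequence lengths.
#'
#' @param path Path to a `.fai`-style TSV.
#' @param genome_id Genome identifier.
#' @return An object of class `genome_index`: list with `genome_id`,
#'   `lengths` (named numeric) and `assembly_size`.
#' @export
read_genome_index <- function(path, genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- tools::file_path_sans_ext(basename(path))
  tab <- read.table(path, sep = "\t", header = FALSE,
                    stringsAsFactors = FALSE)
  genome_index(setNames(as.numeric(tab[[2]]), tab[[1]]), genome_id)
}

#' @rdname read_genome_index
#' @param lengths Named numeric vector of sequence lengths (bp).
#' @export
genome_index <- function(lengths, genome_id = "genome") {
  .rs_assert(length(lengths) > 0 && !is.null(names(lengths)),
             "lengths must be a named vector")
  .rs_assert(all(lengths > 0), "all sequence lengths must be > 0")
  structure(list(genome_id = genome_id,
                 lengths = lengths,
                 assembly_size = sum(lengths)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("genome_index '%s': %d sequences, %.3f Mb\n",
              x$genome_id, length(x$lengths), x$assembly_size / 1e6))
  invisible(x)
}

#' Write a genome index as a .fai-style TSV
#' @param index A `genome_index`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_index <- function(index, path) {
  write.table(data.frame(names(index$lengths), as.integer(index$lengths)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write any record table as TSV
#' @param records A `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach cluster labels to repeat hits
#'
#' Joins a clustering result (see [greedy_cluster()]) onto a hits table
#' by consensus name; hits whose consensus is absent from the assignment
#' keep `cluster_id = NA`.
#'
#' @param hits Repeat hits `data.frame`.
#' @param assignment A `cluster_assignment` or its `$members` table.
#' @return The hits table with `cluster_id` filled in.
#' @export
assign_clusters <- function(hits, assignment) {
  members <- if (inherits(assignment, "cluster_assignment"))
    assignment$members else assignment
  idx <- match(hits$repeat_name, members$sequence_name)
  hits$cluster_id <- members$cluster_id[idx]
  hits
}
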