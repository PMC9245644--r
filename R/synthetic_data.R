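#' Configuration for the synthetic repeat-landscape generator
#'
#' The generator emulates the statistical structure of an annotated
#' genome: a consensus library over a class taxonomy, repeat copies
#' placed as a Poisson process with class-specific merged-density
#' targets, non-overlapping gene models, and optional planted regional
#' enrichments in which one category's placement intensity inside the
#' gene-flank regions of a chosen gene set is raised so that the
#' EXPECTED merged density there equals `fold` times background.
#' Everything is a pure function of `(config, seed)`.
#'
#' Intensities are overlap-corrected: a merged-density target d is
#' realized with raw coverage `-log(1 - d)`, so planted folds are folds
#' of merged (observable) density, not raw copy mass.
#'
#' @param seed Mandatory integer seed.
#' @param genome_id Genome label.
#' @param seq_lengths Named vector of sequence lengths (bp). Default two
#'   chromosomes totalling 10 Mb, small enough that a full pipeline run
#'   takes seconds.
#' @param classes `data.frame` with columns `class`, `density` (target
#'   merged background density in [0, 1)) and `copy_length` (mean copy
#'   length, bp). The default taxonomy carries the classes prominent in
#'   teleost repeatomes (BovB LINEs, Tc1 and Tigger DNA transposons,
#'   unclassifiable repeats, Rex-Babar LINEs, hAT-Charlie).
#' @param families_per_class Consensus families simulated per class.
#' @param consensus_length_range Range of consensus lengths (bp).
#' @param n_genes,gene_length Gene models (non-overlapping, uniform).
#' @param divergence_range Range of per-copy percent divergence.
#' @param enrichments List of planted enrichments; each element a list
#'   with `gene_set_id`, `m` (focal set size), `category` (class),
#'   `fold` (>= 0) and `flank` (bp). Entries sharing a `gene_set_id`
#'   share the same focal genes.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed,
                              genome_id = "simgenome",
                              seq_lengths = c(chr1 = 8e6, chr2 = 2e6),
                              classes = default_class_table(),
                              families_per_class = 3L,
                              consensus_length_range = c(300L, 3000L),
                              n_genes = 500L,
                              gene_length = 4000L,
                              divergence_range = c(0, 25),
                              enrichments = list()) {
  .rs_assert(!missing(seed) && is.numeric(seed), "seed is mandatory")
  .rs_assert(all(seq_lengths > 0), "sequence lengths must be positive")
  .rs_assert(all(c("class", "density", "copy_length") %in% names(classes)),
             "classes needs columns class, density, copy_length")
  .rs_assert(all(classes$density >= 0 & classes$density < 1),
             "class densities must be in [0, 1)")
  for (e in enrichments) {
    .rs_assert(all(c("gene_set_id", "m", "category", "fold", "flank") %in%
                     names(e)), "incomplete enrichment spec")
    .rs_assert(e$fold >= 0, "planted fold must be >= 0")
    d <- classes$density[classes$class == e$category]
    .rs_assert(length(d) == 1L, "enrichment category not in class table")
    .rs_assert(e$fold * d < 1,
               "planted density fold * background >= 1 is infeasible for %s",
               e$category)
  }
  structure(list(seed = as.integer(seed), genome_id = genome_id,
                 seq_lengths = seq_lengths, classes = classes,
                 families_per_class = as.integer(families_per_class),
                 consensus_length_range = as.integer(consensus_length_range),
                 n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 divergence_range = divergence_range,
                 enrichments = enrichments),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_class_table <- function() {
  data.frame(
    class = c("LINE/BovB", "DNA/TcMar-Tc1", "DNA/TcMar-Tigger",
              "Unknown", "LINE/Rex-Babar", "DNA/hAT-Charlie"),
    density = c(0.10, 0.18, 0.05, 0.08, 0.03, 0.02),
    copy_length = c(100L, 120L, 300L, 200L, 250L, 300L),
    stringsAsFactors = FALSE)
}

#' @noRd
.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a repeat consensus library
#'
#' Draws `families_per_class` random consensus sequences per class with
#' `name#Class/Family`-style identities that round-trip through
#' [read_library_fasta()].
#'
#' @param config A [simulation_config()].
#' @return Library `data.frame` (`name`, `class`, `sequence`).
#' @export
make_library <- function(config) {
  set.seed(.derive_seeds(config$seed, 8)[1])
  rows <- lapply(seq_len(nrow(config$classes)), function(i) {
    cls <- config$classes$class[i]
    slug <- gsub("[^A-Za-z0-9]", "-", cls)
    data.frame(
      name = sprintf("fam-%s-%d", slug, seq_len(config$families_per_class)),
      class = cls,
      sequence = vapply(seq_len(config$families_per_class), function(j)
        .random_dna(sample(seq(config$consensus_length_range[1],
                               config$consensus_length_range[2]), 1)),
        character(1)),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Non-overlapping uniform gene placement on one sequence via
# stick-breaking: shrink the axis by the total gene footprint, drop
# sorted uniform starts, then re-inflate.
#' @noRd
.place_genes <- function(n, L, gene_len) {
  .rs_assert(n * gene_len < L, "gene footprint exceeds sequence length")
  starts <- floor(sort(runif(n)) * (L - n * gene_len)) +
    (seq_len(n) - 1L) * gene_len
  data.frame(start = as.integer(starts),
             end = as.integer(starts + gene_len))
}

#' Generate a synthetic annotated genome with planted truth
#'
#' Produces, deterministically from `(config, seed)`: a repeat library,
#' repeat hits in the internal representation (plus `.out`/GFF3/index
#' files when `outdir` is given), non-overlapping gene models with
#' focal-family labels, and a truth record holding every planted
#' parameter together with the REALIZED densities so estimator error can
#' be separated from sampling noise.
#'
#' @param config A [simulation_config()].
#' @param outdir Optional directory; when given, writes
#'   `<genome_id>.out`, `<genome_id>.gff3`, `<genome_id>.fai`,
#'   `<genome_id>_library.fasta` and `<genome_id>_truth.json`.
#' @param emit_fasta Also write the genome sequence as FASTA (slow for
#'   multi-Mb genomes; intended for small fixtures). Copies are mutated
#'   consensus instances; intervening sequence is random.
#' @return A list with `hits`, `genes`, `index`, `library`, `truth`
#'   (class `planted_genome`).
#' @export
plant_genome <- function(config, outdir = NULL, emit_fasta = FALSE) {
  seeds <- .derive_seeds(config$seed, 8)
  lib <- make_library(config)
  set.seed(seeds[2])

  ## gene models, proportional to sequence length
  n_by_seq <- .apportion(config$n_genes, config$seq_lengths)
  genes <- do.call(rbind, lapply(names(config$seq_lengths), function(s) {
    n <- n_by_seq[[s]]
    if (n == 0L) return(NULL)
    g <- .place_genes(n, config$seq_lengths[[s]], config$gene_length)
    cbind(seq_id = s, g)
  }))
  genes <- data.frame(gene_id = sprintf("g%05d", seq_len(nrow(genes))),
                      seq_id = genes$seq_id, start = genes$start,
                      end = genes$end,
                      strand = sample(c("+", "-"), nrow(genes), TRUE),
                      family_id = NA_character_,
                      stringsAsFactors = FALSE)

  ## focal gene sets (shared across enrichments with the same id)
  set_ids <- unique(vapply(config$enrichments, `[[`, character(1),
                           "gene_set_id"))
  available <- seq_len(nrow(genes))
  focal_sets <- list()
  for (sid in set_ids) {
    m <- config$enrichments[[
      which(vapply(config$enrichments, `[[`, character(1),
                   "gene_set_id") == sid)[1]]]$m
    .rs_assert(length(available) >= m, "not enough genes for focal set %s", sid)
    pick <- sample(available, m)
    focal_sets[[sid]] <- genes$gene_id[pick]
    genes$family_id[pick] <- sid
    available <- setdiff(available, pick)
  }

  ## repeat copies: background everywhere + extra intensity in regions
  set.seed(seeds[3])
  index <- genome_index(config$seq_lengths, config$genome_id)
  hit_rows <- list()
  region_sets <- lapply(config$enrichments, function(e)
    flank_regions(genes[genes$gene_id %in% focal_sets[[e$gene_set_id]], ,
                        drop = FALSE], e$flank, index))
  for (i in seq_len(nrow(config$classes))) {
    cls <- config$classes$class[i]
    d <- config$classes$density[i]
    clen <- config$classes$copy_length[i]
    fam <- lib$name[lib$class == cls]
    if (d <= 0) next
    c_bg <- -log(1 - d)
    for (s in names(config$seq_lengths)) {
      L <- config$seq_lengths[[s]]
      n <- rpois(1, c_bg * L / clen)
      if (n > 0) {
        len <- pmax(10L, as.integer(round(clen * runif(n, 0.5, 1.5))))
        st <- floor(runif(n, 0, pmax(1, L - len)))
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(seq_id = s, start = as.integer(st),
                     end = as.integer(st + len), class = cls,
                     family = sample(fam, n, replace = TRUE),
                     stringsAsFactors = FALSE)
      }
    }
    for (k in seq_along(config$enrichments)) {
      e <- config$enrichments[[k]]
      if (e$category != cls || e$fold <= 1) next
      c_extra <- -log(1 - e$fold * d) - c_bg
      reg <- region_sets[[k]]
      for (r in seq_len(nrow(reg))) {
        rs <- reg$start[r]; re <- reg$end[r]
        L <- config$seq_lengths[[reg$seq_id[r]]]
        n <- rpois(1, c_extra * (re - rs) / clen)
        if (n == 0) next
        len <- pmax(10L, as.integer(round(clen * runif(n, 0.5, 1.5))))
        # start window [rs - len, re) gives uniform expected coverage on
        # [rs, re); copies are clipped to the region (and the sequence)
        st <- floor(runif(n, rs - len, re))
        a <- pmax(st, rs, 0)
        b <- pmin(st + len, re, L)
        keep <- b > a
        if (!any(keep)) next
        hit_rows[[length(hit_rows) + 1L]] <-
          data.frame(seq_id = reg$seq_id[r], start = as.integer(a[keep]),
                     end = as.integer(b[keep]), class = cls,
                     family = sample(fam, sum(keep), replace = TRUE),
                     stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(rbind, hit_rows)
  set.seed(seeds[4])
  hits <- data.frame(seq_id = raw$seq_id, start = raw$start, end = raw$end,
                     strand = sample(c("+", "-"), nrow(raw), TRUE),
                     repeat_name = raw$family,
                     repeat_class = raw$class,
                     divergence_pct = round(runif(nrow(raw),
                                                  config$divergence_range[1],
                                                  config$divergence_range[2]),
                                            1),
                     score = as.numeric(sample(200:3000, nrow(raw), TRUE)),
                     cluster_id = NA_character_,
                     stringsAsFactors = FALSE)
  ord <- order(hits$seq_id, hits$start, hits$end, method = "radix")
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "genome_id") <- config$genome_id

  truth <- .truth_record(config, hits, genes, index, focal_sets, region_sets)
  out <- structure(list(hits = hits, genes = genes, index = index,
                        library = lib, truth = truth),
                   class = "planted_genome")
  if (!is.null(outdir)) .write_planted(out, config, outdir, emit_fasta)
  out
}

#' @noRd
.apportion <- function(n, weights) {
  w <- weights / sum(weights)
  base <- floor(n * w)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(n * w - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  setNames(as.integer(base), names(weights))
}

#' @noRd
.truth_record <- function(config, hits, genes, index, focal_sets,
                          region_sets) {
  per_class <- category_occupancy(hits, index, "class")
  enr <- lapply(seq_along(config$enrichments), function(k) {
    e <- config$enrichments[[k]]
    reg <- region_sets[[k]]
    ch <- hits[hits$repeat_class == e$category, , drop = FALSE]
    reg_density <- region_density(reg, ch)
    # background = density of the category outside this gene set's regions
    merged <- merge_intervals(ch)
    reg_bp <- attr(reg, "total_bp")
    in_bp <- reg_density * reg_bp
    bg_density <- (attr(merged, "total_bp") - in_bp) /
      (index$assembly_size - reg_bp)
    list(gene_set_id = e$gene_set_id, category = e$category,
         m = e$m, flank = e$flank,
         planted_fold = e$fold,
         focal_gene_ids = focal_sets[[e$gene_set_id]],
         region_bp = reg_bp,
         realized_region_density = reg_density,
         realized_background_density = bg_density,
         realized_fold = reg_density / bg_density)
  })
  list(genome_id = config$genome_id, seed = config$seed,
       assembly_size = index$assembly_size,
       n_hits = nrow(hits), n_genes = nrow(genes),
       total_repeat_proportion = per_class$total_repeat_proportion,
       class_occupancy = as.list(per_class$occupancy),
       enrichments = enr)
}

#' @noRd
.write_planted <- function(pg, config, outdir, emit_fasta) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(ext) file.path(outdir, paste0(config$genome_id, ext))
  write_repeat_annotation(pg$hits, p(".out"))
  write_gene_annotation(pg$genes, p(".gff3"))
  write_genome_index(pg$index, p(".fai"))
  write_library_fasta(pg$library, p("_library.fasta"))
  jsonlite::write_json(pg$truth, p("_truth.json"), auto_unbox = TRUE,
                       digits = NA)
  if (emit_fasta) .write_planted_fasta(pg, config, p(".fasta"))
  invisible(outdir)
}

# Sequence emission is table-faithful, not alignment-faithful: each
# copy's bases are a substitution-mutated, length-adjusted consensus
# instance; everything else is random.
#' @noRd
.write_planted_fasta <- function(pg, config, path) {
  set.seed(.derive_seeds(config$seed, 8)[5])
  cons <- setNames(pg$library$sequence, pg$library$name)
  seqs <- lapply(names(config$seq_lengths), function(s) {
    L <- config$seq_lengths[[s]]
    chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    h <- pg$hits[pg$hits$seq_id == s, , drop = FALSE]
    for (i in seq_len(nrow(h))) {
      w <- h$end[i] - h$start[i]
      tmpl <- strsplit(cons[[h$repeat_name[i]]], "", fixed = TRUE)[[1]]
      tmpl <- rep_len(tmpl, w)
      nmut <- round(w * h$divergence_pct[i] / 100)
      if (nmut > 0) {
        at <- sample.int(w, nmut)
        tmpl[at] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
      }
      chars[(h$start[i] + 1):h$end[i]] <- tmpl
    }
    paste(chars, collapse = "")
  })
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(config$seq_lengths)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Simulate traits under Brownian motion along a tree
#'
#' Generates `y = a + b x + e`, where `e` is multivariate normal with
#' covariance `sigma2 * V(tree)` — the model [pgls_fit()] assumes — so
#' planted regression parameters are recoverable ground truth.
#'
#' @param tree A rooted [ape::phylo] tree.
#' @param a,b Planted intercept and slope.
#' @param sigma2 Brownian rate (trait variance per unit branch length).
#' @param x Predictor values, one per tip (recycled in tip-label order;
#'   may be named by tip).
#' @param seed Integer seed.
#' @return Trait `data.frame` (`genome_id`, `x`, `y`).
#' @export
simulate_bm_traits <- function(tree, a, b, sigma2, x, seed) {
  tips <- tree$tip.label
  n <- length(tips)
  if (!is.null(names(x))) x <- x[tips]
  x <- rep_len(x, n)
  V <- tree_vcv(tree)
  set.seed(seed)
  eps <- if (sigma2 == 0) numeric(n) else
    as.numeric(t(chol(sigma2 * V)) %*% rnorm(n))
  data.frame(genome_id = tips, x = unname(x), y = a + b * x + eps,
             stringsAsFactors = FALSE)
}

#' Random ultrametric tree
#'
#' Coalescent-shaped random tree rescaled to unit root-to-tip depth —
#' a convenient ultrametric phylogeny for simulation studies.
#'
#' @param n_tips Number of tips.
#' @param seed Integer seed.
#' @return An [ape::phylo] tree of depth 1.
#' @export
sim_ultrametric_tree <- function(n_tips, seed) {
  set.seed(seed)
  tree <- ape::rcoal(n_tips, tip.label = sprintf("t%02d", seq_len(n_tips)))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree
}
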