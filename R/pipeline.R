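#' Run the whole repeatome pipeline from a configuration
#'
#' Orchestrates parsing, clustering, occupancy and window
#' quantification, ordination, rank-abundance profiling, regional
#' enrichment testing and PGLS from a single configuration, writing all
#' result tables plus a run manifest to `outdir`. Re-running with an
#' identical configuration and seed reproduces byte-identical outputs.
#'
#' The configuration is a named list (or path to a JSON document) with:
#' \describe{
#'   \item{genomes}{list of `list(genome_id, out, gff, fai)` paths;}
#'   \item{library}{optional consensus FASTA to cluster;}
#'   \item{cluster}{optional [clustering_params()] fields;}
#'   \item{window_size}{window size in bp (default 100000);}
#'   \item{pca}{`list(scale = FALSE)`;}
#'   \item{rad}{`list(top_n = 100)`;}
#'   \item{enrichment}{optional `list(focal_family, categories, flank,
#'     n_resamples, fdr_level)` — run per genome whose GFF3 carries the
#'     focal `family` attribute;}
#'   \item{tree}{optional Newick path; when present, repeat proportion is
#'     regressed on assembly size (Mb) across genomes by PGLS;}
#'   \item{seed}{global seed, propagated to every stochastic stage.}
#' }
#'
#' @param config Named list or path to a JSON config file.
#' @param outdir Output directory (created if absent).
#' @return The manifest, invisibly.
#' @export
full_run <- function(config, outdir) {
  if (is.character(config)) config <- jsonlite::read_json(config)
  .rs_assert(!is.null(config$genomes) && length(config$genomes) > 0,
             "config must list at least one genome")
  .rs_assert(!is.null(config$seed), "config must carry a seed")
  for (g in config$genomes)
    for (f in c("out", "gff", "fai"))
      .rs_assert(file.exists(g[[f]]),
                 "stage validate: missing %s file for genome %s: %s",
                 f, g$genome_id, g[[f]])
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character(0)
  counts <- list()
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_table(df, path)
    artifacts <<- c(artifacts, name)
    path
  }
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  parsed <- stage("parse", {
    lapply(config$genomes, function(g) {
      index <- read_genome_index(g$fai, g$genome_id)
      list(id = g$genome_id,
           hits = read_repeat_annotation(g$out, g$genome_id, index),
           genes = read_gene_annotation(g$gff, index),
           index = index)
    })
  })
  ids <- vapply(parsed, `[[`, character(1), "id")
  names(parsed) <- ids
  counts$hits <- lapply(parsed, function(p) nrow(p$hits))

  assignment <- NULL
  if (!is.null(config$library)) {
    assignment <- stage("cluster", {
      lib <- read_library_fasta(config$library)
      cp <- do.call(clustering_params, as.list(config$cluster))
      greedy_cluster(lib, cp)
    })
    emit(assignment$members, "clusters.tsv")
    for (id in ids)
      parsed[[id]]$hits <- assign_clusters(parsed[[id]]$hits, assignment)
  }

  occ <- stage("quantify", {
    hl <- lapply(parsed, `[[`, "hits")
    il <- lapply(parsed, `[[`, "index")
    occupancy_table(hl, il, "class")
  })
  emit(data.frame(genome_id = rownames(occ$matrix),
                  total_repeat_proportion = occ$total_repeat_proportion,
                  occ$matrix, check.names = FALSE), "occupancy_class.tsv")

  windows <- stage("windows", {
    do.call(rbind, lapply(parsed, function(p) {
      w <- window_density(p$hits, p$index,
                          window_size = config$window_size %||% 100000L)
      cbind(genome_id = p$id, w)
    }))
  })
  emit(windows, "windows.tsv")

  if (length(ids) >= 2) {
    pca <- stage("ordinate", {
      repeat_pca(relative_class_frequencies(occ$matrix),
                 scale = isTRUE(config$pca$scale))
    })
    emit(data.frame(genome_id = rownames(pca$scores), pca$scores,
                    check.names = FALSE), "pca_scores.tsv")
    emit(data.frame(category = rownames(pca$loadings), pca$loadings,
                    check.names = FALSE), "pca_loadings.tsv")
    emit(data.frame(component = seq_along(pca$variance_explained),
                    variance_explained = pca$variance_explained),
         "pca_variance.tsv")
  }

  if (!is.null(assignment)) {
    rad <- stage("rad", {
      do.call(rbind, lapply(parsed, function(p) {
        co <- category_occupancy(p$hits, p$index, "cluster")
        r <- rank_abundance(co$occupancy, config$rad$top_n %||% 100L, p$id)
        cbind(genome_id = p$id, r)
      }))
    })
    emit(rad, "rad.tsv")
  }

  if (!is.null(config$enrichment)) {
    enr <- stage("enrich", {
      ec <- config$enrichment
      do.call(rbind, lapply(parsed, function(p) {
        focal <- p$genes[!is.na(p$genes$family_id) &
                           p$genes$family_id == ec$focal_family, ,
                         drop = FALSE]
        if (nrow(focal) == 0) return(NULL)
        ep <- enrichment_params(flank = ec$flank %||% 1000L,
                                n_resamples = ec$n_resamples %||% 499L,
                                fdr_level = ec$fdr_level %||% 0.1,
                                seed = config$seed)
        sc <- scan_categories(focal, p$hits, p$genes, p$index,
                              unlist(ec$categories), ep,
                              include_total = TRUE,
                              gene_set_id = ec$focal_family)
        cbind(genome_id = p$id, sc)
      }))
    })
    if (!is.null(enr)) emit(enr, "enrichment.tsv")
  }

  if (!is.null(config$tree) && length(ids) >= 3) {
    fit <- stage("pgls", {
      tree <- read_tree(config$tree)
      traits <- data.frame(
        genome_id = ids,
        x = vapply(parsed, function(p) p$index$assembly_size / 1e6,
                   numeric(1)),
        y = unname(occ$total_repeat_proportion))
      pgls_fit(traits, tree)
    })
    path <- file.path(outdir, "pgls.json")
    jsonlite::write_json(fit[c("intercept", "slope", "se", "t", "df", "p",
                               "sigma2", "n")],
                         path, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, "pgls.json")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("repeatscape")),
    seed = config$seed,
    config_md5 = .config_md5(config),
    genomes = as.list(counts$hits),
    artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.config_md5 <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Command-line entry point
#'
#' Thin subcommand dispatcher (`repeatscape <subcommand> --key value
#' ...`) over the package's main functions, suitable for
#' `Rscript -e 'repeatscape::rs_cli()' <args>` or the installed
#' `inst/cli/repeatscape` launcher. Subcommands: `parse`, `cluster`,
#' `quantify`, `windows`, `ordinate`, `rad`, `enrich`, `pgls`,
#' `simulate`, `full-run`. Logs go to stderr; results only ever to
#' files.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status 0, invisibly.
#' @export
rs_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  .rs_assert(length(args) >= 1, "usage: repeatscape <subcommand> [--key value ...]")
  cmd <- args[1]
  opt <- .parse_cli_opts(args[-1])
  need <- function(key) {
    .rs_assert(!is.null(opt[[key]]), "%s: missing required --%s", cmd, key)
    opt[[key]]
  }
  switch(cmd,
    "parse" = {
      index <- if (!is.null(opt[["genome-index"]]))
        read_genome_index(opt[["genome-index"]]) else NULL
      hits <- read_repeat_annotation(need("out"), index = index)
      if (!is.null(opt$gff))
        write_table(read_gene_annotation(opt$gff, index),
                    paste0(need("outdir"), "/genes.tsv"))
      write_table(hits, paste0(need("outdir"), "/hits.tsv"))
    },
    "cluster" = {
      lib <- read_library_fasta(need("library"))
      cp <- clustering_params(
        identity_threshold = as.numeric(opt$identity %||% 0.8))
      write_table(greedy_cluster(lib, cp)$members, need("out"))
    },
    "quantify" = {
      index <- read_genome_index(need("index"))
      hits <- read_repeat_annotation(need("hits"), index = index)
      occ <- category_occupancy(hits, index, opt$by %||% "class")
      write_table(data.frame(category = names(occ$occupancy),
                             proportion = unname(occ$occupancy)),
                  need("out"))
    },
    "windows" = {
      index <- read_genome_index(need("index"))
      hits <- read_repeat_annotation(need("hits"), index = index)
      write_table(window_density(hits, index,
                                 as.integer(opt$window %||% 100000L)),
                  need("out"))
    },
    "ordinate" = {
      mat <- as.matrix(read.table(need("matrix"), header = TRUE,
                                  row.names = 1, sep = "\t",
                                  check.names = FALSE))
      pca <- repeat_pca(mat, scale = isTRUE(opt$scale == "true"))
      base <- need("outdir")
      write_table(data.frame(genome_id = rownames(pca$scores), pca$scores,
                             check.names = FALSE),
                  file.path(base, "scores.tsv"))
      write_table(data.frame(category = rownames(pca$loadings),
                             pca$loadings, check.names = FALSE),
                  file.path(base, "loadings.tsv"))
      write_table(data.frame(component = seq_along(pca$variance_explained),
                             variance_explained = pca$variance_explained),
                  file.path(base, "variance.tsv"))
    },
    "rad" = {
      mat <- as.matrix(read.table(need("matrix"), header = TRUE,
                                  row.names = 1, sep = "\t",
                                  check.names = FALSE))
      out <- do.call(rbind, lapply(rownames(mat), function(g)
        cbind(genome_id = g,
              rank_abundance(mat[g, ], as.integer(opt$top %||% 100L), g))))
      write_table(out, need("out"))
    },
    "enrich" = {
      index <- read_genome_index(need("index"))
      hits <- read_repeat_annotation(need("hits"), index = index)
      genes <- read_gene_annotation(need("genes"), index)
      focal_ids <- readLines(need("focal"))
      focal <- genes[genes$gene_id %in% focal_ids, , drop = FALSE]
      ep <- enrichment_params(flank = as.integer(opt$flank %||% 1000L),
                              n_resamples = as.integer(opt$resamples %||% 499L),
                              fdr_level = as.numeric(opt$fdr %||% 0.1),
                              seed = as.integer(need("seed")))
      cats <- strsplit(need("classes"), ",", fixed = TRUE)[[1]]
      write_table(scan_categories(focal, hits, genes, index,
                                  setdiff(cats, "total"), ep,
                                  include_total = "total" %in% cats),
                  need("out"))
    },
    "pgls" = {
      tree <- read_tree(need("tree"))
      traits <- read.table(need("traits"), header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
      fit <- pgls_fit(traits, tree, x = opt$x %||% "x", y = opt$y %||% "y")
      jsonlite::write_json(fit[c("intercept", "slope", "se", "t", "df",
                                 "p", "sigma2", "n")],
                           need("out"), auto_unbox = TRUE, digits = NA)
    },
    "simulate" = {
      cfgl <- jsonlite::read_json(need("config"), simplifyVector = TRUE)
      cfgl$enrichments <- lapply(
        if (is.data.frame(cfgl$enrichments))
          split(cfgl$enrichments, seq_len(nrow(cfgl$enrichments)))
        else cfgl$enrichments,
        as.list)
      if (!is.null(cfgl$classes)) cfgl$classes <- as.data.frame(cfgl$classes)
      if (!is.null(cfgl$seq_lengths))
        cfgl$seq_lengths <- unlist(cfgl$seq_lengths)
      cfg <- do.call(simulation_config, cfgl)
      plant_genome(cfg, outdir = need("outdir"))
    },
    "full-run" = {
      full_run(need("config"), need("outdir"))
    },
    stop(sprintf("unknown subcommand: %s", cmd), call. = FALSE)
  )
  invisible(0L)
}

#' @noRd
.parse_cli_opts <- function(args) {
  opt <- list()
  i <- 1L
  while (i <= length(args)) {
    .rs_assert(startsWith(args[i], "--"), "expected --option, got %s", args[i])
    key <- substring(args[i], 3)
    .rs_assert(i + 1L <= length(args), "missing value for --%s", key)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opt
}
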