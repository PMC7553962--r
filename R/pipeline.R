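#' Pipeline configuration
#'
#' Bundles the per-stage parameters of an end-to-end run with their
#' standard defaults (KS threshold 0.15, minimum cluster 30, edge alpha
#' 1e-10, module alpha 1e-3, perplexity 30, 50 random sets within 10%,
#' 100 mutation randomizations).
#'
#' @param sim A [sim_config()] describing the synthetic study (used by
#'   the `simulate` stage; omit `sim` and supply `gem_path` etc. to run
#'   on existing files).
#' @param gem_path,labels_path,gene_lengths_path,mutations_path Input
#'   files used when `sim` is `NULL`.
#' @param ks_threshold,min_cluster,max_components,tau_override,edge_alpha,module_alpha,min_module_edges,perplexity,n_random,size_tolerance,n_rand_mutation
#'   Stage parameters.
#' @param merge_map Optional named vector or YAML path for
#'   [merge_anatomical()].
#' @param seed Master seed.
#' @return A list of class `csgcn_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), gem_path = NULL,
                            labels_path = NULL, gene_lengths_path = NULL,
                            mutations_path = NULL, ks_threshold = 0.15,
                            min_cluster = 30, max_components = 5,
                            tau_override = NULL, edge_alpha = 1e-10,
                            module_alpha = 1e-3, min_module_edges = 3,
                            perplexity = 30, n_random = 50,
                            size_tolerance = 0.10, n_rand_mutation = 100,
                            merge_map = NULL, seed = 1L) {
  structure(as.list(environment()), class = "csgcn_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file whose top-level keys match the
#'   [pipeline_config()] arguments (`sim` given as a list of
#'   [sim_config()] arguments).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

write_stage <- function(files, path, writer, obj) {
  writer(obj, path)
  path
}

#' Run the end-to-end pipeline
#'
#' Executes, in order: simulate (or load), preprocess, similarity scan,
#' threshold + extract, link communities, edge/module enrichment, region
#' set selection (and anatomical merging when a map is given), phase-I
#' screening of the region gene sets, phase-II decomposition of the
#' first significant set, mutation enrichment, and embedding.  Every
#' stage's outputs are written under `out_dir` and recorded in a
#' manifest with content hashes; reruns with the same config reproduce
#' all outputs.
#'
#' @param config A `csgcn_pipeline_config` (or a YAML path).
#' @param out_dir Output directory.
#' @param from,to Optional stage names bounding the run (stages:
#'   `simulate`, `preprocess`, `network`, `communities`, `enrichment`,
#'   `screen`, `decompose`, `mutations`, `embed`).  Earlier stages must
#'   have been run into the same `out_dir`.
#' @return A list of class `csgcn_pipeline_result` with the stage
#'   results and a `manifest` tibble (`file`, `md5`, `stage`).
#' @export
run_pipeline <- function(config, out_dir, from = "simulate", to = "embed") {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "csgcn_pipeline_config"))
  stages <- c("simulate", "preprocess", "network", "communities",
              "enrichment", "screen", "decompose", "mutations", "embed")
  from_i <- match(match.arg(from, stages), stages)
  to_i <- match(match.arg(to, stages), stages)
  assert_that(from_i <= to_i, "`from` stage is after `to`")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list()
  note <- function(stage, ...) {
    for (f in c(...))
      manifest[[length(manifest) + 1]] <<-
        tibble::tibble(file = f, md5 = unname(tools::md5sum(f)),
                       stage = stage)
  }
  res <- list(config = config)
  active <- function(s) {
    i <- match(s, stages)
    i >= from_i && i <= to_i
  }

  # -- simulate / load ------------------------------------------------
  if (active("simulate") && !is.null(config$sim)) {
    paths <- simulate_study(config$sim, out_dir)
    note("simulate", paths)
  }
  gem_path <- config$gem_path %||% file.path(out_dir, "gem.tsv")
  labels_path <- config$labels_path %||% file.path(out_dir, "labels.tsv")
  lengths_path <- config$gene_lengths_path %||%
    file.path(out_dir, "gene_lengths.tsv")
  mut_path <- config$mutations_path %||% file.path(out_dir, "mutations.tsv")
  raw <- read_gem(gem_path, labels = labels_path,
                  gene_lengths = lengths_path)

  # -- preprocess -----------------------------------------------------
  if (active("preprocess")) {
    pp <- preprocess_gem(raw, ks_threshold = config$ks_threshold)
    res$preprocess <- pp
    f1 <- file.path(out_dir, "gem_preprocessed.tsv")
    f2 <- file.path(out_dir, "ks_report.tsv")
    write_gem(pp$gem, f1)
    write_preprocess_report(pp$report, f2)
    note("preprocess", f1, f2)
  } else {
    pp <- list(gem = read_gem(file.path(out_dir, "gem_preprocessed.tsv"),
                              labels = labels_path,
                              gene_lengths = lengths_path))
    pp$gem$scale <- "log2"
  }
  gp <- pp$gem

  # -- network --------------------------------------------------------
  if (active("network")) {
    ec <- similarity_scan(gp, min_cluster = config$min_cluster,
                          max_components = config$max_components,
                          seed = derive_seed(config$seed, 21L))
    thr <- rmt_threshold(ec, tau_override = config$tau_override)
    tau <- if (thr$no_threshold) {
      warning("no RMT transition found; using the 0.85 fallback threshold")
      0.85
    } else thr$tau
    net <- extract_network(ec, tau)
    res$edge_clusters <- ec
    res$threshold <- thr
    res$network <- net
    f1 <- file.path(out_dir, "edges_all.tsv")
    f2 <- file.path(out_dir, "network_edges.tsv")
    f3 <- file.path(out_dir, "rmt_trace.tsv")
    write_edges(ec, f1)
    write_edges(net$edges, f2)
    readr::write_tsv(thr$scan_trace, f3)
    note("network", f1, f2, f3)
  } else {
    ec <- read_edges(file.path(out_dir, "edges_all.tsv"))
    attr(ec, "sample_ids") <- colnames(gp$values)
    net <- extract_network(ec, config$tau_override %||% 0.85)
    net$sample_ids <- colnames(gp$values)
    res$network <- net
  }

  # -- communities + enrichment --------------------------------------
  if (active("communities")) {
    lc <- link_communities(net, min_edges = config$min_module_edges)
    res$communities <- lc
    f <- file.path(out_dir, "modules.tsv")
    write_modules(lc, f)
    note("communities", f)
  }
  if (active("enrichment")) {
    er <- edge_label_enrichment(net, gp$labels)
    res$edge_enrichment <- er
    rs <- select_region_sets(er, edge_alpha = config$edge_alpha)
    res$region_sets <- rs
    if (res$communities$n_modules %||% 0 > 0) {
      res$module_enrichment <- module_label_enrichment(
        res$communities, net, gp$labels)
    }
    if (!is.null(config$merge_map)) {
      res$merged <- merge_anatomical(rs, config$merge_map)
      res$gene_sets <- merged_gene_sets(res$merged)
    } else {
      res$gene_sets <- lapply(
        split(rs$region_nodes$gene, rs$region_nodes$region), unique)
    }
    f1 <- file.path(out_dir, "edge_enrichment.tsv")
    f2 <- file.path(out_dir, "region_edges.tsv")
    readr::write_tsv(tibble::as_tibble(er), f1)
    readr::write_tsv(rs$region_edges, f2)
    note("enrichment", f1, f2)
  }

  # -- screening ------------------------------------------------------
  if (active("screen")) {
    sets <- purrr::keep(res$gene_sets, ~ length(.x) >= 2)
    res$screen <- phase1_screen(
      gp, sets, n_random = config$n_random,
      size_tolerance = config$size_tolerance,
      seed = derive_seed(config$seed, 22L))
    f <- file.path(out_dir, "phase1_screen.tsv")
    readr::write_tsv(tibble::as_tibble(res$screen), f)
    note("screen", f)
  }

  # -- decomposition --------------------------------------------------
  if (active("decompose") && !is.null(res$screen) &&
      any(res$screen$significant)) {
    sig_sets <- res$screen$set[res$screen$significant]
    sizes <- res$screen$size[res$screen$significant]
    pick <- sig_sets[which.min(sizes)]
    gs <- res$gene_sets[[pick]]
    if (length(gs) >= 4) {
      res$decomposition <- phase2_combinatorial(
        gp, gs, seed = derive_seed(config$seed, 23L))
      f <- file.path(out_dir, "decomposition_frequency.tsv")
      readr::write_tsv(res$decomposition$frequency, f)
      writeLines(res$decomposition$candidates,
                 file.path(out_dir, "candidates.txt"))
      note("decompose", f, file.path(out_dir, "candidates.txt"))
    }
  }

  # -- mutations ------------------------------------------------------
  if (active("mutations") && file.exists(mut_path)) {
    muts <- read_mutations(mut_path)
    universe <- intersect(rownames(gp$values), names(gp$gene_lengths))
    sets <- purrr::keep(res$gene_sets %||% list(),
                        ~ length(.x) >= 2)
    if (length(sets) > 0) {
      res$mutation_enrichment <- mutation_enrichment_table(
        muts, sets, universe, gp$gene_lengths,
        n_rand = config$n_rand_mutation,
        seed = derive_seed(config$seed, 24L))
      f <- file.path(out_dir, "mutation_enrichment.tsv")
      readr::write_tsv(res$mutation_enrichment, f)
      note("mutations", f)
    }
  }

  # -- embedding ------------------------------------------------------
  if (active("embed") && length(res$gene_sets %||% list()) > 0) {
    genes <- unique(unlist(res$gene_sets))
    if (length(genes) >= 2 &&
        ncol(gp$values) > 3 * config$perplexity) {
      res$embedding <- project_samples(
        gp, genes, perplexity = config$perplexity,
        seed = derive_seed(config$seed, 25L))
      f <- file.path(out_dir, "embedding.tsv")
      readr::write_tsv(tibble::as_tibble(res$embedding), f)
      note("embed", f)
    }
  }

  res$manifest <- dplyr::bind_rows(manifest)
  readr::write_tsv(res$manifest, file.path(out_dir, "manifest.tsv"))
  class(res) <- "csgcn_pipeline_result"
  res
}

#' @export
print.csgcn_pipeline_result <- function(x, ...) {
  cat("<csgcn_pipeline_result> stages written:",
      paste(unique(x$manifest$stage), collapse = ", "), "\n")
  invisible(x)
}
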