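#' Sample-label enrichment of condition-specific edges
#'
#' For every edge cluster and every region label, builds the 2x2 table
#' of samples in/out of the edge's cluster (mask `'1'` vs `'0'`; `'9'`
#' samples excluded) against samples having/lacking the label, and
#' computes the one-sided (enrichment) Fisher exact p-value, i.e. the
#' upper hypergeometric tail.  P-values are Hochberg-adjusted, by default
#' over the whole edge-by-label family.
#'
#' @param edges Edge-cluster tibble (from [extract_network()]'s `edges`
#'   element, or [similarity_scan()] output) with a `sample_mask` column.
#' @param labels Named character vector, sample id -> region label,
#'   covering every sample in the mask ordering.
#' @param sample_ids Character vector giving the sample order of the mask
#'   strings; defaults to the `sample_ids` attribute of `edges` (or of a
#'   `csgcn_network` passed as `edges`).
#' @param family Hochberg adjustment family: `"global"` adjusts all
#'   edge-by-label tests together, `"per_target"` within each edge.
#' @return A tibble of class `csgcn_enrichment`: `target`, `gene_a`,
#'   `gene_b`, `cluster_index`, `label`, the 2x2 cells `a` (in-cluster
#'   with label), `b` (in-cluster without), `c` (out-of-cluster with),
#'   `d` (out-of-cluster without), `p_raw`, `p_adj`.
#' @export
edge_label_enrichment <- function(edges, labels, sample_ids = NULL,
                                  family = c("global", "per_target")) {
  family <- match.arg(family)
  if (inherits(edges, "csgcn_network")) {
    sample_ids <- sample_ids %||% edges$sample_ids
    edges <- edges$edges
  }
  sample_ids <- sample_ids %||% attr(edges, "sample_ids")
  assert_that(!is.null(sample_ids),
              "sample_ids not found; pass the mask sample order explicitly")
  assert_that(all(sample_ids %in% names(labels)),
              "labels must cover every sample")
  lab <- labels[sample_ids]
  ulab <- sort(unique(unname(lab)))
  n_e <- nrow(edges)
  assert_that(n_e > 0, "no edges to test")
  chars <- do.call(rbind, strsplit(edges$sample_mask, "", fixed = TRUE))
  assert_that(ncol(chars) == length(sample_ids),
              "mask length does not match sample_ids")
  in_cl <- chars == "1"
  eligible <- chars != "9"
  res <- purrr::map_dfr(ulab, function(L) {
    has <- matrix(rep(lab == L, each = n_e), nrow = n_e)
    a <- rowSums(in_cl & has)
    b <- rowSums(in_cl & !has & eligible)
    cc <- rowSums(!in_cl & eligible & has)
    d <- rowSums(!in_cl & eligible & !has)
    p <- phyper(a - 1, a + cc, b + d, a + b, lower.tail = FALSE)
    tibble::tibble(
      target = edge_key(edges$gene_a, edges$gene_b, edges$cluster_index),
      gene_a = edges$gene_a, gene_b = edges$gene_b,
      cluster_index = edges$cluster_index, label = L,
      a = a, b = b, c = cc, d = d, p_raw = p)
  })
  res$p_adj <- if (family == "global") {
    p.adjust(res$p_raw, method = "hochberg")
  } else {
    stats::ave(res$p_raw, res$target,
               FUN = function(p) p.adjust(p, method = "hochberg"))
  }
  class(res) <- c("csgcn_enrichment", class(res))
  attr(res, "family") <- family
  attr(res, "n_regions") <- length(ulab)
  res
}

#' Sample-label enrichment of link-community modules
#'
#' A module's sample set is, by default, the union of its member edges'
#' in-cluster (`'1'`) samples; `"intersection"` requires membership in
#' every member edge.  A sample enters the 2x2 table if it is eligible
#' (non-`'9'`) in at least one member edge.  The Fisher/Hochberg
#' machinery matches [edge_label_enrichment()]; modules are called
#' significantly enriched at adjusted p < 1e-3 downstream.
#'
#' @param modules A `csgcn_linkcomm` from [link_communities()], or a
#'   tibble (`module_id`, `gene_a`, `gene_b`).
#' @param edges Edge-cluster tibble carrying the `sample_mask` per gene
#'   pair (all clusters of a member pair contribute).
#' @param sample_set `"union"` or `"intersection"`.
#' @inheritParams edge_label_enrichment
#' @return A `csgcn_enrichment` tibble with `target` = module id.
#' @export
module_label_enrichment <- function(modules, edges, labels,
                                    sample_ids = NULL,
                                    sample_set = c("union", "intersection"),
                                    family = c("global", "per_target")) {
  sample_set <- match.arg(sample_set)
  family <- match.arg(family)
  if (inherits(modules, "csgcn_linkcomm")) modules <- modules$modules
  if (inherits(edges, "csgcn_network")) {
    sample_ids <- sample_ids %||% edges$sample_ids
    edges <- edges$edges
  }
  sample_ids <- sample_ids %||% attr(edges, "sample_ids")
  assert_that(!is.null(sample_ids), "sample_ids not found")
  assert_that(nrow(modules) > 0, "no modules to test")
  lab <- labels[sample_ids]
  ulab <- sort(unique(unname(lab)))
  mods <- unique(modules$module_id)
  mem <- dplyr::inner_join(
    dplyr::select(modules, "module_id", "gene_a", "gene_b"),
    dplyr::select(edges, "gene_a", "gene_b", "sample_mask"),
    by = c("gene_a", "gene_b"))
  res <- purrr::map_dfr(mods, function(mid) {
    msk <- mem$sample_mask[mem$module_id == mid]
    ch <- do.call(rbind, strsplit(msk, "", fixed = TRUE))
    eligible <- colSums(ch != "9") > 0
    in_mod <- if (sample_set == "union") colSums(ch == "1") > 0
      else colSums(ch == "1") == nrow(ch)
    purrr::map_dfr(ulab, function(L) {
      has <- lab == L
      a <- sum(in_mod & has)
      b <- sum(in_mod & !has & eligible)
      cc <- sum(!in_mod & eligible & has)
      d <- sum(!in_mod & eligible & !has)
      tibble::tibble(target = mid, label = L, a = a, b = b, c = cc, d = d,
                     p_raw = phyper(a - 1, a + cc, b + d, a + b,
                                    lower.tail = FALSE))
    })
  })
  res$p_adj <- if (family == "global") {
    p.adjust(res$p_raw, method = "hochberg")
  } else {
    stats::ave(res$p_raw, res$target,
               FUN = function(p) p.adjust(p, method = "hochberg"))
  }
  class(res) <- c("csgcn_enrichment", class(res))
  attr(res, "family") <- family
  res
}

#' Region-specific edge sets, unique edges and region-count histogram
#'
#' Selects, for every region, the edges significantly enriched in it
#' (adjusted p strictly below `edge_alpha`), derives per-region node
#' lists, the per-edge region count, the unique edges (enriched in
#' exactly one region), and the histogram of edges by number of enriched
#' regions (bin 0 collects edges enriched nowhere).
#'
#' @param records A `csgcn_enrichment` from [edge_label_enrichment()].
#' @param edge_alpha Significance threshold on adjusted p (strict `<`).
#' @return An object of class `csgcn_region_sets`: list with
#'   `region_edges` (tibble `region`, `target`, `gene_a`, `gene_b`,
#'   `cluster_index`, `p_adj`, `unique`), `region_nodes`, `region_counts`
#'   (per edge), `histogram` (tibble `n_regions`, `n_edges`) and
#'   `edge_alpha`.
#' @export
select_region_sets <- function(records, edge_alpha = 1e-10) {
  sig <- dplyr::filter(records, .data$p_adj < edge_alpha)
  counts <- records |>
    dplyr::distinct(.data$target) |>
    dplyr::left_join(dplyr::count(sig, .data$target, name = "n_regions"),
                     by = "target") |>
    dplyr::mutate(n_regions = dplyr::coalesce(.data$n_regions, 0L))
  uniq <- counts$target[counts$n_regions == 1]
  region_edges <- sig |>
    dplyr::transmute(region = .data$label, .data$target, .data$gene_a,
                     .data$gene_b, .data$cluster_index, .data$p_adj,
                     unique = .data$target %in% uniq)
  region_nodes <- region_edges |>
    tidyr::pivot_longer(c("gene_a", "gene_b"), values_to = "gene") |>
    dplyr::distinct(.data$region, .data$gene)
  max_r <- attr(records, "n_regions") %||% max(counts$n_regions, 1)
  histogram <- tibble::tibble(n_regions = 0:max_r) |>
    dplyr::left_join(dplyr::count(counts, .data$n_regions, name = "n_edges"),
                     by = "n_regions") |>
    dplyr::mutate(n_edges = dplyr::coalesce(.data$n_edges, 0L))
  structure(list(region_edges = region_edges, region_nodes = region_nodes,
                 region_counts = counts, histogram = histogram,
                 edge_alpha = edge_alpha),
            class = "csgcn_region_sets")
}

#' @export
print.csgcn_region_sets <- function(x, ...) {
  cat("<csgcn_region_sets> alpha =", format(x$edge_alpha), "\n")
  print(x$region_edges |>
          dplyr::group_by(.data$region) |>
          dplyr::summarise(n_edges = dplyr::n(),
                           n_unique = sum(.data$unique), .groups = "drop"))
  invisible(x)
}

#' Merge region-specific sets into anatomical groups
#'
#' Combines region edge sets into larger anatomical mini-network gene
#' sets (e.g. several basal-ganglia structures into one group) by taking
#' the union of member regions' edges and nodes.  Groups whose edge set
#' is smaller than `min_edges` are flagged as too small to use.
#'
#' @param region_sets A `csgcn_region_sets` from [select_region_sets()].
#' @param merge_map Named character vector mapping every raw region label
#'   to a group name, or a path to a YAML file of `group: [regions]`
#'   lists.  The packaged example
#'   `system.file("extdata", "gtex_brain_region_merge.yaml", package =
#'   "csgcn")` carries the 13-region brain map onto 6 anatomical groups.
#' @param min_edges Minimum group edge count; smaller groups get
#'   `too_small = TRUE`.
#' @param unique_only Merge only each region's unique edges (default
#'   merges all region-enriched edges).
#' @return A tibble of class `csgcn_merged_sets`: `group`, `region`,
#'   `target`, `gene_a`, `gene_b`, with a `group_summary` attribute
#'   (`group`, `n_edges`, `n_nodes`, `too_small`).
#' @export
merge_anatomical <- function(region_sets, merge_map, min_edges = 3,
                             unique_only = FALSE) {
  stopifnot(inherits(region_sets, "csgcn_region_sets"))
  if (is.character(merge_map) && length(merge_map) == 1 &&
      file.exists(merge_map)) {
    merge_map <- read_merge_map(merge_map)
  }
  re <- region_sets$region_edges
  if (unique_only) re <- dplyr::filter(re, .data$unique)
  missing_lab <- setdiff(unique(re$region), names(merge_map))
  assert_that(length(missing_lab) == 0,
              paste("region(s) not covered by merge map:",
                    paste(missing_lab, collapse = ", ")))
  merged <- re |>
    dplyr::mutate(group = unname(merge_map[.data$region])) |>
    dplyr::distinct(.data$group, .data$region, .data$target, .data$gene_a,
                    .data$gene_b)
  summ <- merged |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n_edges = length(unique(.data$target)),
                     n_nodes = length(unique(c(.data$gene_a, .data$gene_b))),
                     .groups = "drop") |>
    dplyr::mutate(too_small = .data$n_edges < min_edges)
  structure(merged, class = c("csgcn_merged_sets", class(merged)),
            group_summary = summ)
}

#' @rdname merge_anatomical
#' @param path YAML file with one `group: [region, ...]` entry per group.
#' @export
read_merge_map <- function(path) {
  y <- yaml::read_yaml(path)
  out <- unlist(lapply(names(y), function(g) setNames(rep(g, length(y[[g]])),
                                                      y[[g]])))
  out
}

#' Gene sets of merged anatomical groups
#'
#' @param merged A `csgcn_merged_sets`.
#' @param drop_small Drop groups flagged `too_small`.
#' @return Named list of gene id vectors, one per group.
#' @export
merged_gene_sets <- function(merged, drop_small = TRUE) {
  summ <- attr(merged, "group_summary")
  keep <- if (drop_small) summ$group[!summ$too_small] else summ$group
  lapply(setNames(keep, keep), function(g) {
    rows <- merged[merged$group == g, ]
    sort(unique(c(rows$gene_a, rows$gene_b)))
  })
}

#' Mean/SD expression of a node set against all genes
#'
#' @param x A log2-scale [gem].
#' @param node_set Character vector of gene ids (subset of the GEM).
#' @return Tibble with `mu_set`, `sigma_set`, `mu_all`, `sigma_all`
#'   (mean/SD of log2 expression over the node subset and over all
#'   genes).
#' @export
node_expression_stats <- function(x, node_set) {
  stopifnot(inherits(x, "gem"))
  assert_that(length(node_set) > 0, "empty node set")
  assert_that(all(node_set %in% rownames(x$values)),
              "node_set contains genes absent from the GEM")
  sub <- x$values[node_set, , drop = FALSE]
  tibble::tibble(
    mu_set = mean(sub, na.rm = TRUE),
    sigma_set = sd(as.vector(sub), na.rm = TRUE),
    mu_all = mean(x$values, na.rm = TRUE),
    sigma_all = sd(as.vector(x$values), na.rm = TRUE))
}

#' Edge counts per region over a sweep of significance thresholds
#'
#' @param records A `csgcn_enrichment`.
#' @param alphas Thresholds to sweep (strict `<` at each).
#' @return Tibble `alpha`, `region`, `n_edges`, `n_nodes`.
#' @export
enrichment_threshold_sweep <- function(records,
                                       alphas = c(1e-3, 1e-5, 1e-10,
                                                  1e-15, 1e-20)) {
  purrr::map_dfr(alphas, function(al) {
    sig <- dplyr::filter(records, .data$p_adj < al)
    sig |>
      dplyr::group_by(region = .data$label) |>
      dplyr::summarise(
        n_edges = dplyr::n(),
        n_nodes = length(unique(c(.data$gene_a, .data$gene_b))),
        .groups = "drop") |>
      dplyr::mutate(alpha = al, .before = 1)
  })
}
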