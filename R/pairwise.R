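#' Cluster one gene pair's samples with a 2-D Gaussian mixture
#'
#' Samples with a missing or negative value in either vector are excluded
#' (mask character `'9'`).  The remaining points are fit with
#' full-covariance 2-D Gaussian mixtures for 1..`max_components`
#' components (EM with k-means++ initialization and restarts); the
#' component count is chosen by BIC.  Each cluster becomes one row; only
#' clusters with at least `min_cluster` members are eligible for a
#' Spearman correlation downstream (`rho` is left unset here).
#'
#' @param x,y Numeric vectors over the same samples (log2 scale).
#' @param min_cluster Minimum cluster size eligible for correlation.
#' @param max_components Largest mixture size tried.
#' @param seed Integer seed (deterministic fit).
#' @param keep_small Keep clusters below `min_cluster` (with `rho` unset)?
#' @param restarts,max_iter,tol EM controls.
#' @return A tibble with columns `cluster_index` (0-based), `n_clusters`,
#'   `cluster_size`, `sample_mask` (string over `'1'`/`'0'`/`'9'`) and
#'   `rho` (always `NA`; see [cluster_spearman()]).  Zero rows when fewer
#'   than `min_cluster` usable samples exist.
#' @export
pairwise_clusters <- function(x, y, min_cluster = 30, max_components = 5,
                              seed = 1L, keep_small = TRUE,
                              restarts = 2, max_iter = 75, tol = 1e-5) {
  stopifnot(length(x) == length(y))
  r <- .pair_clusters_cpp(as.numeric(x), as.numeric(y),
                          as.integer(min_cluster), as.integer(max_components),
                          as.integer(restarts), as.integer(max_iter), tol,
                          as.integer(seed), keep_small)
  tibble::tibble(cluster_index = as.integer(r$cluster_index),
                 n_clusters = as.integer(r$n_clusters),
                 cluster_size = as.integer(r$cluster_size),
                 sample_mask = as.character(r$sample_mask),
                 rho = NA_real_)
}

#' Spearman correlation within a sample cluster
#'
#' Rank correlation (average-rank ties) over the samples selected by
#' `mask`; returns `NA` when either rank vector has zero variance (the
#' cluster is dropped downstream).
#'
#' @param x,y Numeric vectors over the same samples.
#' @param mask Either a mask string over `'1'`/`'0'`/`'9'` or a logical
#'   vector selecting the in-cluster samples.
#' @return Spearman rho in `[-1, 1]`, or `NA`.
#' @export
cluster_spearman <- function(x, y, mask) {
  if (is.character(mask) && length(mask) == 1) mask <- mask_to_logical(mask)
  stopifnot(length(mask) == length(x), length(x) == length(y))
  xs <- x[mask]; ys <- y[mask]
  ok <- is.finite(xs) & is.finite(ys)
  if (sum(ok) < 2) return(NA_real_)
  .spearman_cpp(xs[ok], ys[ok])
}

#' Scan all gene pairs for condition-specific correlation clusters
#'
#' Applies [pairwise_clusters()] plus the per-cluster Spearman
#' correlation to every unordered gene pair of a preprocessed GEM.  The
#' whole scan is deterministic given `seed` (each pair draws from its own
#' derived stream), so chunked runs reproduce the full run: use `chunk =
#' c(i, n)` to visit only the i-th of n contiguous blocks of the pair
#' list and row-bind the results.
#'
#' @param x A preprocessed (log2, normalized) [gem].
#' @inheritParams pairwise_clusters
#' @param chunk Optional length-2 integer vector `c(index, n_chunks)`.
#' @param keep_small Keep sub-threshold clusters (with `rho` `NA`)?
#'   Default drops them, as only clusters of at least `min_cluster`
#'   samples carry a correlation.
#' @return A tibble of edge clusters: `gene_a`, `gene_b` (with
#'   `gene_a < gene_b`), `cluster_index`, `n_clusters`, `cluster_size`,
#'   `rho`, `sample_mask`.  The `sample_ids` attribute records the mask
#'   column order.
#' @export
similarity_scan <- function(x, min_cluster = 30, max_components = 5,
                            seed = 1L, keep_small = FALSE, chunk = NULL,
                            restarts = 2, max_iter = 75, tol = 1e-5) {
  stopifnot(inherits(x, "gem"))
  genes <- rownames(x$values)
  n <- length(genes)
  assert_that(n >= 2, "need at least two genes")
  idx <- t(combn(n, 2))
  # canonicalize each pair by gene name, and derive the per-pair RNG
  # stream from the names, so results do not depend on row order
  swap <- genes[idx[, 1]] > genes[idx[, 2]]
  idx[swap, ] <- idx[swap, c(2, 1)]
  ord <- order(genes[idx[, 1]], genes[idx[, 2]])
  idx <- idx[ord, , drop = FALSE]
  if (!is.null(chunk)) {
    stopifnot(length(chunk) == 2, chunk[1] >= 1, chunk[1] <= chunk[2])
    splits <- parallel_splits(nrow(idx), chunk[2])
    idx <- idx[splits == chunk[1], , drop = FALSE]
  }
  name_key <- vapply(genes, function(g) sum(utf8ToInt(g) * seq_len(nchar(g))),
                     numeric(1))
  pair_seed <- vapply(seq_len(nrow(idx)), function(p) {
    derive_seed(seed, name_key[idx[p, 1]], name_key[idx[p, 2]])
  }, integer(1))
  r <- .similarity_scan_cpp(x$values, idx[, 1], idx[, 2], pair_seed,
                            as.integer(min_cluster), as.integer(max_components),
                            as.integer(restarts), as.integer(max_iter), tol,
                            keep_small)
  out <- tibble::tibble(gene_a = genes[r$i], gene_b = genes[r$j],
                        cluster_index = as.integer(r$cluster_index),
                        n_clusters = as.integer(r$n_clusters),
                        cluster_size = as.integer(r$cluster_size),
                        rho = as.numeric(r$rho),
                        sample_mask = as.character(r$sample_mask)) |>
    dplyr::arrange(.data$gene_a, .data$gene_b, .data$cluster_index)
  attr(out, "sample_ids") <- colnames(x$values)
  out
}

parallel_splits <- function(n, k) {
  sort(rep_len(seq_len(k), n))
}

#' Read / write an edge-cluster list as TSV
#'
#' The edge-cluster TSV (`gene_a`, `gene_b`, `rho`, `cluster_index`,
#' `n_clusters`, `cluster_size`, `sample_mask`) is the exchange format
#' between the network stage and all downstream modules.
#'
#' @param edges An edge-cluster tibble from [similarity_scan()] or
#'   [extract_network()].
#' @param path File path.
#' @export
write_edges <- function(edges, path) {
  readr::write_tsv(
    dplyr::select(tibble::as_tibble(edges), "gene_a", "gene_b", "rho",
                  "cluster_index", "n_clusters", "cluster_size",
                  "sample_mask"),
    path)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_a = "c", gene_b = "c", rho = "d", cluster_index = "i",
    n_clusters = "i", cluster_size = "i", sample_mask = "c"))
}
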