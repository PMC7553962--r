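#' Partition density of an edge partition
#'
#' For a community `c` with `m_c` edges and `n_c` nodes the link density
#' is `D_c = (m_c - (n_c - 1)) / (n_c (n_c - 1) / 2 - (n_c - 1))` (zero
#' for `n_c = 2`); the partition density is the edge-weighted mean
#' `D = (2 / M) * sum_c m_c (m_c - n_c + 1) / ((n_c - 1)(n_c - 2))`.
#'
#' @param edge_modules Tibble with columns `gene_a`, `gene_b`, `module`.
#' @return Numeric scalar.
#' @export
partition_density <- function(edge_modules) {
  M <- nrow(edge_modules)
  if (M == 0) return(0)
  per <- edge_modules |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      m = dplyr::n(),
      n = length(unique(c(.data$gene_a, .data$gene_b))),
      .groups = "drop") |>
    dplyr::mutate(dc = ifelse(.data$n <= 2, 0,
                              (.data$m - .data$n + 1) * 2 /
                                ((.data$n - 1) * (.data$n - 2))))
  sum(per$m * per$dc) / M
}

# Jaccard similarity of two edges sharing a node, over the inclusive
# neighborhoods of their non-shared endpoints
edge_similarity_matrix <- function(pairs) {
  nodes <- sort(unique(c(pairs$gene_a, pairs$gene_b)))
  nbr <- lapply(setNames(nodes, nodes), function(g) {
    c(g, pairs$gene_b[pairs$gene_a == g], pairs$gene_a[pairs$gene_b == g])
  })
  m <- nrow(pairs)
  sim <- matrix(0, m, m)
  # index edges by node for adjacency lookup
  by_node <- list()
  for (e in seq_len(m)) {
    for (g in c(pairs$gene_a[e], pairs$gene_b[e]))
      by_node[[g]] <- c(by_node[[g]], e)
  }
  for (g in names(by_node)) {
    es <- by_node[[g]]
    if (length(es) < 2) next
    for (a in seq_len(length(es) - 1)) {
      for (b in (a + 1):length(es)) {
        e1 <- es[a]; e2 <- es[b]
        i <- setdiff(c(pairs$gene_a[e1], pairs$gene_b[e1]), g)
        j <- setdiff(c(pairs$gene_a[e2], pairs$gene_b[e2]), g)
        if (length(i) == 0 || length(j) == 0) next
        ni <- nbr[[i]]; nj <- nbr[[j]]
        s <- length(intersect(ni, nj)) / length(union(ni, nj))
        sim[e1, e2] <- max(sim[e1, e2], s)
        sim[e2, e1] <- sim[e1, e2]
      }
    }
  }
  sim
}

#' Link-community module detection
#'
#' Clusters the network's edges (unique gene pairs) by the standard
#' link-community procedure: edge-edge similarity is the Jaccard index of
#' the inclusive neighbor sets of the two non-shared endpoints (edges
#' sharing no node have similarity zero), edges are merged by
#' single-linkage hierarchical clustering, and the dendrogram is cut at
#' the height maximizing the partition density.  Modules with fewer than
#' `min_edges` edges are then discarded.
#'
#' @param network A `csgcn_network` from [extract_network()], or an edge
#'   tibble with `gene_a`/`gene_b` columns.
#' @param min_edges Minimum module size in edges.
#' @return An object of class `csgcn_linkcomm`: list with `modules`
#'   (tibble `module`, `gene_a`, `gene_b`), `cut_height`,
#'   `partition_density`, `min_edges` and `n_modules`.  Edge clusters of
#'   a retained gene pair all belong to the pair's module.
#' @export
link_communities <- function(network, min_edges = 3) {
  edges <- if (inherits(network, "csgcn_network")) network$edges else
    tibble::as_tibble(network)
  assert_that(nrow(edges) >= 1, "network has no edges")
  pairs <- dplyr::distinct(edges, .data$gene_a, .data$gene_b)
  m <- nrow(pairs)
  if (m == 1) {
    modules <- pairs[0, ] |> dplyr::mutate(module = integer(0))
    return(structure(list(modules = modules, cut_height = 0,
                          partition_density = 0, min_edges = min_edges,
                          n_modules = 0L),
                     class = "csgcn_linkcomm"))
  }
  sim <- edge_similarity_matrix(pairs)
  d <- stats::as.dist(1 - sim)
  hc <- stats::hclust(d, method = "single")
  heights <- sort(unique(c(0, hc$height)))
  best <- list(D = -Inf, h = 0, cl = NULL)
  for (h in heights) {
    cl <- stats::cutree(hc, h = h + 1e-10)
    D <- partition_density(dplyr::mutate(pairs, module = cl))
    if (D > best$D + 1e-12) best <- list(D = D, h = h, cl = cl)
  }
  modules <- pairs |>
    dplyr::mutate(module = best$cl) |>
    dplyr::group_by(.data$module) |>
    dplyr::filter(dplyr::n() >= min_edges) |>
    dplyr::ungroup()
  # relabel module ids consecutively, stable in first-appearance order
  if (nrow(modules) > 0) {
    modules$module <- match(modules$module, unique(modules$module))
    modules$module_id <- sprintf("M%04d", modules$module)
  } else {
    modules$module_id <- character(0)
  }
  structure(list(modules = modules, cut_height = best$h,
                 partition_density = best$D, min_edges = min_edges,
                 n_modules = length(unique(modules$module_id))),
            class = "csgcn_linkcomm")
}

#' @export
print.csgcn_linkcomm <- function(x, ...) {
  cat("<csgcn_linkcomm> ", x$n_modules, " modules (>= ", x$min_edges,
      " edges) at cut height ", format(x$cut_height),
      ", partition density ", format(x$partition_density), "\n", sep = "")
  invisible(x)
}

#' @rdname link_communities
#' @param x A `csgcn_linkcomm`.
#' @param path Output TSV path (`module_id`, `gene_a`, `gene_b`).
#' @export
write_modules <- function(x, path) {
  readr::write_tsv(dplyr::select(x$modules, "module_id", "gene_a", "gene_b"),
                   path)
  invisible(path)
}
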