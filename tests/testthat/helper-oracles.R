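# independent oracles used by several test files; deliberately written
# without reusing package internals

# one-sided Fisher p as an explicit hypergeometric tail sum
fisher_tail_oracle <- function(a, b, c, d) {
  K <- a + c          # samples carrying the label
  N <- a + b + c + d  # eligible samples
  n <- a + b          # cluster size
  ks <- a:min(K, n)
  sum(vapply(ks, function(k) dhyper(k, K, N - K, n), numeric(1)))
}

# partition density recomputed from scratch for an edge partition
partition_density_oracle <- function(pairs, modules) {
  M <- nrow(pairs)
  total <- 0
  for (cl in unique(modules)) {
    sub <- pairs[modules == cl, , drop = FALSE]
    m <- nrow(sub)
    n <- length(unique(c(sub$gene_a, sub$gene_b)))
    if (n > 2)
      total <- total + m * 2 * (m - n + 1) / ((n - 1) * (n - 2))
  }
  total / M
}

# best partition density over every cut of the package's edge dendrogram,
# found by exhaustive enumeration (for graphs small enough to enumerate)
best_cut_density_oracle <- function(pairs) {
  sim <- csgcn:::edge_similarity_matrix(pairs)
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "single")
  best <- -Inf
  for (h in sort(unique(c(0, hc$height)))) {
    cl <- stats::cutree(hc, h = h + 1e-10)
    best <- max(best, partition_density_oracle(pairs, cl))
  }
  best
}

# brute-force mutation count statistics by explicit nested loops
count_stats_oracle <- function(mutations, gene_set, tumor_type) {
  genes_seen <- character(0)
  tumors_seen <- character(0)
  total <- 0L
  for (i in seq_len(nrow(mutations))) {
    if (mutations$tumor_type[i] == tumor_type &&
        mutations$gene[i] %in% gene_set) {
      genes_seen <- union(genes_seen, mutations$gene[i])
      tumors_seen <- union(tumors_seen, mutations$tumor_id[i])
      total <- total + 1L
    }
  }
  c(mutated_genes = length(genes_seen),
    mutated_tumors = length(tumors_seen),
    total_mutations = total)
}

# build a single-edge tibble with a given mask for enrichment tests
edge_fixture <- function(mask, gene_a = "GA", gene_b = "GB") {
  tibble::tibble(gene_a = gene_a, gene_b = gene_b, cluster_index = 0L,
                 n_clusters = 1L, cluster_size = sum(strsplit(mask, "")[[1]] == "1"),
                 rho = 0.9, sample_mask = mask)
}
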