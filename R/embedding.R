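# Exact (dense) t-SNE, adequate for cohort-scale sample counts.
# Perplexity calibration by per-point binary search on the Gaussian
# kernel bandwidth; KL gradient descent with momentum and early
# exaggeration, random normal initialization.
tsne_exact <- function(X, perplexity = 30, max_iter = 500, seed = 1L,
                       eta = 200, momentum = c(0.5, 0.8),
                       exaggeration = 4, exaggerate_iter = 100) {
  n <- nrow(X)
  assert_that(n - 1 >= 3 * perplexity,
              "perplexity too large for the number of samples")
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    beta <- 1; lo <- -Inf; hi <- Inf
    di <- D2[i, -i]
    for (it in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { p <- rep(1 / length(di), length(di)); break }
      H <- log(sp) + beta * sum(di * p) / sp
      p <- p / sp
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  with_seed(derive_seed(seed, 303L), {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2)
    Pex <- P * exaggeration
    for (iter in seq_len(max_iter)) {
      Pi <- if (iter <= exaggerate_iter) Pex else P
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(W)) %*% Y - W %*% Y)
      mom <- if (iter <= 250) momentum[1] else momentum[2]
      dY <- mom * dY - eta * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    Y
  })
}

#' Two-dimensional embedding of samples from a gene set
#'
#' Restricts the GEM to `gene_set`, reduces the samples with PCA to at
#' most `pca_dims` components, and embeds them in 2-D with t-SNE
#' (random initialization, deterministic given `seed`).  Used to
#' visualize how well a candidate gene set separates the sample regions.
#'
#' @param x A preprocessed [gem].
#' @param gene_set Character vector of gene ids (subset of the GEM).
#' @param perplexity t-SNE perplexity; requires `n_samples > 3 *
#'   perplexity`.
#' @param pca_dims Number of leading principal components kept before
#'   t-SNE (capped at the matrix rank).
#' @param seed Integer seed.
#' @param max_iter t-SNE iterations.
#' @return A tibble of class `csgcn_embedding`: `sample_id`, `x`, `y`
#'   and (when the GEM has labels) `label`; parameters in attributes.
#' @export
project_samples <- function(x, gene_set, perplexity = 30, pca_dims = 50,
                            seed = 1L, max_iter = 500) {
  stopifnot(inherits(x, "gem"))
  assert_that(length(gene_set) > 0, "empty gene set")
  assert_that(all(gene_set %in% rownames(x$values)),
              "gene_set contains genes absent from the GEM")
  m <- t(x$values[gene_set, , drop = FALSE])
  m[is.na(m)] <- 0
  keep <- apply(m, 2, function(v) sd(v) > 0)
  if (any(keep)) m <- m[, keep, drop = FALSE]
  k <- min(pca_dims, ncol(m), nrow(m) - 1)
  pc <- prcomp(m, center = TRUE, scale. = FALSE, rank. = k)
  Y <- tsne_exact(pc$x, perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  out <- tibble::tibble(sample_id = colnames(x$values),
                        x = Y[, 1], y = Y[, 2])
  if (!is.null(x$labels)) out$label <- unname(x$labels[out$sample_id])
  class(out) <- c("csgcn_embedding", class(out))
  attr(out, "params") <- list(perplexity = perplexity, pca_dims = pca_dims,
                              seed = seed, n_genes = length(gene_set))
  out
}

#' Mean silhouette width of region labels in an embedding
#'
#' Quantifies label separation in the 2-D embedding (the package's
#' stand-in for visual "the regions separate" statements).
#'
#' @param embedding A `csgcn_embedding` from [project_samples()].
#' @param labels Optional label vector (defaults to the embedding's
#'   `label` column), in `sample_id` order.
#' @return Mean silhouette width (numeric scalar).
#' @export
embedding_silhouette <- function(embedding, labels = NULL) {
  labels <- labels %||% embedding$label
  assert_that(!is.null(labels), "no labels available")
  cl <- as.integer(factor(labels))
  assert_that(length(unique(cl)) > 1, "need at least two label classes")
  sil <- cluster::silhouette(cl, stats::dist(cbind(embedding$x, embedding$y)))
  mean(sil[, "sil_width"])
}

#' @rdname project_samples
#' @param object A `csgcn_embedding`.
#' @param ... Unused.
#' @export
autoplot.csgcn_embedding <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(object$label))
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$label),
                                 size = 1)
  else p <- p + ggplot2::geom_point(size = 1)
  p + ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "region") +
    ggplot2::theme_minimal()
}
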