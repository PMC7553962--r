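test_that("well-separated clouds are recovered with the right component count", {
  set.seed(5)
  x <- c(rnorm(100, 4), rnorm(60, 10))
  y <- c(rnorm(100, 4), rnorm(60, 10))
  truth <- rep(c(0, 1), c(100, 60))
  pc <- pairwise_clusters(x, y, seed = 1)
  expect_equal(pc$n_clusters[1], 2L)
  # recovered assignment agrees with truth for >= 95% of samples
  best <- max(vapply(seq_len(nrow(pc)), function(k) {
    m <- mask_to_logical(pc$sample_mask[k])
    max(mean(m == (truth == 1)), mean(m == (truth == 0)))
  }, numeric(1)))
  expect_gte(best, 0.95)

  # mclust agrees on the component count for this configuration
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  fit <- mclust::Mclust(cbind(x, y), G = 1:5, verbose = FALSE)
  expect_equal(fit$G, 2L)
})

test_that("a single isotropic cloud selects one component in most seeds", {
  ok <- 0L
  for (s in 1:10) {
    set.seed(s)
    x <- rnorm(120, 5); y <- rnorm(120, 5)
    pc <- pairwise_clusters(x, y, seed = s)
    ok <- ok + (pc$n_clusters[1] == 1L)
  }
  expect_gte(ok, 9L)
})

test_that("too few usable samples yield no eligible cluster", {
  set.seed(2)
  x <- rnorm(29); y <- rnorm(29)
  expect_equal(nrow(pairwise_clusters(x, y)), 0L)
  # missing and negative values are excluded before clustering
  x2 <- c(rnorm(40, 5), rep(-1, 20), rep(NA, 5))
  y2 <- rnorm(65, 5)
  pc <- pairwise_clusters(x2, y2, seed = 1)
  ch <- mask_chars(pc$sample_mask[1])
  expect_true(all(ch[41:65] == "9"))
  expect_equal(sum(ch != "9"), 40L)
})

test_that("cluster Spearman matches a rank-then-Pearson oracle", {
  set.seed(8)
  x <- rnorm(50, 5)
  expect_equal(cluster_spearman(x, exp(x), rep(TRUE, 50)), 1)
  expect_equal(cluster_spearman(x, -x, rep(TRUE, 50)), -1)

  xt <- sample(1:6, 30, replace = TRUE)   # heavy ties
  yt <- sample(1:6, 30, replace = TRUE)
  oracle <- cor(rank(xt), rank(yt))       # average-rank then Pearson
  expect_equal(cluster_spearman(xt, yt, rep(TRUE, 30)), oracle,
               tolerance = 1e-12)

  expect_true(is.na(cluster_spearman(rep(1, 30), rnorm(30), rep(TRUE, 30))))

  # mask strings select the in-cluster samples
  mask <- paste(rep(c("1", "0"), c(30, 20)), collapse = "")
  expect_equal(cluster_spearman(x, 2 * x + 1, mask), 1)
})

test_that("the similarity scan visits every pair exactly once and is canonical", {
  set.seed(4)
  m <- matrix(2^rnorm(10 * 40, 5), 10, 40,
              dimnames = list(paste0("g", sprintf("%02d", 1:10)),
                              paste0("s", 1:40)))
  g <- gem(m) |> log2_transform()
  ec <- similarity_scan(g, seed = 2, keep_small = TRUE)
  expect_equal(nrow(dplyr::distinct(ec, gene_a, gene_b)), choose(10, 2))
  expect_true(all(ec$gene_a < ec$gene_b))

  # permuting gene order gives the same canonical edge set
  g2 <- g
  perm <- sample(10)
  g2$values <- g$values[perm, ]
  ec2 <- similarity_scan(g2, seed = 2, keep_small = TRUE)
  key <- function(e) paste(e$gene_a, e$gene_b, e$cluster_index)
  expect_setequal(key(ec2), key(ec))
  expect_equal(ec2$rho[order(key(ec2))], ec$rho[order(key(ec))],
               tolerance = 1e-12)

  # chunked execution reproduces the full scan
  ch <- dplyr::bind_rows(
    similarity_scan(g, seed = 2, chunk = c(1, 3), keep_small = TRUE),
    similarity_scan(g, seed = 2, chunk = c(2, 3), keep_small = TRUE),
    similarity_scan(g, seed = 2, chunk = c(3, 3), keep_small = TRUE))
  ch <- dplyr::arrange(ch, gene_a, gene_b, cluster_index)
  expect_equal(ch$rho, ec$rho)
  expect_identical(ch$sample_mask, ec$sample_mask)

  # mask conservation
  tab <- table(unlist(strsplit(ec$sample_mask, "")))
  expect_equal(sum(tab), nrow(ec) * 40L)
  expect_true(all(names(tab) %in% c("0", "1", "9")))
})
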