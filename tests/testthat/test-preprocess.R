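toy_gem <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  gem(m)
}

test_that("log2 transform maps values as specified", {
  g <- toy_gem(matrix(c(8, 1, 0.5, 0, NA, 4), nrow = 3))
  out <- log2_transform(g)
  expect_equal(out$values[1, 1], 3)
  expect_equal(out$values[2, 1], 0)
  expect_equal(out$values[3, 1], -1)      # negatives retained
  expect_true(is.na(out$values[1, 2]))    # zero -> missing
  expect_true(is.na(out$values[2, 2]))    # missing stays missing
  expect_equal(out$values[3, 2], 2)
  expect_equal(out$scale, "log2")

  expect_error(log2_transform(toy_gem(matrix(c(-1, 2, 3, 4), 2))),
               "negative")
  # strict monotonicity on positives
  v <- sort(runif(20, 0.01, 100))
  lg <- log2_transform(toy_gem(matrix(v, nrow = 20)))$values[, 1]
  expect_true(all(diff(lg) > 0))
})

test_that("KS screen flags only genuinely shifted samples, strictly above threshold", {
  set.seed(13)
  flagged_any <- 0L
  for (s in 1:3) {
    m <- matrix(rnorm(500 * 12), 500, 12,
                dimnames = list(paste0("g", 1:500), paste0("s", 1:12)))
    rep <- ks_outlier_flags(gem(m, scale = "log2"))
    flagged_any <- flagged_any + any(rep$flagged)
  }
  expect_equal(flagged_any, 0L)

  m <- matrix(rnorm(500 * 16), 500, 16,
              dimnames = list(paste0("g", 1:500), paste0("s", 1:16)))
  m[, 16] <- m[, 16] + 100   # disjoint support
  rep <- ks_outlier_flags(gem(m, scale = "log2"))
  expect_equal(rep$dval[16], 1)
  expect_true(rep$flagged[16])
  expect_identical(attr(rep, "removed_samples"), "s16")

  # the rule is strictly greater: a sample exactly at threshold stays
  rep2 <- ks_outlier_flags(gem(m[, 1:15], scale = "log2"),
                           dval_threshold = max(
                             ks_outlier_flags(gem(m[, 1:15],
                                                  scale = "log2"))$dval))
  expect_false(any(rep2$flagged))

  few <- gem(matrix(c(1, NA, NA, 2, 3, 4), 3,
                    dimnames = list(paste0("g", 1:3), c("a", "b"))),
             scale = "log2")
  expect_error(ks_outlier_flags(few), "non-missing")
})

test_that("quantile normalization handles ties, missing values and is idempotent", {
  # ties receive the mean of their target quantiles
  m <- matrix(c(1, 1, 3, 2, 4, 6), nrow = 3,
              dimnames = list(paste0("g", 1:3), c("s1", "s2")))
  out <- quantile_normalize(gem(m))$values
  ref <- c(1.5, 2.5, 4.5)
  expect_equal(unname(out[, 1]), c(2, 2, 4.5))
  expect_equal(unname(out[, 2]), ref)

  # identical columns unchanged
  m2 <- matrix(c(5, 1, 3, 5, 1, 3), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(quantile_normalize(gem(m2))$values, m2)

  # idempotent on tie-free data
  set.seed(3)
  m3 <- matrix(rnorm(50 * 6), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  q1 <- quantile_normalize(gem(m3, scale = "log2"))
  q2 <- quantile_normalize(q1)
  expect_equal(q2$values, q1$values, tolerance = 1e-12)

  # agrees with the established implementation on complete tie-free data
  skip_if_not_installed("limma")
  expect_equal(unname(q1$values),
               unname(limma::normalizeQuantiles(m3, ties = TRUE)),
               tolerance = 1e-10)

  # missing entries stay missing, ranks over observed values only
  m4 <- m3
  m4[cbind(sample(50, 10), sample(6, 10, replace = TRUE))] <- NA
  q4 <- quantile_normalize(gem(m4, scale = "log2"))
  expect_identical(is.na(q4$values), is.na(m4))
  for (j in 1:6) {
    obs <- !is.na(m4[, j])
    expect_equal(order(q4$values[obs, j]), order(m4[obs, j]))
  }

  m5 <- m3
  m5[, 2] <- NA
  expect_error(quantile_normalize(gem(m5, scale = "log2")),
               "fully-missing")
})

test_that("the preprocessing pipeline applies log2, KS screen and normalization in order", {
  pp <- preprocess_gem(small_sim()$gem)
  expect_equal(attr(pp$report, "steps_applied"),
               c("log2_transform", "ks_outlier_flags", "remove_outliers",
                 "quantile_normalize"))
  expect_equal(pp$gem$scale, "log2")
  # samples with equally many observed values share the same sorted
  # vector after normalization (missingness patterns differ by column)
  counts <- colSums(!is.na(pp$gem$values))
  shared <- which(counts == as.integer(names(which.max(table(counts)))))
  s1 <- sort(pp$gem$values[, shared[1]])
  s2 <- sort(pp$gem$values[, shared[2]])
  expect_equal(s2, s1, tolerance = 1e-12, ignore_attr = TRUE)
  dir <- withr::local_tempdir()
  p <- write_preprocess_report(pp$report, file.path(dir, "ks.tsv"))
  expect_true(file.exists(p))
})
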