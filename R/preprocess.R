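#' Log2-transform a linear-scale GEM
#'
#' Positive values become `log2(x)`, zeros become missing (the log is
#' undefined and downstream similarity ignores negative values anyway),
#' and missing values stay missing.  Negative input values are an error:
#' the input is expected on a TPM-like linear scale.
#'
#' @param x A [gem] on the linear scale.
#' @return A [gem] on the log2 scale.
#' @export
log2_transform <- function(x) {
  stopifnot(inherits(x, "gem"))
  v <- x$values
  if (any(v < 0, na.rm = TRUE))
    stop("negative values in linear-scale GEM", call. = FALSE)
  v[!is.na(v) & v == 0] <- NA_real_
  v[!is.na(v)] <- log2(v[!is.na(v)])
  out <- x
  out$values <- v
  out$scale <- "log2"
  out
}

#' Kolmogorov-Smirnov outlier screen for samples
#'
#' For each sample, computes the KS D statistic between that sample's
#' distribution of non-missing log2 values and the pooled distribution of
#' all other samples' values, and flags samples with D strictly greater
#' than `dval_threshold`.
#'
#' @param x A log2-scale [gem].
#' @param dval_threshold Flagging threshold on D (strictly greater than).
#' @return A tibble (`sample_id`, `dval`, `flagged`) of class
#'   `csgcn_ks_report`, with the threshold and flagged samples as
#'   attributes.
#' @export
ks_outlier_flags <- function(x, dval_threshold = 0.15) {
  stopifnot(inherits(x, "gem"))
  v <- x$values
  n_ok <- colSums(!is.na(v))
  if (any(n_ok < 2))
    stop("sample(s) with fewer than 2 non-missing values: ",
         paste(colnames(v)[n_ok < 2], collapse = ", "), call. = FALSE)
  all_vals <- as.vector(v)
  col_of <- rep(seq_len(ncol(v)), each = nrow(v))
  keep <- !is.na(all_vals)
  all_vals <- all_vals[keep]
  col_of <- col_of[keep]
  dval <- vapply(seq_len(ncol(v)), function(j) {
    xs <- all_vals[col_of == j]
    pooled <- all_vals[col_of != j]
    unname(suppressWarnings(ks.test(xs, pooled)$statistic))
  }, numeric(1))
  out <- tibble::tibble(sample_id = colnames(v), dval = dval,
                        flagged = dval > dval_threshold)
  class(out) <- c("csgcn_ks_report", class(out))
  attr(out, "dval_threshold") <- dval_threshold
  attr(out, "removed_samples") <- out$sample_id[out$flagged]
  out
}

#' Quantile-normalize a GEM across samples
#'
#' After normalization every sample's sorted value vector equals the
#' across-sample mean of sorted vectors; within-sample ranks are
#' preserved and tied values receive the mean of their tied target
#' quantiles.  Missing entries keep their positions: ranks are computed
#' over the non-missing values of each sample and the reference
#' distribution is interpolated for samples with fewer observed values.
#'
#' @param x A [gem] (any scale); no sample may be fully missing.
#' @return The normalized [gem].
#' @export
quantile_normalize <- function(x) {
  stopifnot(inherits(x, "gem"))
  v <- x$values
  n <- nrow(v)
  counts <- colSums(!is.na(v))
  if (any(counts == 0))
    stop("fully-missing sample(s): ",
         paste(colnames(v)[counts == 0], collapse = ", "), call. = FALSE)
  kmax <- max(counts)
  # reference distribution: mean of per-sample sorted vectors, each
  # interpolated onto a common grid of kmax quantiles
  grid <- if (kmax == 1) 0.5 else seq(0, 1, length.out = kmax)
  ref <- rowMeans(vapply(seq_len(ncol(v)), function(j) {
    s <- sort(v[, j][!is.na(v[, j])])
    if (length(s) == 1) rep(s, kmax)
    else if (length(s) == kmax) s
    else approx(seq(0, 1, length.out = length(s)), s, xout = grid)$y
  }, numeric(kmax)))
  ref_at <- function(p) {
    if (kmax == 1) rep(ref[1], length(p))
    else approx(grid, ref, xout = p)$y
  }
  out <- v
  for (j in seq_len(ncol(v))) {
    obs <- which(!is.na(v[, j]))
    k <- length(obs)
    vals <- v[obs, j]
    ord <- order(vals)
    p <- if (k == 1) 0.5 else (seq_len(k) - 1) / (k - 1)
    target <- ref_at(p)          # target quantile for each sorted position
    assigned <- numeric(k)
    assigned[ord] <- target
    # ties: mean of the tied positions' target quantiles
    assigned <- ave(assigned, match(vals, vals), FUN = mean)
    out[obs, j] <- assigned
  }
  res <- x
  res$values <- out
  res
}

#' Full GEM preprocessing pipeline
#'
#' Applies, in order: log2 transform, KS outlier screen (removing flagged
#' samples when `remove_outliers`), and quantile normalization.
#'
#' @param x A linear-scale [gem].
#' @param ks_threshold KS D flagging threshold (strict `>`).
#' @param remove_outliers Drop flagged samples before normalization.
#' @return A list with `gem` (preprocessed) and `report` (a
#'   `csgcn_ks_report` with a `steps_applied` attribute).
#' @export
preprocess_gem <- function(x, ks_threshold = 0.15, remove_outliers = TRUE) {
  g <- log2_transform(x)
  report <- ks_outlier_flags(g, dval_threshold = ks_threshold)
  removed <- attr(report, "removed_samples")
  if (remove_outliers && length(removed) > 0) {
    keep <- setdiff(colnames(g$values), removed)
    g$values <- g$values[, keep, drop = FALSE]
    if (!is.null(g$labels)) g$labels <- g$labels[keep]
  }
  g <- quantile_normalize(g)
  attr(report, "steps_applied") <-
    c("log2_transform", "ks_outlier_flags",
      if (remove_outliers) "remove_outliers", "quantile_normalize")
  list(gem = g, report = report)
}

#' @rdname ks_outlier_flags
#' @param report A `csgcn_ks_report`.
#' @param path Output TSV path.
#' @export
write_preprocess_report <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path)
  invisible(path)
}
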