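#' Chi-square statistic of the nearest-neighbor spacing distribution
#'
#' Compares a vector of (unfolded, mean-1) eigenvalue spacings against
#' the Poisson (exponential) spacing law with a binned chi-square
#' statistic: `n_bins` equal-width bins on `[0, 3]`, expected counts from
#' the exponential distribution.  Under Poisson spacings the statistic is
#' approximately chi-square with `n_bins` degrees of freedom; the
#' conventional critical value 99.607 is the 99.9% quantile at 60 bins.
#'
#' @param spacings Positive spacings, ideally with mean 1 (they are
#'   rescaled to mean 1 internally).
#' @param n_bins Number of histogram bins over `[0, 3]`.
#' @return The chi-square statistic (numeric scalar).
#' @export
nnsd_chisq <- function(spacings, n_bins = 60) {
  s <- spacings[is.finite(spacings) & spacings >= 0]
  if (length(s) < 2) return(NA_real_)
  s <- s / mean(s)
  n_total <- length(s)
  breaks <- seq(0, 3, length.out = n_bins + 1)
  s <- s[s <= 3]  # histogram support [0, 3]; the exponential tail beyond
                  # is excluded from both observed and expected counts
  obs <- tabulate(pmin(findInterval(s, breaks, rightmost.closed = TRUE),
                       n_bins), nbins = n_bins)
  expd <- n_total * (exp(-breaks[-length(breaks)]) - exp(-breaks[-1]))
  sum((obs - expd)^2 / expd)
}

# unfold eigenvalues: map through a smoothed empirical staircase
# (monotone spline through every `pace`-th eigenvalue) so that spacings
# have unit mean; near-duplicate eigenvalues are collapsed first
unfold_spacings <- function(ev, pace = 10, dedup_tol = 1e-6) {
  ev <- sort(ev)
  keep <- c(TRUE, diff(ev) > dedup_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < 10) return(numeric(0))
  idx <- unique(c(seq(1, n, by = pace), n))
  if (length(idx) < 4) return(numeric(0))
  fit <- stats::splinefun(ev[idx], idx, method = "hyman")
  diff(fit(ev))
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate thresholds downward from `scan_start` in steps of
#' `scan_step`.  At each threshold the thresholded correlation matrix
#' (maximum `|rho|` per gene pair over its clusters, zero-degree genes
#' dropped) is built, its eigenvalues unfolded, and the chi-square
#' statistic of the nearest-neighbor spacing distribution against the
#' Poisson law computed.  Sparse random-like networks show Poisson
#' spacings (low statistic); as real correlation structure enters, the
#' spacings shift toward the Gaussian-orthogonal-ensemble law and the
#' statistic rises.  The selected threshold `tau` is the last scanned
#' value before the statistic exceeds `chi2_crit`.
#'
#' @param edge_clusters Edge-cluster tibble from [similarity_scan()].
#' @param scan_start,scan_step,scan_end Scan grid (strictly decreasing
#'   thresholds from `scan_start` down to `scan_end`).
#' @param chi2_crit Transition critical value (99.9% chi-square quantile
#'   at 60 bins by default).
#' @param smooth_window Width (in scored thresholds with distinct edge
#'   sets) of the running median applied to the chi-square series before
#'   locating the transition; the raw statistic is noisy at small matrix
#'   sizes and isolated exceedances must not stop the scan.
#' @param min_eigenvalues Minimum distinct eigenvalues needed to score a
#'   threshold; smaller matrices are recorded with `NA` statistic.
#' @param tau_override If supplied, no scan is run and this value is
#'   recorded verbatim as `tau` (as a published threshold would be).
#' @return An object of class `csgcn_threshold`: list with `tau` (numeric
#'   or `NA` if no transition was found), `no_threshold` flag, and
#'   `scan_trace` tibble (`threshold`, `n_edges`, `n_nodes`, `nnsd_chi2`).
#' @export
rmt_threshold <- function(edge_clusters, scan_start = 0.99,
                          scan_step = 0.001, scan_end = 0.5,
                          chi2_crit = 99.607, smooth_window = 5,
                          min_eigenvalues = 30, tau_override = NULL) {
  if (!is.null(tau_override)) {
    return(structure(list(tau = tau_override, no_threshold = FALSE,
                          overridden = TRUE,
                          scan_trace = tibble::tibble(
                            threshold = tau_override, n_edges = NA_integer_,
                            n_nodes = NA_integer_, nnsd_chi2 = NA_real_)),
                     class = "csgcn_threshold"))
  }
  ec <- dplyr::filter(edge_clusters, is.finite(.data$rho))
  assert_that(nrow(ec) > 0, "no finite-correlation edge clusters")
  pair <- ec |>
    dplyr::group_by(.data$gene_a, .data$gene_b) |>
    dplyr::summarise(arho = max(abs(.data$rho)), .groups = "drop")
  assert_that(any(pair$arho > scan_end),
              "no edge cluster inside the scan region")
  genes <- sort(unique(c(pair$gene_a, pair$gene_b)))
  ia <- match(pair$gene_a, genes)
  ib <- match(pair$gene_b, genes)
  thresholds <- seq(scan_start, scan_end, by = -scan_step)
  trace <- vector("list", length(thresholds))
  prev_edges <- -1L
  prev_chi2 <- NA_real_
  for (t in seq_along(thresholds)) {
    th <- thresholds[t]
    sel <- pair$arho > th
    n_edges <- sum(sel)
    chi2 <- NA_real_
    n_nodes <- 0L
    if (n_edges > 0 && n_edges == prev_edges) {
      chi2 <- prev_chi2  # same edge set, same spectrum
    } else if (n_edges > 0) {
      keep_genes <- sort(unique(c(ia[sel], ib[sel])))
      n_nodes <- length(keep_genes)
      m <- diag(1, n_nodes)
      ra <- match(ia[sel], keep_genes)
      rb <- match(ib[sel], keep_genes)
      vals <- pair$arho[sel]
      m[cbind(ra, rb)] <- vals
      m[cbind(rb, ra)] <- vals
      ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
      sp <- unfold_spacings(ev)
      if (length(sp) >= min_eigenvalues) chi2 <- nnsd_chisq(sp)
    }
    trace[[t]] <- tibble::tibble(threshold = th, n_edges = n_edges,
                                 n_nodes = n_nodes, nnsd_chi2 = chi2)
    prev_edges <- n_edges
    prev_chi2 <- chi2
  }
  trace <- dplyr::bind_rows(trace)
  # transition: running median of the chi-square over distinct edge sets,
  # in scan order; tau = the last threshold whose smoothed statistic is
  # still Poisson-consistent, provided the scan ends in sustained
  # exceedance below it (matrices near the top of the scan are tiny and
  # their raw statistic is unstable, so early exceedances are ignored)
  scored <- trace[is.finite(trace$nnsd_chi2) &
                    !duplicated(trace$n_edges, fromLast = FALSE), ]
  tau <- NA_real_
  if (nrow(scored) >= smooth_window) {
    sm <- stats::runmed(scored$nnsd_chi2, k = smooth_window,
                        endrule = "constant")
    ok <- which(sm <= chi2_crit)
    if (length(ok) > 0 && max(ok) < length(sm))
      tau <- scored$threshold[max(ok)]
  }
  structure(list(tau = tau, no_threshold = !is.finite(tau),
                 overridden = FALSE, scan_trace = trace),
            class = "csgcn_threshold")
}

#' @export
print.csgcn_threshold <- function(x, ...) {
  if (x$no_threshold) cat("<csgcn_threshold> no transition found\n")
  else cat("<csgcn_threshold> tau =", format(x$tau), "\n")
  invisible(x)
}

#' Extract the thresholded network
#'
#' Keeps edge clusters with `|rho|` strictly greater than `tau` and
#' computes cluster-level node degrees.
#'
#' @param edge_clusters Edge-cluster tibble from [similarity_scan()].
#' @param tau Correlation threshold in `(0, 1)`; may come from
#'   [rmt_threshold()].
#' @return An object of class `csgcn_network`: list with `edges` (tibble,
#'   one row per retained edge cluster, plus an `edge` key column) and
#'   `degrees` (tibble `gene`, `k`).
#' @export
extract_network <- function(edge_clusters, tau) {
  if (inherits(tau, "csgcn_threshold")) tau <- tau$tau
  assert_that(is.finite(tau) && tau > 0 && tau < 1, "tau must be in (0,1)")
  edges <- edge_clusters |>
    dplyr::filter(is.finite(.data$rho), abs(.data$rho) > tau) |>
    dplyr::mutate(edge = edge_key(.data$gene_a, .data$gene_b,
                                  .data$cluster_index))
  degrees <- tibble::tibble(gene = c(edges$gene_a, edges$gene_b)) |>
    dplyr::count(.data$gene, name = "k") |>
    dplyr::arrange(dplyr::desc(.data$k))
  structure(list(edges = edges, degrees = degrees, tau = tau,
                 sample_ids = attr(edge_clusters, "sample_ids")),
            class = "csgcn_network")
}

#' @export
print.csgcn_network <- function(x, ...) {
  cat("<csgcn_network> ", nrow(x$edges), " edges, ", nrow(x$degrees),
      " nodes (tau = ", format(x$tau), ")\n", sep = "")
  invisible(x)
}
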