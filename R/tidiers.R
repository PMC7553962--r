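#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy methods for screening, decomposition and mutation results
#'
#' `tidy()` returns one row per elementary result (fold, gene, or
#' statistic); `glance()` returns a one-row summary.
#'
#' @param x A `csgcn_screen`, `csgcn_phase1`, `csgcn_rf`,
#'   `csgcn_decomposition`, `csgcn_threshold` or
#'   `csgcn_mutation_enrichment` object.
#' @param ... Unused.
#' @name csgcn-tidiers
NULL

#' @rdname csgcn-tidiers
#' @export
tidy.csgcn_screen <- function(x, ...) {
  tibble::tibble(fold = seq_along(x$fold_accuracy),
                 accuracy = x$fold_accuracy)
}

#' @rdname csgcn-tidiers
#' @export
glance.csgcn_screen <- function(x, ...) {
  tibble::tibble(set_size = x$set_size, mean_accuracy = x$mean_accuracy,
                 sd_accuracy = sd(x$fold_accuracy),
                 folds = length(x$fold_accuracy),
                 pooled_accuracy = sum(diag(x$confusion)) / sum(x$confusion))
}

#' @rdname csgcn-tidiers
#' @export
tidy.csgcn_phase1 <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "csgcn_phase1")
  attr(out, "reports") <- NULL
  out
}

#' @rdname csgcn-tidiers
#' @export
tidy.csgcn_rf <- function(x, ...) {
  tibble::tibble(gene = names(x$importance),
                 importance = unname(x$importance)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' @rdname csgcn-tidiers
#' @export
glance.csgcn_rf <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, folds = length(x$fold_accuracy),
                 n_trees = x$params$n_trees)
}

#' @rdname csgcn-tidiers
#' @export
tidy.csgcn_decomposition <- function(x, ...) {
  dplyr::left_join(x$aggregate,
                   tibble::tibble(gene = x$candidates, candidate = TRUE),
                   by = "gene") |>
    dplyr::mutate(candidate = !is.na(.data$candidate)) |>
    dplyr::arrange(dplyr::desc(.data$aggregate_frequency))
}

#' @rdname csgcn-tidiers
#' @export
glance.csgcn_decomposition <- function(x, ...) {
  tibble::tibble(n_genes = length(x$candidates) + length(x$non_candidates),
                 n_candidates = length(x$candidates),
                 candidate_threshold = x$candidate_threshold,
                 iterations = nrow(x$iterations))
}

#' @rdname csgcn-tidiers
#' @export
tidy.csgcn_threshold <- function(x, ...) x$scan_trace

#' @rdname csgcn-tidiers
#' @export
glance.csgcn_threshold <- function(x, ...) {
  tibble::tibble(tau = x$tau, no_threshold = x$no_threshold,
                 thresholds_scanned = nrow(x$scan_trace))
}

#' Plot the confusion matrix of a screening run
#'
#' @param object A `csgcn_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csgcn_screen <- function(object, ...) {
  df <- tibble::as_tibble(object$confusion, rownames = "true") |>
    tidyr::pivot_longer(-"true", names_to = "predicted", values_to = "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$true,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "predicted region", y = "true region") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot target vs random-set accuracies from a phase-I screen
#'
#' @param object A `csgcn_phase1`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csgcn_phase1 <- function(object, ...) {
  reports <- attr(object, "reports")
  df <- purrr::imap_dfr(reports, function(r, nm) {
    dplyr::bind_rows(
      tibble::tibble(set = nm, kind = "target",
                     accuracy = r$target$fold_accuracy),
      tibble::tibble(set = nm, kind = "random", accuracy = r$random_means))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accuracy, y = .data$set,
                                   colour = .data$kind)) +
    ggplot2::geom_jitter(height = 0.15, width = 0, alpha = 0.6, size = 1) +
    ggplot2::labs(x = "classification accuracy", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Heatmap of per-iteration gene frequencies from a decomposition
#'
#' @param object A `csgcn_decomposition`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.csgcn_decomposition <- function(object, ...) {
  ggplot2::ggplot(object$frequency,
                  ggplot2::aes(x = .data$gene, y = .data$iteration,
                               fill = .data$frequency)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkred") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "iteration (subset size)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Histogram of edges by number of enriched regions
#'
#' @param region_sets A `csgcn_region_sets`.
#' @return A ggplot.
#' @export
plot_region_histogram <- function(region_sets) {
  ggplot2::ggplot(region_sets$histogram,
                  ggplot2::aes(x = factor(.data$n_regions),
                               y = .data$n_edges)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "number of enriched regions", y = "edges") +
    ggplot2::theme_minimal()
}

#' Plot the RMT threshold scan trace
#'
#' @param threshold A `csgcn_threshold`.
#' @param chi2_crit Critical value drawn as a reference line.
#' @return A ggplot.
#' @export
plot_rmt_trace <- function(threshold, chi2_crit = 99.607) {
  df <- dplyr::filter(threshold$scan_trace, is.finite(.data$nnsd_chi2))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold,
                                   y = .data$nnsd_chi2)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = chi2_crit, linetype = 2,
                        colour = "firebrick") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "correlation threshold",
                  y = "NNSD chi-square statistic") +
    ggplot2::theme_minimal()
}
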