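# deterministic per-subset accuracy scorer; the same subset always gets
# the same seed so beam and exhaustive strategies score it identically
score_subset <- function(x, genes, labels, scorer, folds, seed, n_trees,
                         mlp_args) {
  sub_seed <- derive_seed(seed, 1111L, match(genes, rownames(x$values)))
  if (scorer == "rf") {
    m <- feature_matrix(x, genes)
    yfac <- factor(unname(labels[colnames(x$values)]))
    fold <- stratified_folds(as.character(yfac), folds, sub_seed)
    df <- as.data.frame(m)
    acc <- vapply(seq_len(folds), function(f) {
      tr <- fold != f
      fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = yfac[tr],
                            num.trees = n_trees,
                            seed = derive_seed(sub_seed, f),
                            num.threads = 1)
      mean(stats::predict(fit, df[!tr, , drop = FALSE],
                          num.threads = 1)$predictions == yfac[!tr])
    }, numeric(1))
    mean(acc)
  } else {
    do.call(train_eval,
            c(list(x = x, gene_set = genes, labels = labels, folds = folds,
                   seed = sub_seed), mlp_args))$mean_accuracy
  }
}

#' Phase-II combinatorial decomposition of a gene set
#'
#' Searches gene subsets of growing size for the most discriminatory
#' genes.  At iteration `k` the candidate subsets are all `C(n, k)`
#' subsets while `k <= exhaustive_max`, and afterwards the beam
#' extensions of the previous iteration's top-`beam_width` subsets (each
#' retained subset extended by every absent gene, deduplicated).  Every
#' subset is scored by cross-validated classification accuracy with a
#' deterministic per-subset seed; the top `beam_width` subsets survive
#' to the next iteration.  The per-iteration gene frequency is the
#' fraction of counted subsets containing the gene — all candidate
#' subsets during the exhaustive iterations (hence equal frequencies
#' there), the retained subsets afterwards.  A gene is a candidate when
#' its aggregate (across-iteration mean) frequency is at least half a
#' standard deviation above the mean aggregate frequency.
#'
#' @param x A preprocessed [gem] with labels.
#' @param gene_set Character vector of at least 4 gene ids.
#' @param labels Defaults to the GEM's labels.
#' @param exhaustive_max Largest subset size enumerated exhaustively.
#' @param beam_width Number of subsets retained between iterations.
#' @param scorer `"rf"` (fast Random-Forest CV, the default) or `"mlp"`
#'   (the phase-I network).
#' @param folds CV folds used by the subset scorer.
#' @param n_trees Trees per forest for the `"rf"` scorer.
#' @param seed Integer seed.
#' @param mlp_args List of extra arguments for [train_eval()] when
#'   `scorer = "mlp"`.
#' @return An object of class `csgcn_decomposition`: list with
#'   `frequency` (tibble `iteration`, `gene`, `frequency`), `aggregate`
#'   (tibble `gene`, `aggregate_frequency`), `candidate_threshold`
#'   (mean + 0.5 * sample SD), `candidates`, `non_candidates` and
#'   `iterations` (per-iteration bookkeeping).
#' @export
phase2_combinatorial <- function(x, gene_set, labels = NULL,
                                 exhaustive_max = 3, beam_width = 32,
                                 scorer = c("rf", "mlp"), folds = 3,
                                 n_trees = 50, seed = 1L,
                                 mlp_args = list()) {
  scorer <- match.arg(scorer)
  stopifnot(inherits(x, "gem"))
  labels <- labels %||% x$labels
  assert_that(!is.null(labels), "no sample labels available")
  assert_that(beam_width >= 1, "beam_width must be >= 1")
  n <- length(gene_set)
  assert_that(n >= 4, "gene_set must have at least 4 genes")
  gene_set <- sort(gene_set)
  freq_rows <- list()
  iter_info <- list()
  retained <- NULL
  for (k in seq_len(n - 1)) {
    if (k <= exhaustive_max) {
      cand <- combn(gene_set, k, simplify = FALSE)
    } else {
      ext <- list()
      for (s in retained) {
        for (g in setdiff(gene_set, s)) {
          ext[[length(ext) + 1]] <- sort(c(s, g))
        }
      }
      keys <- vapply(ext, paste, character(1), collapse = "|")
      cand <- ext[!duplicated(keys)]
    }
    scores <- vapply(cand, function(s)
      score_subset(x, s, labels, scorer, folds, seed, n_trees, mlp_args),
      numeric(1))
    ord <- order(scores, decreasing = TRUE)
    keep <- ord[seq_len(min(beam_width, length(cand)))]
    retained <- cand[keep]
    counted <- if (k <= exhaustive_max) cand else retained
    cnt <- table(factor(unlist(counted), levels = gene_set))
    freq_rows[[k]] <- tibble::tibble(
      iteration = k, gene = gene_set,
      frequency = as.numeric(cnt) / length(counted))
    iter_info[[k]] <- tibble::tibble(
      iteration = k, n_candidates = length(cand),
      n_retained = length(retained), best_accuracy = max(scores),
      exhaustive = k <= exhaustive_max)
  }
  frequency <- dplyr::bind_rows(freq_rows)
  aggregate <- frequency |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(aggregate_frequency = mean(.data$frequency),
                     .groups = "drop")
  thr <- candidate_threshold(aggregate$aggregate_frequency)
  candidates <- aggregate$gene[aggregate$aggregate_frequency >= thr]
  structure(list(
    frequency = frequency, aggregate = aggregate,
    candidate_threshold = thr, candidates = candidates,
    non_candidates = setdiff(gene_set, candidates),
    iterations = dplyr::bind_rows(iter_info),
    params = list(exhaustive_max = exhaustive_max, beam_width = beam_width,
                  scorer = scorer, folds = folds, n_trees = n_trees,
                  seed = seed)),
    class = "csgcn_decomposition")
}

#' Candidate threshold: mean + 0.5 * sample SD
#'
#' @param aggregate_frequency Numeric vector of aggregate frequencies.
#' @return The threshold value.
#' @export
candidate_threshold <- function(aggregate_frequency) {
  mean(aggregate_frequency) + 0.5 * sd(aggregate_frequency)
}

#' @export
print.csgcn_decomposition <- function(x, ...) {
  cat("<csgcn_decomposition> ", length(x$candidates), " candidate(s) of ",
      length(x$candidates) + length(x$non_candidates),
      " genes (threshold ", sprintf("%.3f", x$candidate_threshold), ")\n",
      sep = "")
  cat("  candidates: ", paste(x$candidates, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Top-k genes by Random-Forest importance
#'
#' Companion candidate extraction from [rf_classify()] importances, for
#' comparison with the phase-II candidates.
#'
#' @param importance Named importance vector (e.g. from [rf_classify()]),
#'   or a `csgcn_rf` object.
#' @param k Number of genes (defaults to all).
#' @param phase2 Optional `csgcn_decomposition`; when given, `k` defaults
#'   to the phase-II candidate count and the overlap is reported in the
#'   `overlap` attribute.
#' @return Character vector of the top-k genes by importance.
#' @export
rf_candidates <- function(importance, k = NULL, phase2 = NULL) {
  if (inherits(importance, "csgcn_rf")) importance <- importance$importance
  if (!is.null(phase2)) k <- k %||% length(phase2$candidates)
  k <- k %||% length(importance)
  assert_that(k <= length(importance), "k exceeds the gene-set size")
  top <- names(sort(importance, decreasing = TRUE))[seq_len(k)]
  if (!is.null(phase2)) attr(top, "overlap") <- intersect(top, phase2$candidates)
  top
}

#' Validate a decomposition by re-screening candidate and non-candidate sets
#'
#' Runs the Random-Forest classifier on the full set, the candidates and
#' the non-candidates, each against `n_random` size-controlled random
#' sets, and reports the accuracy difference from random for each — the
#' candidate set is expected to show the largest difference.
#'
#' @param x A preprocessed [gem] with labels and gene lengths.
#' @param candidates,non_candidates Disjoint gene sets.
#' @param labels,gene_lengths Default to the GEM's.
#' @param n_random Random sets per evaluated set.
#' @param folds,n_trees,seed Classifier controls.
#' @return Tibble (`set`, `size`, `accuracy`, `random_mean`,
#'   `delta_accuracy`), one row per non-empty set.
#' @export
validate_decomposition <- function(x, candidates, non_candidates,
                                   labels = NULL, gene_lengths = NULL,
                                   n_random = 50, folds = 5, n_trees = 100,
                                   seed = 1L) {
  stopifnot(inherits(x, "gem"))
  labels <- labels %||% x$labels
  gene_lengths <- gene_lengths %||% x$gene_lengths
  assert_that(length(intersect(candidates, non_candidates)) == 0,
              "candidate and non-candidate sets must be disjoint")
  universe <- intersect(rownames(x$values), names(gene_lengths))
  sets <- list(full = union(candidates, non_candidates),
               candidates = candidates, non_candidates = non_candidates)
  purrr::imap_dfr(sets, function(gs, nm) {
    if (length(gs) == 0) {
      message("set '", nm, "' is empty; skipped")
      return(tibble::tibble())
    }
    # seeds derive from the set content, so identical gene sets yield
    # identical reports regardless of which slot they occupy
    set_key <- sum(match(sort(gs), rownames(x$values)))
    obs <- rf_classify(x, gs, labels = labels, n_trees = n_trees,
                       folds = folds, seed = derive_seed(seed, 1212L, set_key))
    rsets <- random_size_controlled_sets(
      gs, universe, gene_lengths, n_sets = n_random,
      seed = derive_seed(seed, 1313L, set_key))
    rand <- vapply(seq_along(rsets), function(i) {
      rf_classify(x, rsets[[i]], labels = labels, n_trees = n_trees,
                  folds = folds,
                  seed = derive_seed(seed, 1414L, set_key, i))$accuracy
    }, numeric(1))
    tibble::tibble(set = nm, size = length(gs), accuracy = obs$accuracy,
                   random_mean = mean(rand),
                   delta_accuracy = obs$accuracy - mean(rand))
  })
}
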