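# stratified fold assignment, deterministic given seed
stratified_folds <- function(labels, folds, seed) {
  with_seed(derive_seed(seed, 404L), {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      assert_that(length(idx) >= folds,
                  paste0("class '", cl, "' has fewer samples than folds"))
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    fold
  })
}

# gene-set feature matrix: samples x genes, NA -> 0
feature_matrix <- function(x, gene_set) {
  assert_that(length(gene_set) > 0, "empty gene set")
  assert_that(all(gene_set %in% rownames(x$values)),
              "gene_set contains genes absent from the GEM")
  m <- t(x$values[gene_set, , drop = FALSE])
  m[is.na(m)] <- 0
  m
}

#' Cross-validated neural-network classification of samples from a gene set
#'
#' Trains the screening classifier — a feedforward network with an input
#' layer sized to the gene set, three ReLU hidden layers (512, 256 and
#' 128 units) and a softmax output over regions — under stratified
#' k-fold cross-validation, and reports per-fold accuracies and the
#' pooled confusion matrix.  Features are standardized per fold using
#' training-set statistics.  Deterministic given `seed`.
#'
#' @param x A preprocessed [gem] with labels (or pass `labels`).
#' @param gene_set Character vector of gene ids.
#' @param labels Named character vector sample -> region; defaults to the
#'   GEM's labels.
#' @param folds Number of CV folds.
#' @param seed Integer seed.
#' @param hidden Hidden layer sizes.
#' @param epochs,batch_size,learning_rate Training recipe (mini-batch
#'   Adam on the cross-entropy loss, single precision).
#' @return An object of class `csgcn_screen`: list with `fold_accuracy`,
#'   `mean_accuracy`, `confusion` (true x predicted counts),
#'   `class_recall`, `set_size` and `params`.
#' @export
train_eval <- function(x, gene_set, labels = NULL, folds = 10, seed = 1L,
                       hidden = c(512L, 256L, 128L), epochs = 15,
                       batch_size = 128, learning_rate = 3e-3) {
  stopifnot(inherits(x, "gem"))
  labels <- labels %||% x$labels
  assert_that(!is.null(labels), "no sample labels available")
  labels <- labels[colnames(x$values)]
  m <- feature_matrix(x, gene_set)
  yfac <- factor(unname(labels))
  yint <- as.integer(yfac) - 1L
  classes <- levels(yfac)
  fold <- stratified_folds(as.character(yfac), folds, seed)
  confusion <- matrix(0L, length(classes), length(classes),
                      dimnames = list(true = classes, predicted = classes))
  fold_acc <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(m[tr, , drop = FALSE])
    sg <- apply(m[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    Xtr <- sweep(sweep(m[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Xte <- sweep(sweep(m[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    pred <- .mlp_fit_predict_cpp(Xtr, yint[tr], Xte, length(classes),
                                 as.integer(hidden), as.integer(epochs),
                                 as.integer(batch_size), learning_rate,
                                 derive_seed(seed, 505L, f))
    truth <- yint[!tr]
    fold_acc[f] <- mean(pred == truth)
    for (i in seq_along(pred))
      confusion[truth[i] + 1L, pred[i] + 1L] <-
        confusion[truth[i] + 1L, pred[i] + 1L] + 1L
  }
  structure(list(
    set_size = length(gene_set), gene_set = gene_set,
    fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
    confusion = confusion,
    class_recall = diag(confusion) / pmax(rowSums(confusion), 1),
    params = list(folds = folds, seed = seed, hidden = hidden,
                  epochs = epochs, batch_size = batch_size,
                  learning_rate = learning_rate)),
    class = "csgcn_screen")
}

#' @export
print.csgcn_screen <- function(x, ...) {
  cat("<csgcn_screen> ", x$set_size, " genes, mean accuracy ",
      sprintf("%.3f", x$mean_accuracy), " over ",
      length(x$fold_accuracy), " folds\n", sep = "")
  invisible(x)
}

#' Size-controlled random gene sets
#'
#' Builds `n_sets` random gene sets matched to `gene_set`: for each
#' target gene, a gene is drawn uniformly from the universe genes whose
#' length lies within `size_tolerance` of the target gene's length,
#' excluding the target set and genes already chosen for the same random
#' set.  When no candidate is in tolerance the nearest-length gene is
#' used as a fallback (reported via a message).
#'
#' @param gene_set Target gene ids.
#' @param universe All candidate gene ids (e.g. all GEM genes).
#' @param gene_lengths Named numeric vector covering the universe.
#' @param n_sets Number of random sets.
#' @param size_tolerance Relative length tolerance (0.10 = within 10%).
#' @param seed Integer seed.
#' @return A list of `n_sets` character vectors, each the size of
#'   `gene_set`.
#' @export
random_size_controlled_sets <- function(gene_set, universe, gene_lengths,
                                        n_sets = 50, size_tolerance = 0.10,
                                        seed = 1L) {
  assert_that(all(gene_set %in% universe), "gene_set must be in universe")
  assert_that(all(universe %in% names(gene_lengths)),
              "gene_lengths must cover the universe")
  pool0 <- setdiff(universe, gene_set)
  assert_that(length(pool0) >= length(gene_set),
              "universe too small to draw size-controlled sets")
  len <- gene_lengths[pool0]
  n_fallback <- 0L
  sets <- with_seed(derive_seed(seed, 606L), {
    lapply(seq_len(n_sets), function(s) {
      taken <- character(0)
      chosen <- vapply(gene_set, function(g) {
        L <- gene_lengths[[g]]
        avail <- setdiff(pool0, taken)
        cand <- avail[gene_lengths[avail] >= (1 - size_tolerance) * L &
                        gene_lengths[avail] <= (1 + size_tolerance) * L]
        pick <- if (length(cand) > 0) {
          cand[sample.int(length(cand), 1)]
        } else {
          n_fallback <<- n_fallback + 1L
          avail[which.min(abs(gene_lengths[avail] - L))]
        }
        taken <<- c(taken, pick)
        pick
      }, character(1))
      unname(chosen)
    })
  })
  if (n_fallback > 0)
    message("size-controlled matching: ", n_fallback,
            " gene(s) had no candidate within tolerance; ",
            "nearest-length fallback used")
  sets
}

#' Phase-I gene-set biomarker screening
#'
#' Screens each gene set for significant classification potential:
#' the set and each of its `n_random` size-controlled random sets are
#' evaluated with [train_eval()], and the set's fold accuracies are
#' compared with the random sets' mean accuracies by a two-sample
#' Student's t-test.  A set is significant when p < `alpha` and its mean
#' accuracy exceeds the random mean.
#'
#' @param x A preprocessed [gem] with labels and gene lengths.
#' @param gene_sets Named list of gene id vectors.
#' @param labels,gene_lengths Default to the GEM's.
#' @param n_random Number of random sets per target set.
#' @param size_tolerance Length-matching tolerance.
#' @param alpha Significance level on the t-test.
#' @param folds,seed,... Passed to [train_eval()].
#' @return An object of class `csgcn_phase1`: tibble with one row per
#'   set (`set`, `size`, `mean_accuracy`, `random_mean`, `random_sd`,
#'   `t_statistic`, `p_value`, `p_value_all_folds`, `significant`), with
#'   the per-set `csgcn_screen` reports and random accuracies in the
#'   `reports` attribute.
#' @export
phase1_screen <- function(x, gene_sets, labels = NULL, gene_lengths = NULL,
                          n_random = 50, size_tolerance = 0.10,
                          alpha = 0.001, folds = 10, seed = 1L, ...) {
  stopifnot(inherits(x, "gem"))
  labels <- labels %||% x$labels
  gene_lengths <- gene_lengths %||% x$gene_lengths
  assert_that(!is.null(gene_lengths), "gene lengths required")
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  universe <- intersect(rownames(x$values), names(gene_lengths))
  reports <- list()
  rows <- purrr::imap_dfr(gene_sets, function(gs, nm) {
    target <- train_eval(x, gs, labels = labels, folds = folds,
                         seed = derive_seed(seed, 707L, match(nm, names(gene_sets))),
                         ...)
    rsets <- random_size_controlled_sets(
      gs, universe, gene_lengths, n_sets = n_random,
      size_tolerance = size_tolerance,
      seed = derive_seed(seed, 808L, match(nm, names(gene_sets))))
    rand <- lapply(seq_along(rsets), function(k) {
      train_eval(x, rsets[[k]], labels = labels, folds = folds,
                 seed = derive_seed(seed, 909L, match(nm, names(gene_sets)), k),
                 ...)
    })
    rand_means <- vapply(rand, `[[`, numeric(1), "mean_accuracy")
    rand_folds <- unlist(lapply(rand, `[[`, "fold_accuracy"))
    tt <- t.test(target$fold_accuracy, rand_means)
    tt2 <- t.test(target$fold_accuracy, rand_folds)
    reports[[nm]] <<- list(target = target, random_means = rand_means,
                           random_sets = rsets)
    tibble::tibble(
      set = nm, size = length(gs),
      mean_accuracy = target$mean_accuracy,
      random_mean = mean(rand_means), random_sd = sd(rand_means),
      t_statistic = unname(tt$statistic), p_value = tt$p.value,
      p_value_all_folds = tt2$p.value,
      significant = tt$p.value < alpha &&
        target$mean_accuracy > mean(rand_means))
  })
  class(rows) <- c("csgcn_phase1", class(rows))
  attr(rows, "reports") <- reports
  attr(rows, "alpha") <- alpha
  rows
}

#' Cross-validated Random-Forest classification and gene importances
#'
#' Random-Forest comparator for the network classifier: stratified CV
#' accuracy plus impurity-based gene importances (normalized to sum to
#' one).  `n_trees = 100` with fully-grown trees mirrors a forest with a
#' negligible (1e-7) impurity-decrease stopping threshold.
#'
#' @inheritParams train_eval
#' @param n_trees Number of trees.
#' @return List of class `csgcn_rf`: `fold_accuracy`, `accuracy`,
#'   `importance` (named, sums to 1).
#' @export
rf_classify <- function(x, gene_set, labels = NULL, n_trees = 100,
                        folds = 10, seed = 1L) {
  stopifnot(inherits(x, "gem"))
  labels <- labels %||% x$labels
  labels <- labels[colnames(x$values)]
  m <- feature_matrix(x, gene_set)
  yfac <- factor(unname(labels))
  fold <- stratified_folds(as.character(yfac), folds, seed)
  fold_acc <- numeric(folds)
  imp <- numeric(ncol(m))
  df <- as.data.frame(m)
  names(df) <- make.names(colnames(m))
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit <- ranger::ranger(x = df[tr, , drop = FALSE], y = yfac[tr],
                          num.trees = n_trees, importance = "impurity",
                          seed = derive_seed(seed, 1010L, f),
                          num.threads = 1)
    pred <- stats::predict(fit, df[!tr, , drop = FALSE],
                           num.threads = 1)$predictions
    fold_acc[f] <- mean(pred == yfac[!tr])
    imp <- imp + fit$variable.importance
  }
  imp <- pmax(imp, 0)
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  names(imp) <- gene_set
  structure(list(fold_accuracy = fold_acc, accuracy = mean(fold_acc),
                 importance = imp,
                 params = list(n_trees = n_trees, folds = folds, seed = seed)),
            class = "csgcn_rf")
}
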