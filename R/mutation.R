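#' Read a simplified somatic-mutation table
#'
#' Expects a TSV with at least the columns `tumor_id`, `tumor_type` and
#' `gene`, one row per mutation event; any extra (MAF-style) columns are
#' ignored.
#'
#' @param path File path.
#' @return A tibble (`tumor_id`, `tumor_type`, `gene`).
#' @export
read_mutations <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("tumor_id", "tumor_type", "gene")
  miss <- setdiff(required, names(df))
  assert_that(length(miss) == 0,
              paste("missing required column(s):",
                    paste(miss, collapse = ", ")))
  dplyr::select(df, dplyr::all_of(required))
}

#' Mutation count statistics for a gene set in one tumor type
#'
#' Restricted to the rows of `tumor_type` whose gene is in `gene_set`:
#' the number of distinct mutated genes, the number of distinct tumors
#' with at least one mutation, and the total mutation count.
#'
#' @param mutations Mutation tibble (see [read_mutations()]).
#' @param gene_set Character vector of gene ids.
#' @param tumor_type Tumor type present in the table.
#' @return A named numeric vector `c(mutated_genes, mutated_tumors,
#'   total_mutations)`.
#' @export
count_stats <- function(mutations, gene_set, tumor_type) {
  assert_that(length(gene_set) > 0, "empty gene set")
  assert_that(tumor_type %in% mutations$tumor_type,
              paste0("tumor type '", tumor_type, "' not in table"))
  sub <- mutations[mutations$tumor_type == tumor_type &
                     mutations$gene %in% gene_set, ]
  c(mutated_genes = length(unique(sub$gene)),
    mutated_tumors = length(unique(sub$tumor_id)),
    total_mutations = nrow(sub))
}

#' Empirical mutation-enrichment test for a gene set
#'
#' Compares the observed count statistics of `gene_set` in `tumor_type`
#' against `n_rand` size-controlled random gene sets (length-matched
#' within 10% by default, same matcher as the classifier screening).
#' For each statistic the add-one empirical p-value is
#' `(1 + #\{random >= observed\}) / (n_rand + 1)` (ties count as
#' exceedances); the uncorrected `#\{random >= observed\} / n_rand` is
#' also reported.
#'
#' @param mutations Mutation tibble.
#' @param gene_set Target gene ids.
#' @param tumor_type Tumor type to test.
#' @param universe Candidate genes for the random sets.
#' @param gene_lengths Named lengths covering the universe.
#' @param n_rand Number of random sets.
#' @param size_tolerance Length-matching tolerance.
#' @param seed Integer seed (a per-tumor-type offset keeps draws
#'   reproducible across types).
#' @param alpha Significance level on the add-one p-value.
#' @return A tibble of class `csgcn_mutation_enrichment`: one row per
#'   statistic (`statistic`, `observed`, `random_mean`, `p_value`
#'   (add-one), `p_plain`, `significant`), with `n_rand`, `tumor_type`
#'   and set size in attributes.
#' @export
empirical_enrichment <- function(mutations, gene_set, tumor_type, universe,
                                 gene_lengths, n_rand = 100,
                                 size_tolerance = 0.10, seed = 1L,
                                 alpha = 0.01) {
  assert_that(all(gene_set %in% universe),
              "gene_set must be contained in the universe")
  obs <- count_stats(mutations, gene_set, tumor_type)
  type_seed <- derive_seed(seed, 1515L,
                           sum(utf8ToInt(tumor_type)))
  rsets <- random_size_controlled_sets(
    gene_set, universe, gene_lengths, n_sets = n_rand,
    size_tolerance = size_tolerance, seed = type_seed)
  rand <- vapply(rsets, function(gs) count_stats(mutations, gs, tumor_type),
                 numeric(3))
  out <- purrr::map_dfr(seq_along(obs), function(i) {
    r <- rand[i, ]
    exceed <- sum(r >= obs[i])
    tibble::tibble(statistic = names(obs)[i], observed = unname(obs[i]),
                   random_mean = mean(r),
                   p_value = (1 + exceed) / (n_rand + 1),
                   p_plain = exceed / n_rand)
  })
  out$significant <- out$p_value < alpha
  class(out) <- c("csgcn_mutation_enrichment", class(out))
  attr(out, "tumor_type") <- tumor_type
  attr(out, "set_size") <- length(gene_set)
  attr(out, "n_rand") <- n_rand
  out
}

#' Mutation enrichment over several gene sets and tumor types
#'
#' @param gene_sets Named list of gene sets.
#' @param tumor_types Tumor types to test (default: all in the table).
#' @inheritParams empirical_enrichment
#' @return A tibble with `set`, `tumor_type` and the per-statistic
#'   columns of [empirical_enrichment()].
#' @export
mutation_enrichment_table <- function(mutations, gene_sets, universe,
                                      gene_lengths, tumor_types = NULL,
                                      n_rand = 100, size_tolerance = 0.10,
                                      seed = 1L, alpha = 0.01) {
  tumor_types <- tumor_types %||% sort(unique(mutations$tumor_type))
  if (is.null(names(gene_sets)))
    names(gene_sets) <- paste0("set", seq_along(gene_sets))
  purrr::imap_dfr(gene_sets, function(gs, nm) {
    purrr::map_dfr(tumor_types, function(tt) {
      res <- empirical_enrichment(mutations, gs, tt, universe, gene_lengths,
                                  n_rand = n_rand,
                                  size_tolerance = size_tolerance,
                                  seed = seed, alpha = alpha)
      dplyr::mutate(tibble::as_tibble(res), set = nm, tumor_type = tt,
                    .before = 1)
    })
  })
}
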