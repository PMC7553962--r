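toy_muts <- tibble::tibble(
  tumor_id = c("t1", "t1", "t2"),
  tumor_type = "GBM",
  gene = c("A", "A", "B"))

test_that("mutation tables parse with required columns and ignore extras", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "muts.tsv")
  readr::write_tsv(dplyr::mutate(toy_muts, vaf = 0.3, caller = "muse"), p)
  mt <- read_mutations(p)
  expect_equal(nrow(mt), 3L)
  expect_named(mt, c("tumor_id", "tumor_type", "gene"))

  readr::write_tsv(toy_muts[, c("tumor_id", "tumor_type")], p)
  expect_error(read_mutations(p), "gene")
})

test_that("count statistics match hand counts and the brute-force oracle", {
  expect_equal(count_stats(toy_muts, c("A", "B"), "GBM"),
               c(mutated_genes = 2, mutated_tumors = 2,
                 total_mutations = 3))
  expect_equal(count_stats(toy_muts, "A", "GBM")[["mutated_tumors"]], 1)
  expect_equal(
    count_stats(tibble::tibble(tumor_id = c("t1", "t2"), tumor_type = "GBM",
                               gene = "A"), "A", "GBM"),
    c(mutated_genes = 1, mutated_tumors = 2, total_mutations = 2))
  expect_equal(count_stats(toy_muts, c("Z1", "Z2"), "GBM"),
               c(mutated_genes = 0, mutated_tumors = 0,
                 total_mutations = 0))
  expect_error(count_stats(toy_muts, character(0), "GBM"), "empty")
  expect_error(count_stats(toy_muts, "A", "LUAD"), "LUAD")

  # random tables against the nested-loop recount
  set.seed(81)
  for (i in 1:10) {
    mt <- tibble::tibble(
      tumor_id = sample(sprintf("t%02d", 1:15), 200, replace = TRUE),
      tumor_type = sample(c("GBM", "LGG"), 200, replace = TRUE),
      gene = sample(LETTERS[1:12], 200, replace = TRUE))
    gs <- sample(LETTERS[1:12], 5)
    expect_identical(count_stats(mt, gs, "GBM"),
                     count_stats_oracle(mt, gs, "GBM"))
  }

  # adding a row inside the set never decreases any statistic
  mt <- toy_muts
  grown <- dplyr::bind_rows(mt, tibble::tibble(
    tumor_id = "t3", tumor_type = "GBM", gene = "A"))
  expect_true(all(count_stats(grown, c("A", "B"), "GBM") >=
                    count_stats(mt, c("A", "B"), "GBM")))
})

test_that("empirical p-values follow the add-one convention", {
  lengths <- setNames(rep(1000, 30), sprintf("g%02d", 1:30))
  universe <- names(lengths)
  # all mutations fall in the target set: observed beats every random draw
  mt <- tibble::tibble(tumor_id = sprintf("t%d", 1:10), tumor_type = "GBM",
                       gene = rep(universe[1:2], 5))
  res <- empirical_enrichment(mt, universe[1:2], "GBM", universe, lengths,
                              n_rand = 100, seed = 2)
  expect_equal(res$p_value, rep(1 / 101, 3), tolerance = 1e-12)
  expect_equal(res$p_plain, rep(0, 3))
  expect_true(all(res$significant))

  # observed at zero while random sets tie or exceed: p = 1
  res0 <- empirical_enrichment(mt, universe[25:26], "GBM", universe,
                               lengths, n_rand = 50, seed = 3)
  expect_equal(res0$p_value, rep(1, 3))
  expect_false(any(res0$significant))

  expect_error(empirical_enrichment(mt, "absent", "GBM", universe, lengths),
               "universe")
})

test_that("enrichment over sets and tumor types returns a tidy table", {
  cfg <- small_config()
  mt <- simulate_mutations(cfg)$mutations
  lengths <- small_sim()$gem$gene_lengths
  tab <- mutation_enrichment_table(
    mt, list(planted = cfg$enriched_sets[[1]]$genes),
    universe = cfg$gene_ids, gene_lengths = lengths,
    n_rand = 30, seed = 4)
  expect_equal(nrow(tab), 3L * length(cfg$tumor_types))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  # the planted 5x set stands out for the mutated-gene count
  expect_true(all(tab$observed[tab$statistic == "mutated_genes"] >
                    tab$random_mean[tab$statistic == "mutated_genes"]))
})
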