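test_that("edge enrichment reproduces exact hypergeometric cases", {
  # cluster = exactly the 30 samples of region r out of 100
  labels <- setNames(rep(c("r", "other"), c(30, 70)), sprintf("s%03d", 1:100))
  mask <- paste(rep(c("1", "0"), c(30, 70)), collapse = "")
  rec <- edge_label_enrichment(edge_fixture(mask), labels,
                               sample_ids = names(labels),
                               family = "per_target")
  p_r <- rec$p_raw[rec$label == "r"]
  expect_equal(p_r * choose(100, 30), 1, tolerance = 1e-9)

  # cluster = all samples: no discrimination, p = 1 for every label
  rec_all <- edge_label_enrichment(edge_fixture(strrep("1", 100)), labels,
                                   sample_ids = names(labels))
  expect_true(all(rec_all$p_raw == 1))

  # '9' samples are excluded from the table
  mask9 <- paste(c(rep("1", 20), rep("9", 10), rep("0", 70)), collapse = "")
  rec9 <- edge_label_enrichment(edge_fixture(mask9), labels,
                                sample_ids = names(labels),
                                family = "per_target")
  r9 <- rec9[rec9$label == "r", ]
  expect_equal(r9$a + r9$b + r9$c + r9$d, 90)
  expect_equal(r9$a + r9$c, 20)  # only 20 eligible 'r' samples remain

  # implementation agrees with stats::fisher.test one-sided
  ft <- fisher.test(matrix(c(r9$a, r9$b, r9$c, r9$d), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(r9$p_raw, ft$p.value, tolerance = 1e-9)
})

test_that("Hochberg adjustment behaves as a step-up family correction", {
  labels <- setNames(rep(c("r1", "r2", "r3"), each = 20),
                     sprintf("s%02d", 1:60))
  masks <- vapply(1:8, function(i) {
    paste(sample(c(rep("1", 20), rep("0", 40))), collapse = "")
  }, character(1))
  set.seed(61)
  edges <- dplyr::bind_rows(lapply(1:8, function(i)
    edge_fixture(masks[i], gene_a = paste0("x", i), gene_b = paste0("y", i))))
  rec <- edge_label_enrichment(edges, labels, sample_ids = names(labels))
  expect_true(all(rec$p_adj >= rec$p_raw))
  expect_true(all(rec$p_adj <= 1))
  # matches p.adjust on the global family
  expect_equal(rec$p_adj, p.adjust(rec$p_raw, "hochberg"))
  # ordering preserved
  o <- order(rec$p_raw)
  expect_true(all(diff(rec$p_adj[o]) >= -1e-15))
  # per-target family of size n_labels
  rec_t <- edge_label_enrichment(edges, labels, sample_ids = names(labels),
                                 family = "per_target")
  one <- rec_t[rec_t$target == rec_t$target[1], ]
  expect_equal(one$p_adj, p.adjust(one$p_raw, "hochberg"))
})

test_that("module enrichment unions member edge masks", {
  labels <- setNames(rep(c("r1", "r2"), each = 30), sprintf("s%02d", 1:60))
  m1 <- paste(rep(c("1", "0"), c(15, 45)), collapse = "")
  m2 <- paste(c(rep("0", 15), rep("1", 15), rep("0", 30)), collapse = "")
  edges <- dplyr::bind_rows(
    edge_fixture(m1, "a", "b"),
    edge_fixture(m2, "b", "c"))
  modules <- tibble::tibble(module_id = "M0001",
                            gene_a = c("a", "b"), gene_b = c("b", "c"))

  rec <- module_label_enrichment(modules, edges, labels,
                                 sample_ids = names(labels),
                                 family = "per_target")
  r1 <- rec[rec$label == "r1", ]
  # union covers exactly the 30 r1 samples
  expect_equal(r1$a, 30)
  expect_equal(r1$p_raw, fisher_tail_oracle(30, 0, 0, 30), tolerance = 1e-12)

  # single-edge module has the edge's own p
  mod1 <- tibble::tibble(module_id = "M0002", gene_a = "a", gene_b = "b")
  rec1 <- module_label_enrichment(mod1, edges, labels,
                                  sample_ids = names(labels),
                                  family = "per_target")
  edge_rec <- edge_label_enrichment(edges[1, ], labels,
                                    sample_ids = names(labels),
                                    family = "per_target")
  expect_equal(rec1$p_raw, edge_rec$p_raw)

  # union covering every sample is uninformative
  mod_all <- module_label_enrichment(
    modules,
    dplyr::bind_rows(edge_fixture(strrep("1", 60), "a", "b"),
                     edge_fixture(strrep("1", 60), "b", "c")),
    labels, sample_ids = names(labels))
  expect_true(all(mod_all$p_raw == 1))
})

test_that("region sets honor the strict significance threshold", {
  rec <- tibble::tibble(
    target = c("e1", "e2", "e3"),
    gene_a = c("a", "b", "c"), gene_b = c("x", "y", "z"),
    cluster_index = 0L,
    label = "r1",
    a = 1, b = 1, c = 1, d = 1,
    p_raw = c(1e-12, 1e-10, 2e-11),
    p_adj = c(1e-12, 1e-10, 2e-11))
  attr(rec, "n_regions") <- 1L
  rs <- select_region_sets(rec, edge_alpha = 1e-10)
  # p_adj exactly at the threshold is NOT selected
  expect_setequal(rs$region_edges$target, c("e1", "e3"))
  expect_equal(rs$histogram$n_edges[rs$histogram$n_regions == 0], 1L)
  expect_true(all(rs$region_edges$unique))
})

test_that("region selection and uniqueness bookkeeping are consistent", {
  g <- ref_gem()
  ec <- ref_scan()
  net <- extract_network(ec, rmt_threshold(ec))
  rec <- edge_label_enrichment(net, g$labels)
  rs <- select_region_sets(rec, edge_alpha = 1e-10)
  counts <- rs$region_counts
  expect_setequal(
    rs$region_edges$target[rs$region_edges$unique],
    counts$target[counts$n_regions == 1])
  expect_equal(sum(rs$histogram$n_edges), nrow(counts))
  # histogram bin 0 = edges enriched nowhere
  expect_equal(rs$histogram$n_edges[rs$histogram$n_regions == 0],
               sum(counts$n_regions == 0))

  # label-shuffled null: virtually no edge reaches significance
  set.seed(71)
  frac <- vapply(1:50, function(i) {
    sh <- setNames(sample(unname(g$labels)), names(g$labels))
    r <- edge_label_enrichment(net, sh)
    length(unique(r$target[r$p_adj < 1e-3])) / length(unique(r$target))
  }, numeric(1))
  expect_lte(mean(frac), 0.002)
})

test_that("anatomical merging unions region sets and flags small groups", {
  rec <- tibble::tibble(
    target = c("e1", "e2", "e3", "e4"),
    gene_a = c("a", "b", "c", "d"), gene_b = c("x", "y", "z", "w"),
    cluster_index = 0L,
    label = c("R1", "R2", "R2", "R3"),
    a = 1, b = 1, c = 1, d = 1,
    p_raw = 1e-12, p_adj = 1e-12)
  attr(rec, "n_regions") <- 3L
  rs <- select_region_sets(rec, edge_alpha = 1e-10)

  # identity map: groups are the regions themselves
  ident <- setNames(c("R1", "R2", "R3"), c("R1", "R2", "R3"))
  m_id <- merge_anatomical(rs, ident, min_edges = 1)
  expect_setequal(unique(m_id$group), c("R1", "R2", "R3"))

  # disjoint regions merge additively
  mp <- c(R1 = "grp", R2 = "grp", R3 = "solo")
  m <- merge_anatomical(rs, mp, min_edges = 3)
  summ <- attr(m, "group_summary")
  expect_equal(summ$n_edges[summ$group == "grp"], 3L)
  expect_true(summ$too_small[summ$group == "solo"])
  sets <- merged_gene_sets(m, drop_small = FALSE)
  expect_setequal(sets$grp, c("a", "b", "c", "x", "y", "z"))

  expect_error(merge_anatomical(rs, c(R1 = "grp")), "not covered")

  # the packaged 13-region example map loads and covers 13 labels
  map_path <- system.file("extdata", "gtex_brain_region_merge.yaml",
                          package = "csgcn")
  brain <- read_merge_map(map_path)
  expect_length(brain, 13L)
  expect_setequal(unique(unname(brain)),
                  c("basal ganglia", "cerebellum", "cortex", "hypothalamus",
                    "spinal cord", "substantia nigra", "amygdala",
                    "hippocampus"))
})

test_that("node expression statistics match hand arithmetic", {
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  g <- gem(m, scale = "log2")
  st <- node_expression_stats(g, c("g1", "g2"))
  expect_equal(st$mu_set, mean(c(1, 2, 4, 5)))
  expect_equal(st$sigma_set, sd(c(1, 2, 4, 5)))
  expect_equal(st$mu_all, mean(1:6))

  all_st <- node_expression_stats(g, c("g1", "g2", "g3"))
  expect_equal(all_st$mu_set, all_st$mu_all)

  cg <- gem(matrix(5, 1, 4, dimnames = list("g", paste0("s", 1:4))),
            scale = "log2")
  expect_equal(node_expression_stats(cg, "g")$sigma_set, 0)
  expect_error(node_expression_stats(g, character(0)), "empty")
})

test_that("the threshold sweep counts edges per region at each alpha", {
  rec <- tibble::tibble(
    target = sprintf("e%d", 1:6),
    gene_a = letters[1:6], gene_b = LETTERS[1:6], cluster_index = 0L,
    label = rep(c("R1", "R2"), 3),
    a = 1, b = 1, c = 1, d = 1,
    p_raw = c(1e-21, 1e-16, 1e-11, 1e-6, 1e-4, 0.5),
    p_adj = c(1e-21, 1e-16, 1e-11, 1e-6, 1e-4, 0.5))
  sw <- enrichment_threshold_sweep(rec)
  expect_equal(sum(sw$n_edges[sw$alpha == 1e-20]), 1L)
  expect_equal(sum(sw$n_edges[sw$alpha == 1e-3]), 5L)
})
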