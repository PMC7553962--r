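test_that("the network classifier learns planted structure and honors chance", {
  g <- small_gem()
  informative <- small_informative()

  r <- train_eval(g, informative, seed = 1L)
  expect_gte(r$mean_accuracy, 0.9)
  expect_equal(sum(r$confusion), ncol(g$values))
  expect_equal(unname(rowSums(r$confusion)),
               unname(as.vector(table(g$labels))))
  # pooled accuracy equals the confusion trace over total
  expect_equal(glance(r)$pooled_accuracy,
               sum(diag(r$confusion)) / sum(r$confusion))

  # deterministic given seed
  r2 <- train_eval(g, informative, seed = 1L)
  expect_identical(r$fold_accuracy, r2$fold_accuracy)

  # shuffled labels: chance level is 1 / n_classes
  sh <- g
  set.seed(17)
  sh$labels <- setNames(sample(unname(g$labels)), names(g$labels))
  acc <- train_eval(sh, informative, seed = 2L)$mean_accuracy
  expect_lt(abs(acc - 1 / 3), 0.07)

  # duplicating a gene leaves the achievable accuracy unchanged
  dup <- train_eval(g, c(informative, informative[1]), seed = 1L)
  expect_lt(abs(dup$mean_accuracy - r$mean_accuracy), 0.05)

  expect_error(train_eval(g, character(0)), "empty")
  expect_error(train_eval(g, informative, folds = 50), "fewer samples")
})

test_that("size-controlled random sets respect the length tolerance", {
  lengths <- setNames(seq(500, 5000, length.out = 200),
                      sprintf("u%03d", 1:200))
  universe <- names(lengths)
  target <- universe[c(20, 80, 140)]
  sets <- random_size_controlled_sets(target, universe, lengths,
                                      n_sets = 50, seed = 3)
  expect_length(sets, 50L)
  for (s in sets) {
    expect_length(s, 3L)
    expect_false(any(s %in% target))
    expect_false(any(duplicated(s)))
    expect_true(all(abs(lengths[s] - lengths[target]) <=
                      0.1 * lengths[target] + 1e-9))
  }
  # deterministic
  sets2 <- random_size_controlled_sets(target, universe, lengths,
                                       n_sets = 50, seed = 3)
  expect_identical(sets, sets2)

  # no candidate in tolerance: nearest-length fallback, with a message
  sparse_len <- setNames(c(1000, 5000, 5050), c("t", "far1", "far2"))
  expect_message(
    out <- random_size_controlled_sets("t", names(sparse_len), sparse_len,
                                       n_sets = 1, seed = 1),
    "fallback")
  expect_identical(out[[1]], "far1")

  # universe = target set only: impossible
  expect_error(random_size_controlled_sets(c("a", "b"), c("a", "b"),
                                           c(a = 1, b = 2), n_sets = 1),
               "universe")
})

test_that("phase-I screening flags planted sets and not noise (small study)", {
  g <- small_gem()
  informative <- small_informative()
  decoy <- setdiff(rownames(g$values), informative)[1:8]

  scr <- phase1_screen(g, list(planted = informative, decoy = decoy),
                       n_random = 8, seed = 5L)
  expect_true(scr$significant[scr$set == "planted"])
  expect_false(scr$significant[scr$set == "decoy"])
  expect_equal(nrow(scr), 2L)
  reports <- attr(scr, "reports")
  expect_length(reports$planted$random_means, 8L)
  # tidiers
  td <- tidy(scr)
  expect_false(inherits(td, "csgcn_phase1"))
  expect_named(tidy(reports$planted$target), c("fold", "accuracy"))
})

test_that("the random-forest comparator ranks a separating gene first", {
  g <- small_gem()
  # construct a gene that encodes the label perfectly
  g2 <- g
  marker <- as.numeric(factor(g2$labels[colnames(g2$values)]))
  g2$values <- rbind(g2$values,
                     MARKER = marker + rnorm(length(marker), 0, 0.01))
  gs <- c("MARKER", setdiff(rownames(g$values), small_informative())[1:5])
  rf <- rf_classify(g2, gs, folds = 5, seed = 4L)
  expect_equal(names(which.max(rf$importance)), "MARKER")
  expect_equal(sum(rf$importance), 1, tolerance = 1e-12)
  expect_gte(rf$accuracy, 0.9)

  # shuffled labels: near chance
  sh <- g2
  set.seed(31)
  sh$labels <- setNames(sample(unname(g2$labels)), names(g2$labels))
  rf0 <- rf_classify(sh, gs, folds = 5, seed = 4L)
  expect_lt(rf0$accuracy, 1 / 3 + 0.12)

  expect_named(tidy(rf), c("gene", "importance"))
})
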