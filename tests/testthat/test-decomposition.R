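test_that("the candidate threshold is mean + half a sample SD", {
  agg <- c(0.9, 0.2, 0.2, 0.2, 0.5)
  thr <- candidate_threshold(agg)
  # independent one-pass mean/SD computation
  n <- length(agg)
  mu <- sum(agg) / n
  s2 <- (sum(agg^2) - n * mu^2) / (n - 1)
  expect_equal(thr, mu + 0.5 * sqrt(s2), tolerance = 1e-12)
  expect_identical(agg >= thr, c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("exhaustive iterations count every gene equally", {
  g <- small_gem()
  set.seed(51)
  gs <- c(sample(small_informative(), 2),
          sample(setdiff(rownames(g$values), small_informative()), 4))
  dec <- phase2_combinatorial(g, gs, seed = 2L, folds = 2, n_trees = 25)
  for (k in 1:3) {
    fk <- dec$frequency$frequency[dec$frequency$iteration == k]
    expect_equal(fk, rep(k / 6, 6), tolerance = 1e-12)
  }
  expect_setequal(c(dec$candidates, dec$non_candidates), unname(gs))
  expect_length(intersect(dec$candidates, dec$non_candidates), 0L)
  expect_true(all(
    dec$aggregate$aggregate_frequency[
      dec$aggregate$gene %in% dec$candidates] >= dec$candidate_threshold))
  # frequencies are proper fractions
  expect_true(all(dec$frequency$frequency >= 0 &
                    dec$frequency$frequency <= 1))
  expect_error(phase2_combinatorial(g, gs[1:3]), "at least 4")
  expect_error(phase2_combinatorial(g, gs, beam_width = 0), "beam_width")
})

test_that("a planted discriminative gene rises to candidacy", {
  g <- small_gem()
  set.seed(52)
  planted <- sample(small_informative(), 1)
  noise <- sample(setdiff(rownames(g$values), small_informative()), 7)
  dec <- phase2_combinatorial(g, c(planted, noise), seed = 3L,
                              folds = 2, n_trees = 30)
  expect_true(planted %in% dec$candidates)
  agg <- dec$aggregate
  expect_equal(agg$gene[which.max(agg$aggregate_frequency)], planted)
  expect_named(glance(dec),
               c("n_genes", "n_candidates", "candidate_threshold",
                 "iterations"))
})

test_that("rf candidate extraction takes the top-k importances", {
  imp <- c(g1 = 0.5, g2 = 0.3, g3 = 0.15, g4 = 0.05)
  expect_identical(rf_candidates(imp, 1), "g1")
  expect_setequal(rf_candidates(imp), names(imp))
  expect_error(rf_candidates(imp, 5), "exceeds")
  fake_p2 <- structure(list(candidates = c("g1", "g9")),
                       class = "csgcn_decomposition")
  top <- rf_candidates(imp, phase2 = fake_p2)
  expect_length(top, 2L)
  expect_identical(attr(top, "overlap"), "g1")
})

test_that("validation orders candidate sets above non-candidates", {
  g <- small_gem()
  informative <- small_informative()
  noise <- setdiff(rownames(g$values), informative)[1:6]
  val <- validate_decomposition(g, candidates = informative[1:6],
                                non_candidates = noise,
                                n_random = 4, folds = 3, n_trees = 50,
                                seed = 6L)
  expect_setequal(val$set, c("full", "candidates", "non_candidates"))
  expect_gt(val$delta_accuracy[val$set == "candidates"],
            val$delta_accuracy[val$set == "non_candidates"])

  # candidates = full set gives an identical report row
  val2 <- validate_decomposition(g, candidates = informative[1:6],
                                 non_candidates = character(0),
                                 n_random = 3, folds = 3, seed = 6L)
  expect_equal(val2$accuracy[val2$set == "full"],
               val2$accuracy[val2$set == "candidates"])
  expect_equal(val2$random_mean[val2$set == "full"],
               val2$random_mean[val2$set == "candidates"])
  expect_false("non_candidates" %in% val2$set)
})
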