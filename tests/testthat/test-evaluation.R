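test_that("pair errors are counted by decomposing clusters into pairs", {
  # {1,2,3} against reference {1,2},{3}: pairs 1-2 correct, 1-3 and 2-3 not
  pe <- count_pair_errors(c(a = 1, b = 1, c = 1), c(a = 1, b = 1, c = 2))
  expect_equal(pe, list(correct = 1, incorrect = 2, total = 3))
  # all singletons contribute no pairs at all
  pe0 <- count_pair_errors(1:5, rep(1, 5))
  expect_equal(pe0$total, 0)
  expect_equal(pe0$incorrect, 0)
  # a partition is perfectly correct against itself
  set.seed(51)
  p <- sample(4, 30, replace = TRUE)
  pe_id <- count_pair_errors(p, p)
  expect_equal(pe_id$incorrect, 0)
  expect_equal(pe_id$correct, pe_id$total)
})

test_that("pair counts are conserved: correct + incorrect = total pairs", {
  set.seed(52)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    p <- sample(6, n, replace = TRUE)
    ref <- sample(5, n, replace = TRUE)
    pe <- count_pair_errors(p, ref)
    total <- sum(choose(table(p), 2))
    expect_equal(pe$correct + pe$incorrect, total)
    expect_equal(pe$total, total)
  }
})

test_that("partitions are aligned by object names", {
  p <- c(a = 1, b = 1, c = 2)
  ref_shuffled <- c(c = "y", a = "x", b = "x")
  expect_equal(count_pair_errors(p, ref_shuffled)$incorrect, 0)
  expect_error(count_pair_errors(p, c(a = 1, b = 1, d = 2)),
               "same object set")
  expect_error(count_pair_errors(unname(p), c(1, 1)), "length")
})

test_that("clustering similarity is the Jaccard index of pair sets", {
  expect_equal(clustering_similarity(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  # {1,2},{3,4} vs {1,2,3,4}: pair sets {12,34} vs all six pairs
  expect_equal(clustering_similarity(c(1, 1, 2, 2), rep(1, 4)), 2 / 6)
  # disjoint non-empty pair sets
  expect_equal(clustering_similarity(c(1, 1, 2, 2), c(1, 2, 2, 1)), 0)
  # symmetry
  set.seed(53)
  p1 <- sample(3, 20, replace = TRUE)
  p2 <- sample(4, 20, replace = TRUE)
  expect_equal(clustering_similarity(p1, p2),
               clustering_similarity(p2, p1))
  expect_error(clustering_similarity(p1, p2, metric = "cosine"))
})

test_that("Rand variants agree with an independent implementation", {
  set.seed(54)
  for (rep in 1:10) {
    p1 <- sample(4, 25, replace = TRUE)
    p2 <- sample(3, 25, replace = TRUE)
    expect_equal(clustering_similarity(p1, p2, metric = "adjusted_rand"),
                 mclust::adjustedRandIndex(p1, p2))
  }
  expect_equal(clustering_similarity(1:4, 1:4, metric = "rand"), 1)
  expect_equal(clustering_similarity(1:4, 1:4, metric = "adjusted_rand"), 1)
})

test_that("size histograms bucket clusters of size 1..5 and >5", {
  expect_equal(size_histogram(1:7),
               c("1" = 7L, "2" = 0L, "3" = 0L, "4" = 0L, "5" = 0L,
                 ">5" = 0L))
  fx_ic <- independent_clusters(scg_a2(scg_trace_fixture()))
  expect_equal(unname(size_histogram(fx_ic)),
               c(0L, 0L, 1L, 1L, 0L, 0L))
  # objects are conserved across buckets
  set.seed(55)
  p <- sample(8, 60, replace = TRUE)
  h <- size_histogram(p)
  sizes <- table(p)
  expect_equal(sum((1:5) * h[1:5]) + sum(sizes[sizes > 5]), 60)
})

test_that("the evaluation report combines counts, percentages and the
           histogram", {
  rep_ <- evaluation_report(c(a = 1, b = 1, c = 1), c(a = 1, b = 1, c = 2))
  expect_equal(rep_$n_clusters, 1)
  expect_equal(rep_$n_non_singleton, 1)
  expect_equal(rep_$incorrect_pairs, 2)
  expect_equal(rep_$percent_correct + rep_$percent_incorrect, 100)
  expect_equal(unname(rep_$size_histogram["3"]), 1L)
  out <- capture.output(print(rep_))
  expect_true(any(grepl("incorrect pairs", out)))
  # no pairs: percentages are undefined, not zero
  rep0 <- evaluation_report(c(a = 1, b = 2), c(a = 1, b = 1))
  expect_true(is.na(rep0$percent_correct))
})
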