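test_that("ranks of collinear points follow hand-sorted distances", {
  D <- as.matrix(dist(c(0, 1, 3)))
  rm <- scg_rank_matrix(D)
  # point at 0: self, then the point at 1, then the point at 3
  expect_equal(rm$rmatrix[1, ], c(1L, 2L, 3L))
  # point at 1: self, then 0 (d=1), then 3 (d=2)
  expect_equal(rm$rmatrix[2, ], c(2L, 1L, 3L))
  expect_equal(rm$smatrix[2, ], c(2L, 1L, 3L))
})

test_that("a single object yields the only possible permutation", {
  rm <- scg_rank_matrix(matrix(0, 1, 1))
  expect_equal(rm$rmatrix, matrix(1L, 1, 1))
  expect_equal(rm$smatrix, matrix(1L, 1, 1))
})

test_that("every output row is a permutation with diagonal 1 and a
           consistent inverse", {
  set.seed(11)
  for (n in c(2, 3, 7, 15)) {
    m <- matrix(runif(n * n), n, n)
    diag(m) <- 0
    rm <- scg_rank_matrix(m)
    for (i in seq_len(n)) {
      expect_setequal(rm$rmatrix[i, ], seq_len(n))
      expect_identical(rm$rmatrix[i, i], 1L)
      expect_identical(rm$smatrix[i, 1], i)
      expect_identical(rm$smatrix[i, rm$rmatrix[i, ]], seq_len(n))
    }
  }
})

test_that("ranks are invariant under strictly monotone distance
           transforms", {
  set.seed(12)
  pts <- matrix(rnorm(20), 10, 2)
  D <- as.matrix(dist(pts))
  rm0 <- scg_rank_matrix(D)
  expect_identical(scg_rank_matrix(D^3)$rmatrix, rm0$rmatrix)
  expect_identical(scg_rank_matrix(exp(D))$rmatrix, rm0$rmatrix)
  # similarity orientation with a decreasing transform gives the same order
  expect_identical(scg_rank_matrix(-D, orientation = "similarity")$rmatrix,
                   rm0$rmatrix)
  expect_identical(scg_rank_matrix(1 / (1 + D),
                                   orientation = "similarity")$rmatrix,
                   rm0$rmatrix)
})

test_that("ties are broken by ascending object id, self always first", {
  m <- matrix(1, 4, 4)  # all distances equal
  diag(m) <- 0
  rm <- scg_rank_matrix(m)
  expect_equal(rm$smatrix[3, ], c(3L, 1L, 2L, 4L))
  # a tied self-distance still puts self at rank 1
  m2 <- matrix(0, 3, 3)
  expect_equal(scg_rank_matrix(m2)$smatrix[2, ], c(2L, 1L, 3L))
})

test_that("invalid score input is rejected", {
  expect_error(scg_rank_matrix(matrix(0, 2, 3)), "square")
  m <- matrix(c(0, NA, 1, 0), 2, 2)
  expect_error(scg_rank_matrix(m), "missing")
  expect_error(scg_rank_matrix(matrix(0, 2, 2), tie_break = "random"),
               "tie_break")
  expect_error(scg_rank_matrix(matrix(0, 2, 2),
                               labels = c("a", "a")), "unique")
})

test_that("an empty pair list densifies to ranks fixed by the tie rule", {
  m <- densify_pair_scores(data.frame(id1 = character(),
                                      id2 = character(),
                                      score = numeric()),
                           labels = c("a", "b", "c"))
  rm <- scg_rank_matrix(m, orientation = "similarity")
  expect_equal(rm$smatrix[1, ], c(1L, 2L, 3L))
  expect_equal(rm$smatrix[3, ], c(3L, 1L, 2L))
})

test_that("a single observed similarity outranks all absent pairs", {
  m <- densify_pair_scores(data.frame(id1 = "a", id2 = "b", score = 5),
                           labels = c("a", "b", "c"))
  rm <- scg_rank_matrix(m, orientation = "similarity")
  expect_equal(rm$rmatrix[1, 2], 2L)  # b is rank 2 in row a
  expect_equal(rm$rmatrix[1, 3], 3L)  # c is rank 3 in row a
})

test_that("a symmetric full pair list round-trips to the direct matrix", {
  set.seed(13)
  labs <- letters[1:5]
  sim <- matrix(runif(25, 1, 10), 5, 5, dimnames = list(labs, labs))
  sim <- (sim + t(sim)) / 2
  diag(sim) <- 100
  idx <- which(upper.tri(sim), arr.ind = TRUE)
  pairs <- data.frame(id1 = labs[idx[, 1]], id2 = labs[idx[, 2]],
                      score = sim[idx])
  pairs <- rbind(pairs, data.frame(id1 = pairs$id2, id2 = pairs$id1,
                                   score = pairs$score))
  dense <- densify_pair_scores(pairs, labels = labs)
  expect_identical(scg_rank_matrix(dense, orientation = "similarity")$rmatrix,
                   scg_rank_matrix(sim, orientation = "similarity")$rmatrix)
})

test_that("duplicate pair records keep the better score and can be made
           strict", {
  pairs <- data.frame(id1 = c("a", "a"), id2 = c("b", "b"),
                      score = c(3, 7))
  expect_warning(m <- densify_pair_scores(pairs, labels = c("a", "b", "c")),
                 "better score")
  expect_equal(m["a", "b"], 7)
  expect_error(
    suppressWarnings(densify_pair_scores(pairs, labels = c("a", "b", "c"),
                                         duplicates = "error")),
    "conflicting")
  expect_error(densify_pair_scores(data.frame(id1 = "a", id2 = "z",
                                              score = 1),
                                   labels = c("a", "b")), "unknown")
})

test_that("one-directional scores are preserved asymmetrically when
           mirroring is off", {
  pairs <- data.frame(id1 = c("a", "b"), id2 = c("b", "a"),
                      score = c(5, 2))
  m <- densify_pair_scores(pairs, labels = c("a", "b"))
  expect_equal(m["a", "b"], 5)
  expect_equal(m["b", "a"], 2)
})
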