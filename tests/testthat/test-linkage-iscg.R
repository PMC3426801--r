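test_that("linkage cutoff mode follows the merge criterion", {
  D2 <- as.matrix(dist(c(0, 1)))
  expect_equal(unname(linkage_partition(D2, "complete", cutoff = 2)),
               c(1L, 1L))
  # chaining: single linkage bridges 0-1.5-3; complete linkage cannot
  D3 <- as.matrix(dist(c(0, 1.5, 3)))
  expect_equal(unname(linkage_partition(D3, "single", cutoff = 2)),
               c(1L, 1L, 1L))
  cl <- linkage_partition(D3, "complete", cutoff = 2)
  expect_true(same_grouping(cl, c(1, 1, 2)))
})

test_that("n-cluster mode returns exactly K groups", {
  set.seed(41)
  D <- as.matrix(dist(matrix(runif(30), 15, 2)))
  for (k in c(1, 4, 15)) {
    p <- linkage_partition(D, "average", k = k)
    expect_equal(length(unique(p)), k)
  }
  expect_error(linkage_partition(D, "average", k = 16), "1..n")
  expect_error(linkage_partition(D, "average"), "exactly one")
  expect_error(linkage_partition(D, "average", cutoff = 1, k = 2),
               "exactly one")
  A <- D; A[1, 2] <- A[1, 2] + 1
  expect_error(linkage_partition(A, "single", cutoff = 1), "symmetric")
})

test_that("complete-linkage clusters under a cutoff have diameter at most
           the cutoff", {
  set.seed(42)
  for (rep in 1:5) {
    D <- as.matrix(dist(matrix(runif(40), 20, 2)))
    delta <- runif(1, 0.1, 0.8)
    p <- linkage_partition(D, "complete", cutoff = delta)
    for (g in unique(p)) {
      m <- which(p == g)
      if (length(m) > 1) expect_lte(max(D[m, m]), delta)
    }
  }
})

test_that("a single SCG pass equals iterative SCG with max_iter = 1", {
  set.seed(43)
  pts <- matrix(rnorm(30), 15, 2)
  D <- as.matrix(dist(pts))
  expect_equal(family_of(iscg(D, "min", max_iter = 1)),
               family_of(scg_a3(scg_rank_matrix(D))))
})

test_that("collapsed super-objects merge groups a single pass cannot", {
  D <- iscg_blocked_matrix()
  # single pass: the two tight pairs stay independent
  ic1 <- independent_clusters(scg_a3(scg_rank_matrix(D)))
  expect_true(same_grouping(ic1, c(1, 1, 2, 2, 3, 4)))
  # brute-force oracle on the collapsed min-distance matrix confirms
  # that the two super-objects form a cluster at the second level
  groups <- list(c(1, 2), c(3, 4), 5, 6)
  Dg <- matrix(0, 4, 4)
  for (a in 1:3) for (b in (a + 1):4) {
    Dg[a, b] <- Dg[b, a] <- min(D[groups[[a]], groups[[b]]])
  }
  fam_g <- enumerate_all_clusters(scg_rank_matrix(Dg))
  expect_true(any(vapply(fam_g, identical, TRUE, y = c(1L, 2L))))
  # iSCG(min) therefore merges {1,2} and {3,4} in iteration 2
  f2 <- iscg(D, "min", max_iter = 2)
  expect_true(same_grouping(independent_clusters(f2),
                            c(1, 1, 1, 1, 2, 3)))
  # with the nested pair structure preserved
  expect_true(any(vapply(family_of(f2), identical, TRUE,
                         y = c(1L, 2L, 3L, 4L))))
  expect_true(any(vapply(family_of(f2), identical, TRUE, y = c(1L, 2L))))
  # unconstrained, min-linkage chaining pulls in object 5 one level later
  f <- iscg(D, "min", max_iter = 9)
  expect_equal(attr(f, "iterations"), 3L)
  expect_true(same_grouping(independent_clusters(f),
                            c(1, 1, 1, 1, 1, 2)))
})

test_that("iteration reaches a fixed point and membership is monotone", {
  D <- iscg_blocked_matrix()
  f3 <- iscg(D, "min", max_iter = 3)
  f9 <- iscg(D, "min", max_iter = 9)
  expect_equal(family_of(f3), family_of(f9))  # nothing new after iter 3
  # groups only grow across iteration budgets
  parts <- lapply(1:3, function(k)
    independent_clusters(iscg(D, "min", max_iter = k)))
  for (k in 2:3) {
    tab <- table(parts[[k - 1]], parts[[k]])
    expect_true(all(rowSums(tab > 0) == 1))  # old groups map whole
  }
})

test_that("the min strategy never refines the single-pass partition", {
  set.seed(44)
  for (rep in 1:5) {
    D <- as.matrix(dist(matrix(runif(24, 0, 4), 12, 2)))
    p1 <- independent_clusters(scg_a3(scg_rank_matrix(D)))
    p2 <- independent_clusters(iscg(D, "min", max_iter = 4))
    tab <- table(p1, p2)
    expect_true(all(rowSums(tab > 0) == 1))
  }
})

test_that("the three update strategies and both average variants run and
           respect orientation", {
  D <- iscg_blocked_matrix()
  for (s in c("min", "avg", "max")) {
    f <- iscg(D, s, max_iter = 3)
    expect_s3_class(f, "scg_forest")
    expect_silent(scgclust:::validate_forest(f))
  }
  expect_equal(family_of(iscg(-D, "min", orientation = "similarity",
                              max_iter = 5)),
               family_of(iscg(D, "min", max_iter = 5)))
  f_g <- iscg(D, "avg", avg_update = "groups", max_iter = 3)
  expect_silent(scgclust:::validate_forest(f_g))
  expect_error(iscg(D, "min", max_iter = 0), "max_iter")
})
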