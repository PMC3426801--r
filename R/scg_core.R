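# The self-consistency cluster test, candidate indices, and the three
# SCG algorithms.
#
# A set S of k objects is a cluster iff k < n and rank(x, y) <= k for
# every ordered pair (x, y) in S. The algorithms differ only in how they
# schedule candidate sets (always the first k entries of an smatrix row):
#   a1 - sweep cluster sizes 2..n, testing every object's prefix;
#   a2 - per object, jump straight to the candidate index after each
#        failure ("SCG-fast": finds all independent clusters only);
#   a3 - global scheduler that always examines objects whose candidate
#        index is minimal, recovering the complete structure like a1 at
#        a fraction of the tests.

# Fast unvalidated cluster test used in inner loops.
.is_cluster <- function(members, rmatrix, n) {
  k <- length(members)
  if (k >= n) return(FALSE)
  if (k == 1L) return(TRUE)
  max(rmatrix[members, members]) <= k
}

#' The self-consistency cluster test
#'
#' A set of `k` objects forms a cluster when the rank of any member with
#' respect to any other member is at most `k` — every member counts all
#' the others among its `k` nearest objects. The test is symmetric even
#' though ranks are not. A cluster of size `n` (the whole object set) is
#' disallowed; singletons are trivially clusters.
#'
#' @param members Integer object ids, or labels.
#' @param rm An [scg_rank_matrix()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' fx <- scg_trace_fixture()
#' is_cluster(c(3, 4), fx)  # TRUE: mutual rank-2 neighbours
#' is_cluster(c(5, 6), fx)  # FALSE: rank(6,5) = 3 > 2
#' @export
is_cluster <- function(members, rm) {
  members <- resolve_members(members, rm)
  .is_cluster(members, rm$rmatrix, rm$n)
}

#' Candidate index of a set
#'
#' The maximum pairwise rank within the set: the minimum size any cluster
#' containing the set must have. Equals the set size exactly when the set
#' is a cluster (for sets smaller than `n`).
#'
#' @inheritParams is_cluster
#' @return Integer scalar (1 for a singleton).
#' @examples
#' candidate_index(c(1, 4), scg_trace_fixture())  # 4: rank(4,1) = 4
#' @export
candidate_index <- function(members, rm) {
  members <- resolve_members(members, rm)
  if (length(members) == 1L) return(1L)
  max(rm$rmatrix[members, members])
}

resolve_members <- function(members, rm) {
  if (is.character(members)) {
    idx <- match(members, rm$labels)
    if (anyNA(idx)) stop("unknown object labels: ",
                         paste(members[is.na(idx)], collapse = ", "))
    members <- idx
  }
  members <- unique(as.integer(members))
  if (!length(members)) stop("empty member set")
  if (any(members < 1L | members > rm$n)) {
    stop("member ids out of range 1..", rm$n)
  }
  members
}

# Shared bookkeeping for examination counters: named integer vector
# indexed by candidate size "2".."n".
new_exam_counter <- function(n) {
  cnt <- integer(max(n - 1L, 0L))
  if (n >= 2L) names(cnt) <- as.character(2:n)
  cnt
}

#' SCG by direct size sweep (algorithm A1)
#'
#' For every cluster size `f = 2..n` in turn, tests for each object still
#' valid in the iteration whether the `f` nearest objects (the first `f`
#' entries of its `smatrix` row, itself included) form a cluster. Formed
#' clusters become forest nodes and their members are skipped for the
#' rest of the size-`f` sweep. Because sizes are examined smallest first,
#' the complete subcluster structure is recovered.
#'
#' @param rm An [scg_rank_matrix()].
#' @return An [scg_forest()] whose roots are the independent clusters.
#'   Attribute `"examinations"` counts the cluster tests performed per
#'   candidate size.
#' @examples
#' to_newick(scg_a1(scg_trace_fixture()))
#' @export
scg_a1 <- function(rm) {
  validate_rank_matrix(rm)
  n <- rm$n
  forest <- scg_forest(rm$labels)
  exams <- new_exam_counter(n)
  rmat <- rm$rmatrix
  smat <- rm$smatrix
  if (n < 2L) {
    attr(forest, "examinations") <- exams
    return(forest)
  }
  for (f in 2:n) {
    valid <- rep(TRUE, n)
    for (o in seq_len(n)) {
      if (!valid[o]) next
      S <- smat[o, seq_len(f)]
      exams[f - 1L] <- exams[f - 1L] + 1L
      if (.is_cluster(S, rmat, n)) {
        forest <- merge_cluster(forest, S)
        valid[S] <- FALSE
      }
    }
  }
  attr(forest, "examinations") <- exams
  forest
}

#' SCG-fast (algorithm A2): all independent clusters
#'
#' Examines objects one at a time. For object `o` the candidate set is
#' the first `i` entries of its `smatrix` row, starting at `i = 2`. A
#' failed test jumps `i` straight to the candidate index of the failed
#' set (no smaller superset can be a cluster); a successful test records
#' the cluster and increments `i`. The row stops when an already-invalid
#' object enters the candidate set, when the candidate index reaches `n`,
#' or at the end of the row; the largest cluster found (possibly the
#' singleton `{o}`) is then retired. Guaranteed to find every independent
#' cluster, but not the complete subcluster structure, and the structure
#' it does find can depend on `order`.
#'
#' @param rm An [scg_rank_matrix()].
#' @param order Permutation of `1..n` giving the object examination
#'   order; default ascending id. The independent clusters do not depend
#'   on it.
#' @return An [scg_forest()]; its roots are exactly the independent
#'   clusters (use [independent_clusters()]), its internal structure is
#'   whatever was found incidentally. Attribute `"examinations"` counts
#'   candidate clusters examined per size; a test whose candidate index
#'   equals `n` retires the object and is not counted.
#' @examples
#' independent_clusters(scg_a2(scg_trace_fixture()))
#' @export
scg_a2 <- function(rm, order = NULL) {
  validate_rank_matrix(rm)
  n <- rm$n
  if (is.null(order)) order <- seq_len(n)
  order <- as.integer(order)
  if (!identical(sort(order), seq_len(n))) {
    stop("`order` must be a permutation of 1..n")
  }
  forest <- scg_forest(rm$labels)
  exams <- new_exam_counter(n)
  rmat <- rm$rmatrix
  smat <- rm$smatrix
  invalid <- rep(FALSE, n)
  for (o in order) {
    if (invalid[o]) next
    i <- 2L
    largest <- o  # largest cluster found in this row; singleton {o} if none
    while (i <= n) {
      S <- smat[o, seq_len(i)]
      if (any(invalid[S])) break
      if (.is_cluster(S, rmat, n)) {
        exams[i - 1L] <- exams[i - 1L] + 1L
        forest <- merge_cluster(forest, S)
        largest <- S
        i <- i + 1L
      } else {
        ci <- max(rmat[S, S])
        if (ci >= n) break  # no cluster can contain this candidate set
        exams[i - 1L] <- exams[i - 1L] + 1L
        i <- ci
      }
    }
    invalid[largest] <- TRUE
  }
  attr(forest, "examinations") <- exams
  forest
}

#' SCG by minimum candidate index (algorithm A3)
#'
#' Every object carries an index, initially 2: the size of the smallest
#' cluster that could still contain it as nearest-neighbour prefix. The
#' scheduler repeatedly examines (in ascending id) every valid object
#' whose index equals the current global minimum. A success merges the
#' cluster, increments the members' indices and suspends them for the
#' remainder of the sweep; a failure raises the object's index to the
#' candidate index of the failed set. An object whose candidate index
#' reaches `n` is retired permanently (such a test is not counted in the
#' examination totals). Because candidate sets are examined in
#' non-decreasing size order, subclusters always form before their
#' enclosing clusters and the complete structure is recovered — the
#' output forest is identical to [scg_a1()]'s.
#'
#' @param rm An [scg_rank_matrix()].
#' @return An [scg_forest()] with attribute `"examinations"` (tests per
#'   candidate size).
#' @examples
#' to_newick(scg_a3(scg_trace_fixture()))
#' @export
scg_a3 <- function(rm) {
  validate_rank_matrix(rm)
  n <- rm$n
  forest <- scg_forest(rm$labels)
  exams <- new_exam_counter(n)
  rmat <- rm$rmatrix
  smat <- rm$smatrix
  if (n < 2L) {
    attr(forest, "examinations") <- exams
    return(forest)
  }
  index <- rep(2L, n)
  retired <- rep(FALSE, n)
  if (n == 2L) retired[] <- TRUE  # size-2 set would be size n
  while (!all(retired)) {
    active <- which(!retired)
    m <- min(index[active])
    sweep_invalid <- rep(FALSE, n)
    for (o in active) {
      if (retired[o] || sweep_invalid[o] || index[o] != m) next
      S <- smat[o, seq_len(m)]
      if (.is_cluster(S, rmat, n)) {
        exams[m - 1L] <- exams[m - 1L] + 1L
        forest <- merge_cluster(forest, S)
        index[S] <- index[S] + 1L
        sweep_invalid[S] <- TRUE
      } else {
        ci <- max(rmat[S, S])
        if (ci >= n) {
          retired[o] <- TRUE
        } else {
          exams[m - 1L] <- exams[m - 1L] + 1L
          index[o] <- ci
        }
      }
    }
    if (any(index[!retired] >= n)) retired[index >= n] <- TRUE
  }
  attr(forest, "examinations") <- exams
  forest
}

#' Exhaustively enumerate all clusters (brute-force oracle)
#'
#' Tests every subset of size `2..n-1` with [is_cluster()]. Intended as
#' an independent oracle for small problems: the returned family plus
#' singletons is laminar, its maximal elements are the independent
#' clusters, and building a forest from it reproduces the
#' [scg_a1()]/[scg_a3()] output.
#'
#' @param rm An [scg_rank_matrix()].
#' @param max_n Refuse inputs larger than this (default 15): the cost is
#'   exponential in `n`.
#' @return List of sorted integer member vectors, ordered by smallest
#'   member then size.
#' @export
enumerate_all_clusters <- function(rm, max_n = 15L) {
  validate_rank_matrix(rm)
  n <- rm$n
  if (n > max_n) {
    stop("n = ", n, " exceeds max_n = ", max_n,
         "; brute-force enumeration is exponential")
  }
  rmat <- rm$rmatrix
  out <- list()
  if (n >= 3L) {
    for (k in 2:(n - 1L)) {
      combs <- utils::combn(n, k)
      for (j in seq_len(ncol(combs))) {
        S <- combs[, j]
        if (max(rmat[S, S]) <= k) out[[length(out) + 1L]] <- S
      }
    }
  } else if (n == 2L) {
    # only subsets of size 2..n-1 exist for n >= 3; nothing to test here
  }
  out[order(vapply(out, min, 0L), lengths(out))]
}

# Build a forest from an explicit laminar cluster family (used to turn
# the brute-force enumeration into a forest for comparison).
forest_from_clusters <- function(clusters, labels) {
  forest <- scg_forest(labels)
  for (S in clusters[order(lengths(clusters))]) {
    forest <- merge_cluster(forest, S)
  }
  forest
}
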