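# Rank-matrix construction: the sole input consumed by the SCG algorithms.

#' Build the asymmetric rank matrix from a score matrix
#'
#' The rank of object `y` with respect to object `x` is `p` when `p - 1`
#' objects (including `x` itself) are at least as similar to `x` as `y` is.
#' Each row of the resulting rank matrix is therefore a permutation of
#' `1..n` with `rank(x, x) = 1`: every object is most similar to itself.
#' The companion `smatrix` is the row-wise inverse permutation; row `i`
#' lists the objects in increasing rank to `i`.
#'
#' Ranks depend only on the ordering of the scores within each row, so any
#' strictly monotone transformation of the scores leaves the result
#' unchanged. Asymmetric score matrices are accepted as-is: the rank
#' definition is itself asymmetric.
#'
#' @param scores Square numeric matrix of pairwise scores (a `dist` object
#'   is accepted and expanded). Rows are the reference objects: entry
#'   `[i, j]` scores object `j` relative to object `i`.
#' @param orientation `"distance"` (smaller is more similar, the default)
#'   or `"similarity"` (larger is more similar).
#' @param labels Optional character vector of object labels; defaults to
#'   the matrix dimnames, or `1..n` as character.
#' @param tie_break Tie policy. `"id"` (the only policy) breaks equal
#'   scores by ascending object id, deterministically. The self object is
#'   always rank 1 even under ties.
#'
#' @return An object of class `scg_rank_matrix`: a list with integer
#'   matrices `rmatrix` (ranks) and `smatrix` (row-wise inverse: objects
#'   ordered by rank), `labels`, and `n`.
#'
#' @examples
#' pts <- c(0, 1, 3)  # three collinear points
#' D <- as.matrix(dist(pts))
#' rm <- scg_rank_matrix(D)
#' rm$rmatrix[1, ]  # self = 1, point at 1 = 2, point at 3 = 3
#' @export
scg_rank_matrix <- function(scores,
                            orientation = c("distance", "similarity"),
                            labels = NULL,
                            tie_break = "id") {
  orientation <- match.arg(orientation)
  if (!identical(tie_break, "id")) {
    stop("unknown tie_break policy: ", tie_break)
  }
  if (inherits(scores, "dist")) scores <- as.matrix(scores)
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("`scores` must be a numeric matrix")
  }
  n <- nrow(scores)
  if (ncol(scores) != n) {
    stop("`scores` must be square; got ", n, " x ", ncol(scores))
  }
  if (n < 1L) stop("need at least one object")
  if (is.null(labels)) {
    labels <- rownames(scores)
    if (is.null(labels)) labels <- as.character(seq_len(n))
  }
  if (length(labels) != n) stop("`labels` length must equal nrow(scores)")
  if (anyDuplicated(labels)) stop("object labels must be unique")

  off_diag <- scores[row(scores) != col(scores)]
  if (any(is.na(off_diag)) || any(!is.finite(off_diag) & !is.na(off_diag) &
                                  abs(off_diag) != Inf)) {
    stop("scores contain missing values; densify sparse input first")
  }
  if (any(is.nan(off_diag))) stop("scores contain NaN")

  rmatrix <- matrix(0L, n, n)
  smatrix <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    v <- scores[i, ]
    if (orientation == "similarity") v <- -v
    v[i] <- -Inf  # self is always most similar
    ord <- order(v, seq_len(n))  # ties broken by ascending object id
    smatrix[i, ] <- ord
    rmatrix[i, ord] <- seq_len(n)
  }
  structure(
    list(rmatrix = rmatrix, smatrix = smatrix,
         labels = labels, n = n),
    class = "scg_rank_matrix"
  )
}

#' @export
print.scg_rank_matrix <- function(x, ...) {
  cat("SCG rank matrix over", x$n, "objects\n")
  if (x$n <= 12L) {
    m <- x$rmatrix
    dimnames(m) <- list(x$labels, x$labels)
    print(m)
  } else {
    cat("(rank matrix too large to print; access $rmatrix directly)\n")
  }
  invisible(x)
}

# Internal validator used by tests and by algorithm entry points.
validate_rank_matrix <- function(rm) {
  stopifnot(inherits(rm, "scg_rank_matrix"))
  n <- rm$n
  for (i in seq_len(n)) {
    r <- rm$rmatrix[i, ]
    if (!identical(sort(r), seq_len(n))) {
      stop("rmatrix row ", i, " is not a permutation of 1..n")
    }
    if (r[i] != 1L) stop("rmatrix[", i, ",", i, "] != 1")
    if (rm$smatrix[i, 1L] != i) stop("smatrix[", i, ",1] != ", i)
    if (!identical(rm$smatrix[i, r], seq_len(n))) {
      stop("smatrix row ", i, " is not the inverse permutation of rmatrix")
    }
  }
  invisible(rm)
}

# Construct an scg_rank_matrix directly from an rmatrix (integer ranks).
# Used by the trace fixture and by tests that generate synthetic rank
# matrices without an underlying geometry.
rank_matrix_from_rmatrix <- function(rmatrix, labels = NULL) {
  n <- nrow(rmatrix)
  storage.mode(rmatrix) <- "integer"
  smatrix <- matrix(0L, n, n)
  for (i in seq_len(n)) smatrix[i, rmatrix[i, ]] <- seq_len(n)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  validate_rank_matrix(structure(
    list(rmatrix = rmatrix, smatrix = smatrix, labels = labels, n = n),
    class = "scg_rank_matrix"
  ))
}

#' Densify a sparse pairwise score list into a full score matrix
#'
#' Sparse all-against-all comparisons (e.g. structural-alignment Z-score
#' lists of the form `id1 id2 score`) usually omit pairs below a reporting
#' threshold. Absent pairs are filled with a value strictly worse than
#' every observed score so that they can never enter a cluster by
#' accident. Asymmetric input is preserved as-is; a pair reported in one
#' direction only is mirrored only if the opposite cell is absent and
#' `mirror = TRUE`.
#'
#' @param pairs Data frame (or matrix coercible to one) with columns
#'   `id1`, `id2`, `score` in that order.
#' @param labels Character vector fixing the object set and its order. If
#'   `NULL`, labels are collected from the pair list in first-appearance
#'   order.
#' @param orientation `"similarity"` (the typical case for score lists,
#'   the default here) or `"distance"`.
#' @param worst_policy How to fill absent pairs: `"infinite"` uses
#'   `-Inf`/`+Inf`, `"offset"` uses (min observed - 1) / (max observed + 1).
#' @param duplicates On duplicate records for the same ordered pair:
#'   `"best"` keeps the better score under the orientation and warns on
#'   conflicts; `"error"` fails on any conflicting duplicate.
#' @param mirror Mirror a one-directional score into the absent opposite
#'   cell (default `TRUE`).
#' @return A square numeric matrix with `labels` as dimnames. The
#'   diagonal holds the best possible value under the orientation.
#' @examples
#' p <- data.frame(id1 = "a", id2 = "b", score = 5)
#' densify_pair_scores(p, labels = c("a", "b", "c"))
#' @export
densify_pair_scores <- function(pairs, labels = NULL,
                                orientation = c("similarity", "distance"),
                                worst_policy = c("infinite", "offset"),
                                duplicates = c("best", "error"),
                                mirror = TRUE) {
  orientation <- match.arg(orientation)
  worst_policy <- match.arg(worst_policy)
  duplicates <- match.arg(duplicates)
  pairs <- as.data.frame(pairs)
  if (ncol(pairs) < 3L) stop("`pairs` needs columns id1, id2, score")
  id1 <- as.character(pairs[[1L]])
  id2 <- as.character(pairs[[2L]])
  score <- as.numeric(pairs[[3L]])
  if (any(!is.finite(score))) stop("pair scores must be finite")

  if (is.null(labels)) {
    labels <- unique(c(rbind(id1, id2)))
  }
  unknown <- setdiff(unique(c(id1, id2)), labels)
  if (length(unknown)) {
    stop("pair list references unknown ids: ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  n <- length(labels)
  i <- match(id1, labels)
  j <- match(id2, labels)

  better <- if (orientation == "similarity") `>` else `<`
  if (length(score)) {
    worst_obs <- if (orientation == "similarity") min(score) else max(score)
    best_obs <- if (orientation == "similarity") max(score) else min(score)
  } else {
    worst_obs <- 0
    best_obs <- 0
  }
  fill <- switch(worst_policy,
    infinite = if (orientation == "similarity") -Inf else Inf,
    offset = if (orientation == "similarity") worst_obs - 1 else worst_obs + 1
  )
  self_val <- if (orientation == "similarity") {
    if (is.finite(fill)) max(best_obs, fill) + 1 else best_obs + 1
  } else {
    min(best_obs, 0) - 1
  }

  m <- matrix(fill, n, n, dimnames = list(labels, labels))
  seen <- matrix(FALSE, n, n)
  for (k in seq_along(score)) {
    a <- i[k]; b <- j[k]
    if (a == b) next
    if (seen[a, b]) {
      if (m[a, b] != score[k]) {
        if (duplicates == "error") {
          stop("conflicting duplicate score for pair (", id1[k], ", ",
               id2[k], "): ", m[a, b], " vs ", score[k])
        }
        warning("duplicate pair (", id1[k], ", ", id2[k],
                "): keeping the better score")
        if (better(score[k], m[a, b])) m[a, b] <- score[k]
      }
    } else {
      m[a, b] <- score[k]
      seen[a, b] <- TRUE
    }
  }
  if (mirror) {
    mirror_cells <- seen & !t(seen)
    m[t(mirror_cells)] <- t(m)[t(mirror_cells)]
  }
  diag(m) <- self_val
  m
}

#' The published seven-object execution-trace rank matrix
#'
#' A fixed 7-object rank matrix used throughout the documentation and
#' tests. Running the SCG algorithms on it yields the independent
#' clusters `{1,2,3,4}` and `{5,6,7}` with subclusters `{3,4}`, `{2,3,4}`
#' and `{6,7}`, and exercises every branch of the three algorithms
#' (failed candidate tests, candidate-index jumps, permanent retirement).
#'
#' @return An `scg_rank_matrix` over objects labelled `"1".."7"`.
#' @examples
#' fx <- scg_trace_fixture()
#' independent_clusters(scg_a2(fx))
#' @export
scg_trace_fixture <- function() {
  rmatrix <- rbind(
    c(1L, 4L, 3L, 2L, 7L, 5L, 6L),
    c(4L, 1L, 2L, 3L, 5L, 7L, 6L),
    c(4L, 3L, 1L, 2L, 7L, 5L, 6L),
    c(4L, 3L, 2L, 1L, 6L, 7L, 5L),
    c(4L, 7L, 5L, 6L, 1L, 2L, 3L),
    c(5L, 4L, 6L, 7L, 3L, 1L, 2L),
    c(7L, 5L, 4L, 6L, 3L, 2L, 1L)
  )
  rank_matrix_from_rmatrix(rmatrix)
}
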