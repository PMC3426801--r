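# Agglomerative linkage baselines (single / complete / average), driven
# by stats::hclust. Complete linkage in cutoff mode merges two groups
# only while the maximum cross-pair distance is at most the cutoff,
# which is exactly the tree cut at height delta.

#' Flat partition from agglomerative linkage clustering
#'
#' Standard single, complete or average linkage over a symmetric distance
#' matrix, cut either at a distance cutoff `delta` (groups are merged
#' while the method-specific linkage distance is at most `delta`) or into
#' exactly `k` groups. Singletons count as clusters.
#'
#' @param scores Symmetric numeric distance matrix (or `dist`).
#'   Similarities must be converted to distances upstream.
#' @param method `"single"`, `"complete"` or `"average"`.
#' @param cutoff Distance cutoff `delta > 0` (exclusive with `k`).
#' @param k Desired number of clusters in `1..n` (exclusive with
#'   `cutoff`).
#' @return Named integer vector mapping object labels to group ids.
#' @examples
#' pts <- c(a = 0, b = 1.5, c = 3)
#' D <- as.matrix(dist(pts))
#' linkage_partition(D, "single", cutoff = 2)    # one chained cluster
#' linkage_partition(D, "complete", cutoff = 2)  # {a,b} and {c}
#' @export
linkage_partition <- function(scores,
                              method = c("single", "complete", "average"),
                              cutoff = NULL, k = NULL) {
  method <- match.arg(method)
  if (inherits(scores, "dist")) scores <- as.matrix(scores)
  n <- nrow(scores)
  if (ncol(scores) != n) stop("distance matrix must be square")
  if (!isTRUE(all.equal(scores, t(scores), check.attributes = FALSE))) {
    stop("linkage clustering requires a symmetric distance matrix")
  }
  if (is.null(cutoff) == is.null(k)) {
    stop("specify exactly one of `cutoff` or `k`")
  }
  labels <- rownames(scores)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  if (n == 1L) {
    g <- 1L; names(g) <- labels
    return(g)
  }
  hc <- stats::hclust(stats::as.dist(scores), method = method)
  g <- if (!is.null(cutoff)) {
    if (cutoff <= 0) stop("`cutoff` must be positive")
    stats::cutree(hc, h = cutoff)
  } else {
    if (k < 1L || k > n) stop("`k` must be in 1..n")
    stats::cutree(hc, k = k)
  }
  names(g) <- labels
  g
}

#' Iterative SCG
#'
#' Plain SCG is deliberately stringent; when a few false positives are
#' tolerable in exchange for larger clusters, SCG can be iterated. Each
#' iteration runs the complete-structure algorithm ([scg_a3()]) on the
#' current objects, collapses every independent cluster (singletons
#' included) into a super-object, recomputes inter-group distances with
#' the chosen strategy, rebuilds the rank matrix and repeats. Iteration
#' stops when no non-singleton cluster forms or after `max_iter`
#' iterations. Cluster membership is monotone: groups only grow.
#'
#' @param scores Square numeric score matrix.
#' @param strategy Inter-group distance update: `"min"` (most similar
#'   cross pair, single-linkage-like), `"avg"` (mean, average-linkage-
#'   like) or `"max"` (most distant cross pair, complete-linkage-like).
#' @param max_iter Maximum number of SCG passes (default 10).
#' @param orientation `"distance"` or `"similarity"`; similarities are
#'   negated on entry.
#' @param avg_update For `strategy = "avg"` only: `"pairs"` (default)
#'   recomputes each inter-group distance as the simple arithmetic mean
#'   over all original-object cross pairs; `"groups"` averages the
#'   previous iteration's super-object distances instead (each sub-group
#'   pair counted once, regardless of size). The two coincide in the
#'   first iteration.
#' @return An [scg_forest()] over the original objects in which each
#'   iteration's structure is nested inside the next. Attribute
#'   `"iterations"` gives the number of passes that formed at least one
#'   cluster.
#' @export
iscg <- function(scores, strategy = c("min", "avg", "max"),
                 max_iter = 10L,
                 orientation = c("distance", "similarity"),
                 avg_update = c("pairs", "groups")) {
  strategy <- match.arg(strategy)
  orientation <- match.arg(orientation)
  avg_update <- match.arg(avg_update)
  if (max_iter < 1L) stop("`max_iter` must be at least 1")
  if (inherits(scores, "dist")) scores <- as.matrix(scores)
  n <- nrow(scores)
  if (ncol(scores) != n) stop("score matrix must be square")
  labels <- rownames(scores)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  D <- if (orientation == "similarity") -scores else scores

  forest <- scg_forest(labels)
  groups <- as.list(seq_len(n))  # original members of each super-object
  Dcur <- D                      # current super-object distances
  iterations <- 0L

  for (iter in seq_len(max_iter)) {
    m <- length(groups)
    if (m < 3L) break  # no non-singleton cluster is possible (size-n ban)
    rm_g <- scg_rank_matrix(Dcur, labels = as.character(seq_len(m)))
    f_g <- scg_a3(rm_g)
    fam <- cluster_family(f_g)
    if (!length(fam)) break
    iterations <- iter
    for (S in fam[order(lengths(fam))]) {
      forest <- merge_cluster(forest, unlist(groups[S]))
    }
    ic <- independent_clusters(f_g)
    parts <- unname(split(seq_len(m), ic))
    new_groups <- lapply(parts, function(idx) sort(unlist(groups[idx])))
    Dcur <- collapse_distances(Dcur, D, parts, new_groups,
                               strategy, avg_update)
    groups <- new_groups
  }
  attr(forest, "iterations") <- iterations
  forest
}

# Inter-group distance update after collapsing independent clusters.
# `parts` indexes the previous level's super-objects, `new_groups` the
# original objects. min/max are identical whichever level they are taken
# over; "avg" follows `avg_update`.
collapse_distances <- function(Dcur, D, parts, new_groups,
                               strategy, avg_update) {
  m <- length(parts)
  f <- switch(strategy, min = min, max = max, avg = mean)
  over_pairs <- strategy != "avg" || avg_update == "pairs"
  Dg <- matrix(0, m, m)
  for (a in seq_len(m - 1L)) {
    for (b in (a + 1L):m) {
      cross <- if (over_pairs) {
        D[new_groups[[a]], new_groups[[b]], drop = FALSE]
      } else {
        Dcur[parts[[a]], parts[[b]], drop = FALSE]
      }
      Dg[a, b] <- Dg[b, a] <- f(cross)
    }
  }
  Dg
}
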