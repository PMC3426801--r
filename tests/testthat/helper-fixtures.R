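# Generators and oracles shared across the test files.

# Random valid rank matrix with no underlying geometry: each smatrix row
# is a random permutation with the object itself first.
random_rank_matrix <- function(n) {
  rmatrix <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    ord <- c(i, sample(setdiff(seq_len(n), i)))
    rmatrix[i, ord] <- seq_len(n)
  }
  scgclust:::rank_matrix_from_rmatrix(rmatrix)
}

# Rank matrix derived from random planar points under Euclidean distance.
random_planar_rank_matrix <- function(n, spread = 10) {
  pts <- matrix(stats::runif(2 * n, 0, spread), n, 2)
  scg_rank_matrix(as.matrix(stats::dist(pts)))
}

# Canonical family of non-singleton member sets of a forest, for
# comparing clustering structures.
family_of <- function(forest) scgclust:::cluster_family(forest)

# Maximal elements (not contained in any other set) of a cluster list.
maximal_sets <- function(clusters) {
  keep <- vapply(seq_along(clusters), function(i) {
    !any(vapply(seq_along(clusters), function(j) {
      i != j && all(clusters[[i]] %in% clusters[[j]])
    }, TRUE))
  }, TRUE)
  clusters[keep]
}

# Partition (named integer) from a list of member-id sets over n objects;
# uncovered objects become singletons.
partition_from_sets <- function(sets, labels) {
  n <- length(labels)
  g <- integer(n)
  for (k in seq_along(sets)) g[sets[[k]]] <- k
  nxt <- length(sets)
  for (i in which(g == 0L)) {
    nxt <- nxt + 1L
    g[i] <- nxt
  }
  names(g) <- labels
  g
}

# Two partitions describe the same grouping (up to group relabelling).
same_grouping <- function(p1, p2) {
  isTRUE(clustering_similarity(p1, p2) == 1)
}

# Six-object distance matrix in which {1,2} and {3,4} are tight pairs
# whose merge into {1,2,3,4} is blocked in a single SCG pass by object 5
# sitting between them in object 2's ranking, while the collapsed
# super-objects become mutual nearest neighbours. Objects 5 and 6 stay
# singletons throughout.
iscg_blocked_matrix <- function() {
  D <- matrix(0, 6, 6)
  set_d <- function(i, j, v) D[i, j] <<- D[j, i] <<- v
  set_d(1, 2, 1);    set_d(3, 4, 1.2);  set_d(5, 6, 12)
  set_d(1, 3, 9);    set_d(1, 4, 9.2);  set_d(2, 3, 9.1); set_d(2, 4, 10)
  set_d(2, 5, 9.5);  set_d(1, 5, 15);   set_d(3, 5, 15.5); set_d(4, 5, 16)
  set_d(1, 6, 20);   set_d(2, 6, 21);   set_d(3, 6, 22);  set_d(4, 6, 23)
  dimnames(D) <- list(as.character(1:6), as.character(1:6))
  D
}
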