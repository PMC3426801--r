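# Pair-based evaluation of a clustering against a reference partition,
# plus inter-clustering similarity and cluster-size histograms.
#
# Every cluster is decomposed into its unordered member pairs (a cluster
# {1,2,3} yields 1-2, 1-3, 2-3). A pair is incorrect when its two
# members belong to different reference groups. Singletons contribute no
# pairs, so a fully fragmented clustering has zero incorrect pairs.

# Align two partitions over the same object set; returns a list of two
# integer group vectors in a common object order.
align_partitions <- function(p1, p2,
                             arg1 = "partition", arg2 = "reference") {
  n1 <- names(p1); n2 <- names(p2)
  if (!is.null(n1) && !is.null(n2)) {
    if (length(n1) != length(n2) || !setequal(n1, n2) ||
        anyDuplicated(n1) || anyDuplicated(n2)) {
      stop("`", arg1, "` and `", arg2,
           "` must cover the same object set")
    }
    p2 <- p2[n1]
  } else if (length(p1) != length(p2)) {
    stop("`", arg1, "` and `", arg2, "` differ in length and carry no ",
         "names to align by")
  }
  list(as.integer(factor(p1)), as.integer(factor(p2)))
}

choose2 <- function(x) x * (x - 1) / 2

#' Count correct and incorrect within-cluster pairs
#'
#' Enumerates (combinatorially, without materialising pair lists) the
#' unordered within-cluster pairs of `partition`; a pair is incorrect
#' iff its members fall in different groups of `reference`.
#'
#' @param partition,reference Partitions of the same object set: vectors
#'   of group labels, named by object label (names are used to align; an
#'   unnamed pair of equal-length vectors is aligned positionally).
#' @return List with elements `correct`, `incorrect` and `total`
#'   (`correct + incorrect`).
#' @examples
#' count_pair_errors(c(a = 1, b = 1, c = 1), c(a = 1, b = 1, c = 2))
#' @export
count_pair_errors <- function(partition, reference) {
  ab <- align_partitions(partition, reference)
  tab <- table(ab[[1]], ab[[2]])
  total <- sum(choose2(rowSums(tab)))
  correct <- sum(choose2(tab))
  list(correct = correct, incorrect = total - correct, total = total)
}

#' Similarity between two clusterings
#'
#' Default metric is the Jaccard index of the two within-cluster pair
#' sets: shared pairs over pairs present in either clustering. It is
#' symmetric, lies in `[0, 1]`, and equals 1 exactly when the pair sets
#' coincide. Rand and adjusted Rand indices are available as
#' alternatives.
#'
#' @param p1,p2 Partitions over the same object set (see
#'   [count_pair_errors()] for alignment rules).
#' @param metric `"jaccard"` (default), `"rand"` or `"adjusted_rand"`.
#' @return Numeric scalar.
#' @examples
#' clustering_similarity(c(1, 1, 2, 2), c(1, 1, 1, 1))  # 2 / 6 pairs
#' @export
clustering_similarity <- function(p1, p2,
                                  metric = c("jaccard", "rand",
                                             "adjusted_rand")) {
  metric <- match.arg(metric)
  ab <- align_partitions(p1, p2, "p1", "p2")
  tab <- table(ab[[1]], ab[[2]])
  n <- sum(tab)
  a <- sum(choose2(tab))                 # pairs together in both
  pairs1 <- sum(choose2(rowSums(tab)))
  pairs2 <- sum(choose2(colSums(tab)))
  switch(metric,
    jaccard = {
      denom <- pairs1 + pairs2 - a
      if (denom == 0) 1 else a / denom   # two all-singleton partitions agree
    },
    rand = {
      total <- choose2(n)
      if (total == 0) return(1)
      (total + 2 * a - pairs1 - pairs2) / total
    },
    adjusted_rand = {
      total <- choose2(n)
      expected <- pairs1 * pairs2 / total
      max_index <- (pairs1 + pairs2) / 2
      if (max_index == expected) return(1)
      (a - expected) / (max_index - expected)
    }
  )
}

#' Cluster-size histogram
#'
#' Counts clusters of sizes 1 through 5; larger clusters are lumped into
#' a single `">5"` bucket.
#'
#' @param partition A partition (vector of group labels, optionally
#'   named).
#' @return Named integer vector with entries `"1"..."5"` and `">5"`.
#' @export
size_histogram <- function(partition) {
  sizes <- table(partition)
  h <- integer(6L)
  names(h) <- c(as.character(1:5), ">5")
  for (s in as.vector(sizes)) {
    if (s <= 5L) h[as.character(s)] <- h[as.character(s)] + 1L
    else h[">5"] <- h[">5"] + 1L
  }
  h
}

#' Full evaluation report against a reference partition
#'
#' Combines cluster counts, pair-error counts with percentages, and the
#' cluster-size histogram into one report.
#'
#' @inheritParams count_pair_errors
#' @return An object of class `scg_evaluation`: a list with
#'   `n_clusters` (including singletons), `n_non_singleton`,
#'   `correct_pairs`, `incorrect_pairs`, `percent_correct`,
#'   `percent_incorrect` (of all within-cluster pairs; `NA` when the
#'   clustering has no pairs), and `size_histogram`.
#' @export
evaluation_report <- function(partition, reference) {
  pe <- count_pair_errors(partition, reference)
  sizes <- table(partition)
  structure(
    list(
      n_clusters = length(sizes),
      n_non_singleton = sum(sizes > 1L),
      correct_pairs = pe$correct,
      incorrect_pairs = pe$incorrect,
      percent_correct = if (pe$total > 0) 100 * pe$correct / pe$total
                        else NA_real_,
      percent_incorrect = if (pe$total > 0) 100 * pe$incorrect / pe$total
                          else NA_real_,
      size_histogram = size_histogram(partition)
    ),
    class = "scg_evaluation"
  )
}

#' @export
print.scg_evaluation <- function(x, ...) {
  fmt_pct <- function(p) if (is.na(p)) "-" else sprintf("(%.1f)", p)
  cat("Total number of clusters:        ", x$n_clusters, "\n")
  cat("Number of non-singleton clusters:", x$n_non_singleton, "\n")
  cat("Number of incorrect pairs:       ", x$incorrect_pairs, " ",
      fmt_pct(x$percent_incorrect), "\n", sep = "")
  cat("Number of correct pairs:         ", x$correct_pairs, " ",
      fmt_pct(x$percent_correct), "\n", sep = "")
  cat("Cluster sizes: ",
      paste(names(x$size_histogram), x$size_histogram,
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
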