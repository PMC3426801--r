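# Laminar cluster forest: the tree structure behind subcluster management.
#
# Leaves are the n objects (node ids 1..n); internal nodes are created in
# formation order with ids n+1, n+2, ... . Every internal node's children
# are the roots its member objects had at the moment the cluster formed,
# so earlier clusters are preserved intact as subclusters.

#' Create an empty cluster forest
#'
#' @param labels Character vector of object labels (or an
#'   `scg_rank_matrix`, whose labels are reused).
#' @return An `scg_forest` in which every object is a singleton root.
#' @export
scg_forest <- function(labels) {
  if (inherits(labels, "scg_rank_matrix")) labels <- labels$labels
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 1L) stop("need at least one object")
  if (anyDuplicated(labels)) stop("object labels must be unique")
  structure(
    list(
      n = n,
      labels = labels,
      parent = rep(NA_integer_, n),   # indexed by node id
      children = vector("list", n),   # empty for leaves
      members = as.list(seq_len(n))   # leaf member sets
    ),
    class = "scg_forest"
  )
}

n_nodes <- function(forest) length(forest$parent)

# Root of the tree currently containing node id (leaf or internal).
node_root <- function(forest, id) {
  while (!is.na(forest$parent[id])) id <- forest$parent[id]
  id
}

#' Merge a cluster into the forest
#'
#' Creates a new root whose children are the current roots of the member
#' objects. Any subset of the members that already shares a common root
#' is attached intact, so previously formed subclusters are preserved.
#' The member set must be a union of existing roots; anything else would
#' break laminarity and is an error.
#'
#' @param forest An `scg_forest`.
#' @param members Integer object ids (leaves) forming the new cluster.
#' @return The updated forest, with attribute `"new_node"` holding the id
#'   of the created root.
#' @export
merge_cluster <- function(forest, members) {
  members <- sort(unique(as.integer(members)))
  if (any(members < 1L | members > forest$n)) {
    stop("member ids out of range 1..", forest$n)
  }
  if (length(members) < 2L) stop("a merged cluster needs at least 2 members")
  if (length(members) >= forest$n) {
    stop("a cluster of size n is disallowed")
  }
  roots <- unique(vapply(members, function(o) node_root(forest, o), 0L))
  if (length(roots) == 1L) {
    stop("cluster {", paste(forest$labels[members], collapse = ","),
         "} is already represented by a single node")
  }
  covered <- sort(unlist(forest$members[roots]))
  if (!identical(covered, members)) {
    stop("cluster {", paste(forest$labels[members], collapse = ","),
         "} straddles an existing cluster: laminarity violated")
  }
  new_id <- n_nodes(forest) + 1L
  forest$parent[new_id] <- NA_integer_
  forest$parent[roots] <- new_id
  forest$children[[new_id]] <- roots
  forest$members[[new_id]] <- members
  attr(forest, "new_node") <- new_id
  forest
}

#' Independent clusters of a forest as a flat partition
#'
#' The roots of the forest are the independent clusters: clusters that
#' are not subclusters of any other cluster. Singleton objects count as
#' their own (singleton) clusters, so the groups always partition the
#' object set.
#'
#' @param forest An `scg_forest`.
#' @return A named integer vector mapping each object label to a group
#'   id (groups numbered by ascending smallest member).
#' @export
independent_clusters <- function(forest) {
  roots <- which(is.na(forest$parent))
  # order groups by their smallest member for stable output
  roots <- roots[order(vapply(forest$members[roots], min, 0L))]
  g <- integer(forest$n)
  for (k in seq_along(roots)) g[forest$members[[roots[k]]]] <- k
  names(g) <- forest$labels
  g
}

# All non-singleton member sets in the forest (internal nodes), as a list
# of sorted integer vectors. Canonical representation used to compare
# forests: a laminar family determines its forest uniquely.
cluster_family <- function(forest) {
  ids <- which(lengths(forest$members) > 1L)
  fam <- forest$members[ids]
  fam[order(vapply(fam, min, 0L), lengths(fam))]
}

# Validator: laminarity + member-union invariants.
validate_forest <- function(forest) {
  stopifnot(inherits(forest, "scg_forest"))
  for (id in seq_len(n_nodes(forest))) {
    ch <- forest$children[[id]]
    if (id <= forest$n) {
      stopifnot(is.null(ch), identical(forest$members[[id]], id))
      next
    }
    if (length(ch) < 2L) stop("internal node ", id, " has < 2 children")
    m <- sort(unlist(forest$members[ch]))
    if (anyDuplicated(m)) stop("sibling member sets overlap at node ", id)
    if (!identical(m, forest$members[[id]])) {
      stop("member set of node ", id, " is not the union of its children")
    }
    if (length(m) >= forest$n && forest$n > 1L) {
      stop("node ", id, " has size n")
    }
    if (any(forest$parent[ch] != id)) stop("broken parent link at ", id)
  }
  roots <- which(is.na(forest$parent))
  leaves_covered <- sort(unlist(forest$members[roots]))
  if (!identical(leaves_covered, seq_len(forest$n))) {
    stop("roots do not partition the object set")
  }
  invisible(forest)
}

#' @export
print.scg_forest <- function(x, ...) {
  ic <- independent_clusters(x)
  n_groups <- max(ic)
  cat("SCG cluster forest:", x$n, "objects,", n_groups,
      "independent clusters (incl. singletons)\n")
  nw <- to_newick(x)
  non_single <- nw[!grepl("^[^(]*;$", nw)]
  if (length(non_single)) cat(paste(non_single, collapse = "\n"), "\n")
  invisible(x)
}

newick_quote <- function(label) {
  if (grepl("[][ (),:;'\"]", label)) {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  } else {
    label
  }
}

render_node <- function(forest, id) {
  if (id <= forest$n) return(newick_quote(forest$labels[id]))
  ch <- forest$children[[id]]
  ch <- ch[order(vapply(forest$members[ch], min, 0L))]
  paste0("(", paste(vapply(ch, function(c) render_node(forest, c), ""),
                    collapse = ","), ")")
}

#' Render a cluster forest as Newick trees
#'
#' One `;`-terminated Newick string per root (singleton roots render as a
#' bare label). No branch lengths are emitted: the forest encodes nesting
#' only. Children are listed by ascending smallest member id so output is
#' stable across runs.
#'
#' @param forest An `scg_forest`.
#' @param collapse If non-`NULL`, paste the trees into one string
#'   separated by `collapse`.
#' @return Character vector of Newick strings (or a single string).
#' @examples
#' to_newick(scg_a3(scg_trace_fixture()))
#' @export
to_newick <- function(forest, collapse = NULL) {
  roots <- which(is.na(forest$parent))
  roots <- roots[order(vapply(forest$members[roots], min, 0L))]
  out <- vapply(roots, function(r) paste0(render_node(forest, r), ";"), "")
  if (!is.null(collapse)) out <- paste(out, collapse = collapse)
  out
}

#' Rank clusters by intra-cluster diameter
#'
#' Orders every non-singleton cluster in the forest by the ascending
#' maximum pairwise distance between its members, ranking the natural
#' clusters in the data from best (tightest) to worst. Ties are broken by
#' ascending smallest member id.
#'
#' @param forest An `scg_forest`.
#' @param scores Square numeric matrix of pairwise scores over the same
#'   objects.
#' @param orientation `"distance"` or `"similarity"`; similarities are
#'   negated so that "tightest" still sorts first.
#' @return A data frame with columns `node`, `size`, `diameter` and
#'   `members` (comma-joined labels), best cluster first.
#' @export
rank_clusters_by_diameter <- function(forest, scores,
                                      orientation = c("distance",
                                                      "similarity")) {
  orientation <- match.arg(orientation)
  if (inherits(scores, "dist")) scores <- as.matrix(scores)
  if (nrow(scores) != forest$n) stop("score matrix does not match forest")
  d <- if (orientation == "similarity") -scores else scores
  ids <- which(lengths(forest$members) > 1L)
  if (!length(ids)) {
    return(data.frame(node = integer(), size = integer(),
                      diameter = numeric(), members = character()))
  }
  diam <- vapply(ids, function(id) {
    m <- forest$members[[id]]
    sub <- d[m, m]
    max(sub[upper.tri(sub)], t(sub)[upper.tri(sub)])
  }, 0)
  smallest <- vapply(forest$members[ids], min, 0L)
  o <- order(diam, smallest)
  data.frame(
    node = ids[o],
    size = lengths(forest$members[ids])[o],
    diameter = diam[o],
    members = vapply(forest$members[ids[o]],
                     function(m) paste(forest$labels[m], collapse = ","), "")
  )
}

#' Flat cluster table for a forest
#'
#' One row per object: its label, the id of its root (independent
#' cluster), and the nesting path of internal nodes from the root down to
#' the object's immediate cluster (e.g. `"2/1"` = first subcluster of
#' root 2). Objects sitting directly under root `k` (including singleton
#' roots) have path `"k"`.
#'
#' @param forest An `scg_forest`.
#' @return Data frame with columns `object`, `root`, `path`.
#' @export
forest_to_table <- function(forest) {
  roots <- which(is.na(forest$parent))
  roots <- roots[order(vapply(forest$members[roots], min, 0L))]
  root_num <- integer(n_nodes(forest))
  path <- character(forest$n)
  root_of <- integer(forest$n)
  for (k in seq_along(roots)) {
    walk <- function(id, prefix) {
      if (id <= forest$n) {
        path[id] <<- prefix
        root_of[id] <<- k
        return(invisible())
      }
      ch <- forest$children[[id]]
      ch <- ch[order(vapply(forest$members[ch], min, 0L))]
      sub <- 0L
      for (c in ch) {
        if (c > forest$n) {
          sub <- sub + 1L
          walk(c, paste0(prefix, "/", sub))
        } else {
          walk(c, prefix)
        }
      }
    }
    walk(roots[k], as.character(k))
  }
  data.frame(object = forest$labels, root = root_of, path = path)
}
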