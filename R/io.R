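# File readers and writers: labelled square matrices, 3-column pairwise
# score lists, 2-column reference partitions, flat cluster tables and
# Newick text. TSV is the default dialect; .csv files switch the
# separator by extension.

sep_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a labelled square score matrix
#'
#' The first row and first column carry the object labels; all remaining
#' cells are parsed as numbers. Tab-separated by default, comma-separated
#' for `.csv` files.
#'
#' @param path File path.
#' @return Numeric matrix with labels as dimnames.
#' @export
read_square_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep_for(path),
                          row.names = 1, check.names = FALSE,
                          comment.char = "#")
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric cell in ", path)
  if (nrow(m) != ncol(m)) {
    stop("matrix in ", path, " is not square: ", nrow(m), " x ", ncol(m))
  }
  if (!identical(rownames(m), colnames(m))) {
    stop("row and column labels disagree in ", path)
  }
  if (anyDuplicated(rownames(m))) stop("duplicate labels in ", path)
  m
}

#' Write a labelled square score matrix
#'
#' @param m Numeric matrix with dimnames.
#' @param path Output path (`.csv` switches to comma separation).
#' @export
write_square_matrix <- function(m, path) {
  utils::write.table(cbind(label = rownames(m), as.data.frame(m)),
                     path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a 3-column pairwise score list
#'
#' Lines of the form `id1<TAB>id2<TAB>score`; lines starting with `#`
#' are comments. Use [densify_pair_scores()] to turn the result into a
#' full score matrix.
#'
#' @param path File path.
#' @return Data frame with columns `id1`, `id2`, `score`.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = sep_for(path),
                          comment.char = "#",
                          col.names = c("id1", "id2", "score"),
                          colClasses = c("character", "character",
                                         "numeric"))
  df
}

#' Read a 2-column reference partition
#'
#' Lines of the form `object_label<TAB>group_label` (e.g. a fold
#' assignment per protein domain). `#` starts a comment.
#'
#' @param path File path.
#' @return Named character vector mapping object labels to group labels.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, header = FALSE, sep = sep_for(path),
                          comment.char = "#",
                          col.names = c("object", "group"),
                          colClasses = "character")
  if (anyDuplicated(df$object)) {
    stop("duplicate object labels in ", path)
  }
  stats::setNames(df$group, df$object)
}

#' Write a flat partition as a 2-column table
#'
#' @param partition Named vector mapping object labels to groups.
#' @param path Output path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(object = names(partition), group = as.vector(partition)),
    path, sep = sep_for(path), quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write the flat cluster table of a forest
#'
#' Columns `object`, `root`, `path` (see [forest_to_table()]), with a
#' header row.
#'
#' @param forest An [scg_forest()].
#' @param path Output path.
#' @export
write_clusters <- function(forest, path) {
  utils::write.table(forest_to_table(forest), path, sep = sep_for(path),
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
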