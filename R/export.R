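#' Write the per-cell pseudotime table
#'
#' TSV with columns `cell_id`, `partition`, `entropy`, `pseudotime`;
#' infinite pseudotimes are serialized as the string `"inf"`.
#'
#' @param result A `trajcci_result` from [run_trajcci()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_pseudotime_table <- function(result, path) {
  pt <- result$pseudotime$pseudotime
  cells <- names(pt)
  df <- data.frame(
    cell_id = cells,
    partition = result$partition$labels[cells],
    entropy = result$entropy[cells],
    pseudotime = ifelse(is.infinite(pt), "inf", format(pt, digits = 12)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the lineage tree
#'
#' Edge list TSV (`parent`, `child`, `weight`) and, optionally, a Graphviz
#' DOT rendering.
#'
#' @param tree A `lineage_tree`.
#' @param path Output TSV path.
#' @param dot_path Optional DOT output path.
#' @return Invisibly, `path`.
#' @export
write_lineage_tree <- function(tree, path, dot_path = NULL) {
  utils::write.table(tree$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(dot_path)) {
    lines <- c("digraph lineage {",
               sprintf('  "%s" [shape=doublecircle];', tree$roots),
               sprintf('  "%s" -> "%s" [label="%.3f"];',
                       tree$edges$parent, tree$edges$child,
                       tree$edges$weight),
               "}")
    writeLines(lines, dot_path)
  }
  invisible(path)
}

#' Write per-cell partition labels
#'
#' @param part A `partitioning`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_partition_labels <- function(part, path) {
  df <- data.frame(cell_id = names(part$labels), partition = part$labels,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the weighted cell graph as an edge list
#'
#' TSV with columns `cell_i`, `cell_j`, `p_joint`, `p_hat` over the upper
#' triangle of the graph support.
#'
#' @param p_joint,p_hat Symmetric cells x cells matrices.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_graph_edges <- function(p_joint, p_hat, path) {
  idx <- which(p_joint > 0 & upper.tri(p_joint), arr.ind = TRUE)
  df <- data.frame(cell_i = rownames(p_joint)[idx[, 1]],
                   cell_j = colnames(p_joint)[idx[, 2]],
                   p_joint = p_joint[idx],
                   p_hat = p_hat[idx],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
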