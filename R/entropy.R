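#' Per-cell functional-group entropy
#'
#' Measures differentiation potency as the Shannon entropy of
#' functional-group activation. For each cell, a group f is active in
#' proportion `a_f` = (genes of f expressed above `threshold`) / (size of
#' f); the activation distribution `p_f = a_f / sum(a)` gives entropy
#' `-sum p_f log p_f` (natural log, `0 log 0 := 0`). Without `gene_groups`
#' every gene is its own group and the entropy reduces to the log of the
#' expressed-gene count. High entropy means broad, uncommitted expression.
#'
#' @param x Cells x genes expression matrix.
#' @param gene_groups Optional gene-to-group mapping: a data.frame with
#'   columns `gene` and `group`, or a character vector of groups named by
#'   gene. Genes absent from the mapping are ignored.
#' @param threshold Activation threshold (>= 0), strict inequality.
#' @return Named numeric vector of per-cell entropies (>= 0).
#' @export
cell_entropy <- function(x, gene_groups = NULL, threshold = 1) {
  validate_expression(x)
  stopifnot(threshold >= 0)
  expressed <- x > threshold
  if (is.null(gene_groups)) {
    cnt <- rowSums(expressed)
    if (any(cnt == 0))
      warning("cell(s) with no expressed gene: entropy set to 0")
    ent <- ifelse(cnt > 0, log(cnt), 0)
    return(stats::setNames(as.numeric(ent), rownames(x)))
  }
  if (is.data.frame(gene_groups)) {
    map <- stats::setNames(as.character(gene_groups$group),
                           gene_groups$gene)
  } else {
    map <- gene_groups
  }
  genes <- intersect(colnames(x), names(map))
  if (length(genes) == 0L) stop("no gene of the matrix is in gene_groups")
  grp <- split(genes, map[genes])
  A <- vapply(grp, function(gs)
    rowSums(expressed[, gs, drop = FALSE]) / length(gs),
    numeric(nrow(x)))
  A <- matrix(A, nrow = nrow(x),
              dimnames = list(rownames(x), names(grp)))
  tot <- rowSums(A)
  if (any(tot == 0))
    warning("cell(s) with zero activation in all groups: entropy set to 0")
  p <- A / ifelse(tot > 0, tot, 1)
  ent <- -rowSums(ifelse(p > 0, p * log(p), 0))
  ent[tot == 0] <- 0
  stats::setNames(as.numeric(ent), rownames(x))
}

#' Stable-state entropy per partition
#'
#' Summarizes each partition by the entropy of its most committed core: the
#' `ceiling(core_fraction * n)` lowest-entropy cells (ties broken by cell
#' id), excluding transition-state cells from the differentiation-order
#' estimate.
#'
#' @param entropy Named per-cell entropy vector (see [cell_entropy()]).
#' @param part A `partitioning` object.
#' @param core_fraction Fraction of cells in the core (0 < f <= 1,
#'   default 0.25).
#' @param aggregate `"mean"` (default) or `"median"` over the core.
#' @return Named numeric vector of per-partition stable-state entropies,
#'   with the selected core cells attached as attribute `core_cells`.
#' @export
stable_state_entropy <- function(entropy, part, core_fraction = 0.25,
                                 aggregate = c("mean", "median")) {
  stopifnot(inherits(part, "partitioning"),
            core_fraction > 0, core_fraction <= 1)
  aggregate <- match.arg(aggregate)
  agg <- if (aggregate == "mean") mean else stats::median
  labels <- part$labels
  if (!all(names(labels) %in% names(entropy)))
    stop("entropy must be defined for every partitioned cell")
  ids <- sort(unique(labels))
  cores <- list()
  sse <- numeric(length(ids))
  for (i in seq_along(ids)) {
    cells <- names(labels)[labels == ids[i]]
    if (length(cells) == 0L) stop("empty partition")
    e <- entropy[cells]
    ord <- order(e, cells)
    n_core <- ceiling(core_fraction * length(cells))
    core <- cells[ord[seq_len(n_core)]]
    cores[[as.character(ids[i])]] <- core
    sse[i] <- agg(entropy[core])
  }
  structure(stats::setNames(sse, as.character(ids)), core_cells = cores)
}

#' Orient the partition graph by entropy
#'
#' Turns each undirected connectivity edge into a directed one, pointing
#' from the higher stable-state entropy partition to the lower one (exact
#' ties: from the lower partition id to the higher). Node and edge weights
#' are unchanged.
#'
#' @param pg A `partition_graph` from [paga_connectivity()].
#' @param sse Named per-partition stable-state entropy.
#' @return Object of class `directed_partition_graph`: list with `nodes`,
#'   `sse`, and `edges` (data.frame `from`, `to`, `weight`).
#' @export
orient_partition_graph <- function(pg, sse) {
  stopifnot(inherits(pg, "partition_graph"))
  nodes <- names(pg$sizes)
  if (!all(nodes %in% names(sse)))
    stop("sse must be defined for all partitions")
  sse <- sse[nodes]
  theta <- pg$theta
  from <- character(0); to <- character(0); w <- numeric(0)
  if (length(nodes) > 1) {
    for (a in seq_along(nodes)) {
      for (b in seq_along(nodes)) {
        if (b <= a || theta[a, b] <= 0) next
        i <- nodes[a]; j <- nodes[b]
        if (sse[i] > sse[j]) {
          from <- c(from, i); to <- c(to, j)
        } else if (sse[j] > sse[i]) {
          from <- c(from, j); to <- c(to, i)
        } else if (as.numeric(i) < as.numeric(j)) {
          from <- c(from, i); to <- c(to, j)
        } else {
          from <- c(from, j); to <- c(to, i)
        }
        w <- c(w, theta[a, b])
      }
    }
  }
  structure(list(nodes = nodes, sse = sse,
                 edges = data.frame(from = from, to = to, weight = w,
                                    stringsAsFactors = FALSE)),
            class = "directed_partition_graph")
}
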