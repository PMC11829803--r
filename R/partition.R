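#' Louvain partitioning of the cell graph
#'
#' Community detection on the weighted cell graph with the
#' resolution-scaled modularity objective. Deterministic under a fixed seed.
#'
#' @param adj Symmetric nonnegative adjacency matrix (`p_hat`).
#' @param resolution Modularity resolution (> 0); larger values give more,
#'   smaller partitions.
#' @param seed Integer seed.
#' @return Object of class `partitioning`: list with `labels` (named
#'   integer vector, ids contiguous from 0), `resolution`, `modularity`.
#' @export
louvain_partition <- function(adj, resolution = 1, seed = 1) {
  if (!is.matrix(adj) || nrow(adj) == 0L) stop("empty graph")
  stopifnot(resolution > 0, nrow(adj) == ncol(adj))
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl)) - 1L
  names(labels) <- rownames(adj)
  structure(list(labels = labels, resolution = resolution,
                 modularity = max(igraph::modularity(cl), -1)),
            class = "partitioning")
}

#' Partition-level connectivity graph
#'
#' Abstracts the cell graph to partitions: for each partition pair (i, j)
#' the connectivity is the observed number of inter-edges divided by the
#' count expected under uniform random edge placement,
#' `theta_ij = e_ij / (E_total * n_i * n_j / choose(n, 2))`, clipped to
#' \[0, 1\]. Edges are counted on the binary support of the adjacency.
#'
#' @param adj Symmetric adjacency matrix used for partitioning.
#' @param part A `partitioning` object covering all cells.
#' @return Object of class `partition_graph`: list with `sizes` (named
#'   per-partition cell counts) and `theta` (symmetric partition x partition
#'   connectivity matrix, zero diagonal).
#' @export
paga_connectivity <- function(adj, part) {
  stopifnot(inherits(part, "partitioning"))
  labels <- part$labels
  n <- nrow(adj)
  if (length(labels) != n) stop("partitioning must cover all cells")
  ids <- sort(unique(labels))
  if (!identical(ids, seq_along(ids) - 1L))
    stop("partition ids must be contiguous from 0")
  sizes <- vapply(ids, function(i) sum(labels == i), integer(1))
  if (any(sizes == 0L)) stop("partition of size 0")
  names(sizes) <- as.character(ids)
  A <- (adj > 0)
  diag(A) <- FALSE
  E_total <- sum(A[upper.tri(A)])
  P <- length(ids)
  theta <- matrix(0, P, P, dimnames = list(names(sizes), names(sizes)))
  if (E_total > 0) {
    li <- labels + 1L
    # inter-edge counts via upper-triangle endpoints
    idx <- which(A & upper.tri(A), arr.ind = TRUE)
    e <- matrix(0, P, P)
    for (r in seq_len(nrow(idx))) {
      a <- li[idx[r, 1]]
      b <- li[idx[r, 2]]
      if (a != b) {
        e[a, b] <- e[a, b] + 1
        e[b, a] <- e[b, a] + 1
      }
    }
    expected <- E_total * outer(sizes, sizes) / choose(n, 2)
    theta <- pmin(e / expected, 1)
    diag(theta) <- 0
    dimnames(theta) <- list(names(sizes), names(sizes))
  }
  structure(list(sizes = sizes, theta = theta), class = "partition_graph")
}
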