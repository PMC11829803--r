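#' Select the root cell
#'
#' The root of the trajectory is the highest-entropy cell within the
#' partition of highest stable-state entropy (ties at either level broken
#' towards the lowest id).
#'
#' @param entropy Named per-cell entropy vector.
#' @param sse Named per-partition stable-state entropy.
#' @param part A `partitioning` object.
#' @return A cell id.
#' @export
select_root_cell <- function(entropy, sse, part) {
  stopifnot(inherits(part, "partitioning"), length(sse) >= 1)
  pids <- names(sse)
  best_p <- pids[order(-sse, as.numeric(pids))][1]
  cells <- names(part$labels)[part$labels == as.integer(best_p)]
  e <- entropy[cells]
  cells[order(-e, cells)][1]
}

#' Diffusion pseudotime with disconnected-topology support
#'
#' Random-walk distance from the root cell in diffusion-map space. The
#' weighted cell graph is density-normalized (weights divided by the
#' product of node degrees), row-normalized into a transition matrix, and
#' the symmetrized kernel is eigendecomposed. The accumulated operator uses
#' the top `n_dcs` non-stationary eigenpairs scaled by
#' `lambda / (1 - lambda)`; pseudotime of a cell is the Euclidean distance
#' between its row of the accumulated operator and the root's row. Cells in
#' components not containing the root receive `Inf`.
#'
#' @param adj Symmetric nonnegative adjacency matrix (`p_hat`), with cell
#'   ids as dimnames.
#' @param root Root cell id (pseudotime 0).
#' @param n_dcs Number of diffusion components (>= 2, default 10; capped at
#'   component size - 1).
#' @return Object of class `pseudotime_result`: list with `root_cell`,
#'   `pseudotime` (named, `Inf` outside the root component) and `n_dcs`.
#' @export
diffusion_pseudotime <- function(adj, root, n_dcs = 10) {
  if (!is.matrix(adj) || nrow(adj) != ncol(adj))
    stop("adj must be a square matrix")
  ids <- rownames(adj)
  if (!root %in% ids) stop("root cell not in graph")
  if (n_dcs < 2) stop("n_dcs must be at least 2")
  if (max(abs(adj - t(adj))) > 1e-10) stop("adj must be symmetric")
  if (min(adj) < 0) stop("adj must be nonnegative")
  pt <- stats::setNames(rep(Inf, nrow(adj)), ids)
  pt[root] <- 0
  g <- igraph::graph_from_adjacency_matrix(adj > 0, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  in_comp <- memb == memb[match(root, ids)]
  if (sum(in_comp) == 1L) {
    warning("root cell is isolated; all other cells get infinite pseudotime")
    return(structure(list(root_cell = root, pseudotime = pt, n_dcs = 0L),
                     class = "pseudotime_result"))
  }
  W <- adj[in_comp, in_comp, drop = FALSE]
  diag(W) <- 0
  nc <- nrow(W)
  q <- rowSums(W)
  Kmat <- W / outer(q, q)          # density normalization
  z <- rowSums(Kmat)
  Tsym <- Kmat / sqrt(outer(z, z)) # symmetrized transition kernel
  eig <- eigen(Tsym, symmetric = TRUE)
  n_use <- min(n_dcs, nc - 1L)
  if (n_use < n_dcs)
    warning("n_dcs capped at component size - 1 (", n_use, ")")
  s <- seq_len(n_use) + 1L         # skip the stationary eigenpair
  lam <- pmin(eig$values[s], 1 - 1e-12)
  f <- lam / (1 - lam)
  V <- eig$vectors[, s, drop = FALSE]
  ri <- match(root, ids[in_comp])
  # eigenvector columns are orthonormal, so the distance between rows of
  # the accumulated operator reduces to a weighted coordinate distance
  diffs <- sweep(V, 2, V[ri, ], "-")
  d <- sqrt(rowSums(sweep(diffs, 2, f, "*")^2))
  pt[in_comp] <- d
  pt[root] <- 0
  structure(list(root_cell = root, pseudotime = pt, n_dcs = n_use),
            class = "pseudotime_result")
}
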