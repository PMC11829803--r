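#' Principal-component embedding
#'
#' Centers each gene and projects cells onto the top principal components.
#' Component signs are fixed so the largest-magnitude loading of each
#' component is positive, making the embedding fully deterministic.
#'
#' @param x Cells x genes matrix (log scale).
#' @param n_components Number of components (clamped to
#'   `min(n_cells, n_genes)` with a warning).
#' @param seed Unused for the exact solver; kept for interface stability.
#' @return Object of class `embedding`: list with `coords`
#'   (cells x d scores) and `explained_variance`.
#' @export
pca_embed <- function(x, n_components = 50, seed = 1) {
  validate_expression(x)
  stopifnot(n_components >= 1)
  d_max <- min(nrow(x), ncol(x))
  if (n_components > d_max) {
    warning("n_components clamped to ", d_max)
    n_components <- d_max
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  rownames(coords) <- rownames(x)
  structure(list(coords = coords,
                 explained_variance = pc$sdev[seq_len(n_components)]^2),
            class = "embedding")
}

# smooth-kNN bandwidth: find sigma with sum_j exp(-d0_j / sigma) = target,
# d0 = neighbour distances shifted by rho (so min(d0) = 0). The sum is
# increasing in sigma from m = #(d0 == 0) up to k, so when m already
# exceeds the target (near-equidistant neighbours) no root exists and the
# search saturates at its upper bracket, giving every neighbour weight ~1;
# otherwise a monotone bisection with 64 halvings.
smooth_knn_sigma <- function(d0, target, scale_ref = max(d0),
                             max_iter = 64) {
  f <- function(s) sum(exp(-d0 / s))
  if (sum(d0 <= 1e-9 * scale_ref) > target) {
    sigma <- max(scale_ref * 1e6, 1)
    return(list(sigma = sigma, converged = FALSE))
  }
  hi <- 1
  it <- 0
  while (f(hi) < target && it < max_iter) {
    hi <- hi * 2
    it <- it + 1
  }
  if (f(hi) < target)
    return(list(sigma = hi, converged = FALSE))
  lo <- 0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (f(mid) >= target) hi <- mid else lo <- mid
  }
  list(sigma = hi, converged = abs(f(hi) - target) <= 1e-5 * max(1, target))
}

#' Fuzzy kNN conditional probabilities
#'
#' For each cell i and its k nearest neighbours j (exact Euclidean search),
#' computes `p(i|j) = exp(-(d(x_i, x_j) - rho_i) / sigma_i)` where `rho_i`
#' is the distance to the nearest neighbour (so the nearest neighbour always
#' gets probability 1, keeping every cell locally connected) and `sigma_i`
#' is calibrated by binary search so the probabilities sum to `log2(k)`.
#'
#' @param emb An `embedding` from [pca_embed()], or a plain cells x d
#'   coordinate matrix with rownames.
#' @param k Number of neighbours (2 <= k < n_cells).
#' @return List with `p_cond` (cells x cells, zero off the kNN support),
#'   `rho`, `sigma`, and `k`.
#' @export
conditional_probabilities <- function(emb, k = 10) {
  X <- if (inherits(emb, "embedding")) emb$coords else emb
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2")
  if (k >= n) stop("k must be smaller than the number of cells")
  D <- as.matrix(stats::dist(X))
  ids <- rownames(X)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  rho <- numeric(n)
  sigma <- numeric(n)
  target <- log2(k)
  n_flagged <- 0L
  for (i in seq_len(n)) {
    ord <- order(D[i, ])
    nb <- ord[ord != i][seq_len(k)]
    dn <- D[i, nb]
    rho[i] <- dn[1]
    fit <- smooth_knn_sigma(dn - rho[i], target, scale_ref = max(dn))
    sigma[i] <- fit$sigma
    if (!fit$converged) n_flagged <- n_flagged + 1L
    p[i, nb] <- exp(-(dn - rho[i]) / sigma[i])
  }
  if (n_flagged > 0L)
    warning("sigma calibration did not reach its target for ", n_flagged,
            " cell(s); best bracket retained")
  list(p_cond = p, rho = stats::setNames(rho, ids),
       sigma = stats::setNames(sigma, ids), k = k)
}

#' Symmetric joint membership probabilities
#'
#' Fuzzy-union symmetrization of the conditional probabilities:
#' `p_ij = p(i|j) + p(j|i) - p(i|j) * p(j|i)`, taken over the union of the
#' two cells' neighbour lists. Entries stay in \[0, 1\].
#'
#' @param p_cond Cells x cells conditional probability matrix.
#' @return Symmetric cells x cells matrix.
#' @export
joint_probabilities <- function(p_cond) {
  if (any(p_cond < 0) || any(p_cond > 1))
    stop("conditional probabilities must lie in [0, 1]")
  p_cond + t(p_cond) - p_cond * t(p_cond)
}

#' Add CCI weights to the cell graph
#'
#' Augments the joint-probability edge weights with the symmetrized
#' cell-cell communication matrix: `p_hat_ij = p_ij + K * S_ij`, applied
#' only on the existing graph support (`p_ij > 0`) so sparsity is preserved.
#'
#' @param p_joint Symmetric joint probability matrix.
#' @param S Symmetric nonnegative CCI matrix (same dimensions), or `NULL`
#'   for none.
#' @param K CCI weight parameter (>= 0); `K = 0` returns `p_joint`
#'   unchanged, bypassing communication information.
#' @return Symmetric weighted adjacency matrix `p_hat`.
#' @export
apply_cci_weights <- function(p_joint, S = NULL, K = 0) {
  if (K < 0) stop("K must be nonnegative")
  if (is.null(S) || K == 0) return(p_joint)
  if (!all(dim(S) == dim(p_joint)))
    stop("S dimensions must match p_joint")
  if (any(S < 0)) stop("S must be nonnegative")
  if (max(abs(S - t(S))) > 1e-12) stop("S must be symmetric")
  p_joint + K * S * (p_joint > 0)
}

#' Build the CCI-augmented cell graph in one call
#'
#' Convenience wrapper: PCA embedding, fuzzy kNN conditional probabilities,
#' joint symmetrization, and CCI weighting.
#'
#' @inheritParams pca_embed
#' @inheritParams apply_cci_weights
#' @param n_neighbors Neighbours for the fuzzy kNN graph.
#' @return Object of class `cell_graph`: list with `embedding`, `p_cond`,
#'   `rho`, `sigma`, `p_joint`, `p_hat`, `n_neighbors`.
#' @export
build_cell_graph <- function(x, n_components = 50, n_neighbors = 10,
                             S = NULL, K = 0, seed = 1) {
  emb <- pca_embed(x, n_components, seed)
  cond <- conditional_probabilities(emb, n_neighbors)
  p_joint <- joint_probabilities(cond$p_cond)
  p_hat <- apply_cci_weights(p_joint, S, K)
  structure(list(embedding = emb, p_cond = cond$p_cond, rho = cond$rho,
                 sigma = cond$sigma, p_joint = p_joint, p_hat = p_hat,
                 n_neighbors = n_neighbors),
            class = "cell_graph")
}
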