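#' Assign cells to groups for communication scoring
#'
#' Returns the supplied labels verbatim when given; otherwise clusters the
#' (log-scale) expression matrix with k-means and picks the number of
#' clusters with the Gap statistic (uniform reference draws over the
#' principal-component bounding box; smallest k whose Gap is within one
#' reference standard error of the next, the Tibshirani rule).
#'
#' @param x Cells x genes matrix, log scale.
#' @param labels Optional per-cell labels; returned unchanged when supplied.
#' @param k_max Largest cluster number considered (>= 1).
#' @param n_ref Number of uniform reference datasets for the Gap statistic.
#' @param seed Integer seed; the choice is deterministic under a fixed seed.
#' @return Named integer vector of group labels (1..k).
#' @export
assign_groups <- function(x, labels = NULL, k_max = 8, n_ref = 20,
                          seed = 1) {
  if (!is.null(labels)) {
    if (length(labels) != nrow(x))
      stop("labels length must match the number of cells")
    return(stats::setNames(labels, rownames(x)))
  }
  validate_expression(x)
  if (k_max < 1) stop("k_max must be at least 1")
  k_max <- min(k_max, nrow(x) - 1L)
  if (k_max < 2) {
    return(stats::setNames(rep(1L, nrow(x)), rownames(x)))
  }
  km <- function(xx, k) stats::kmeans(xx, k, nstart = 10, iter.max = 50)
  set.seed(seed)
  gap <- cluster::clusGap(x, FUNcluster = km, K.max = k_max, B = n_ref,
                          d.power = 2, spaceH0 = "scaledPCA",
                          verbose = FALSE)
  k <- cluster::maxSE(gap$Tab[, "gap"], gap$Tab[, "SE.sim"],
                      method = "Tibs2001SEmax")
  set.seed(seed + 1L)
  fit <- km(x, k)
  stats::setNames(as.integer(fit$cluster), rownames(x))
}

#' Cluster-level ligand-receptor communication probabilities
#'
#' For each ligand-receptor pair k = (L, R) and each ordered group pair
#' (i, j), scores the mass-action communication probability with Hill-type
#' saturation: `C^k_{i,j} = (Lbar_i * Rbar_j) / (kh + Lbar_i * Rbar_j)`,
#' where `Lbar_i` is the arithmetic mean expression of the ligand over the
#' cells of group i (0 when the gene is absent from the matrix) and `Rbar_j`
#' likewise for the receptor. All entries lie in \[0, 1).
#'
#' @param x Cells x genes expression matrix.
#' @param groups Per-cell group labels (any atomic type).
#' @param lr Ligand-receptor table with columns `ligand`, `receptor`,
#'   `pair_id` (see [read_lr_table()]).
#' @param kh Saturation constant (> 0).
#' @return Object of class `cluster_communication`: list with the
#'   group x group x pair array `C`, the `group_levels` and the pair table.
#' @export
cluster_communication <- function(x, groups, lr, kh = 0.5) {
  validate_expression(x)
  stopifnot(kh > 0)
  if (length(groups) != nrow(x))
    stop("groups length must match the number of cells")
  lev <- sort(unique(groups))
  if (any(vapply(lev, function(g) sum(groups == g), integer(1)) == 0L))
    stop("empty group")
  gmean <- function(gene) {
    if (!gene %in% colnames(x)) return(rep(0, length(lev)))
    vapply(lev, function(g) mean(x[groups == g, gene]), numeric(1))
  }
  n_pairs <- nrow(lr)
  C <- array(0, dim = c(length(lev), length(lev), max(n_pairs, 1L)),
             dimnames = list(as.character(lev), as.character(lev),
                             if (n_pairs) lr$pair_id else "none"))
  for (k in seq_len(n_pairs)) {
    prod <- outer(gmean(lr$ligand[k]), gmean(lr$receptor[k]))
    C[, , k] <- prod / (kh + prod)
  }
  if (n_pairs == 0L) C <- C[, , 0, drop = FALSE]
  structure(list(C = C, group_levels = lev, pairs = lr, kh = kh),
            class = "cluster_communication")
}

#' Build the single-cell CCI matrix
#'
#' Projects cluster-level communication down to cell pairs: for sender cell
#' p in group i and receiver cell q in group j,
#' `P[p, q] = sum_k C^k[i, j]` over the ligand-receptor pairs k whose ligand
#' is validly expressed in p and whose receptor is validly expressed in q
#' (strictly above `expr_threshold`). The diagonal is forced to zero; the
#' result is a directed sender -> receiver matrix.
#'
#' @inheritParams cluster_communication
#' @param comm A `cluster_communication` object.
#' @param expr_threshold Valid-expression threshold (>= 0, default 1).
#' @return Nonnegative cells x cells matrix with zero diagonal.
#' @export
build_cci_matrix <- function(x, groups, comm, expr_threshold = 1) {
  validate_expression(x)
  stopifnot(expr_threshold >= 0, inherits(comm, "cluster_communication"))
  if (length(groups) != nrow(x))
    stop("groups length must match the number of cells")
  if (!all(unique(groups) %in% comm$group_levels))
    stop("dimension mismatch between communication array and groups")
  n <- nrow(x)
  gi <- match(groups, comm$group_levels)
  P <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  lr <- comm$pairs
  valid <- function(gene) {
    if (!gene %in% colnames(x)) return(rep(FALSE, n))
    x[, gene] > expr_threshold
  }
  for (k in seq_len(nrow(lr))) {
    vl <- valid(lr$ligand[k])
    vr <- valid(lr$receptor[k])
    if (!any(vl) || !any(vr)) next
    nG <- length(comm$group_levels)
    Ck <- matrix(comm$C[, , k], nG, nG)
    P <- P + Ck[gi, gi, drop = FALSE] * outer(vl, vr)
  }
  diag(P) <- 0
  P
}

#' Symmetrize a directed CCI matrix
#'
#' Averages sender->receiver and receiver->sender probabilities,
#' `S = (P + t(P)) / 2`, and optionally min-max scales the result to
#' \[0, 1\] by its global maximum (skipped when the matrix is all zero).
#' The undirected matrix is what enters the cell-graph edge weights.
#'
#' @param P Square nonnegative cells x cells matrix.
#' @param scale Logical; divide by the global maximum (default `TRUE`).
#' @return Symmetric nonnegative matrix.
#' @export
symmetrize_cci <- function(P, scale = TRUE) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("P must be a square matrix")
  S <- (P + t(P)) / 2
  if (scale) {
    mx <- max(S)
    if (mx > 0) S <- S / mx
  }
  S
}
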