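# Independent oracles used across test files. These deliberately use naive
# formulations (explicit loops, exhaustive enumeration, closed forms) so
# they share no code path with the package implementation.

# triple-loop projection of cluster communication onto cell pairs
cci_triple_loop <- function(x, groups, comm, threshold) {
  n <- nrow(x)
  lr <- comm$pairs
  P <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (p in seq_len(n)) {
    for (q in seq_len(n)) {
      if (p == q) next
      for (k in seq_len(nrow(lr))) {
        lg <- lr$ligand[k]
        rg <- lr$receptor[k]
        vl <- lg %in% colnames(x) && x[p, lg] > threshold
        vr <- rg %in% colnames(x) && x[q, rg] > threshold
        if (vl && vr)
          P[p, q] <- P[p, q] +
            comm$C[as.character(groups[p]), as.character(groups[q]), k]
      }
    }
  }
  P
}

# exhaustive maximum spanning arborescence over all parent assignments
arborescence_exhaustive <- function(n, from, to, w, root) {
  nonroot <- setdiff(seq_len(n), root)
  if (!length(nonroot)) return(list(weight = 0, edges = integer(0)))
  choices <- lapply(nonroot, function(v) which(to == v & from != v))
  if (any(lengths(choices) == 0)) return(list(weight = -Inf, edges = NULL))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  best_w <- -Inf
  best_sel <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    par <- rep(NA_integer_, n)
    par[nonroot] <- from[sel]
    ok <- TRUE
    for (v in nonroot) {
      u <- v
      steps <- 0L
      while (u != root && steps <= n) {
        u <- par[u]
        steps <- steps + 1L
      }
      if (u != root) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      tw <- sum(w[sel])
      if (tw > best_w) {
        best_w <- tw
        best_sel <- sel
      }
    }
  }
  list(weight = best_w, edges = best_sel)
}

# plain O(n^2) concordance count
pas_pair_loop <- function(pt, lab) {
  n <- length(pt)
  conc <- disc <- comp <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (lab[i] == lab[j]) next
      comp <- comp + 1L
      if (pt[i] == pt[j]) next
      if ((pt[i] < pt[j]) == (lab[i] < lab[j])) conc <- conc + 1L
      else disc <- disc + 1L
    }
  }
  (conc - disc) / comp
}

# diffusion pseudotime via the closed-form accumulated operator
# M = (I - (Tsym - psi1 psi1'))^{-1} - I, with the stationary eigenvector
# known analytically as sqrt(z) (normalized); distances between rows of M
dpt_matrix_inverse <- function(W, root_idx) {
  q <- rowSums(W)
  K <- W / outer(q, q)
  z <- rowSums(K)
  Tsym <- K / sqrt(outer(z, z))
  v1 <- sqrt(z) / sqrt(sum(z))
  n <- nrow(W)
  M <- solve(diag(n) - (Tsym - v1 %*% t(v1))) - diag(n)
  sqrt(rowSums((M - matrix(M[root_idx, ], n, n, byrow = TRUE))^2))
}

# random digraph on n nodes where every non-root node has at least one
# in-edge reachable from the root (guaranteed by a random backbone)
random_rooted_digraph <- function(n, root = 1L) {
  from <- integer(0); to <- integer(0)
  order <- c(root, sample(setdiff(seq_len(n), root)))
  for (i in 2:n) { # backbone keeps everything reachable
    from <- c(from, sample(order[seq_len(i - 1)], 1))
    to <- c(to, order[i])
  }
  n_extra <- sample(2:(2 * n), 1)
  ef <- sample(seq_len(n), n_extra, replace = TRUE)
  et <- sample(seq_len(n), n_extra, replace = TRUE)
  keep <- ef != et & et != root
  from <- c(from, ef[keep])
  to <- c(to, et[keep])
  list(n = n, from = from, to = to,
       w = round(stats::runif(length(from), 0.01, 1), 3))
}

# gaussian blob matrix helper (nonnegative, named)
make_blobs <- function(centers, n_per, sd, seed = 42) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * ncol(centers),
                        mean = rep(centers[i, ], each = n_per), sd = sd),
           n_per)))
  dimnames(X) <- list(sprintf("c%03d", seq_len(nrow(X))),
                      sprintf("g%02d", seq_len(ncol(X))))
  X - min(X)
}

# small named expression matrix from a vector layout
expr_mat <- function(values, n_cells, n_genes,
                     cells = sprintf("cell%02d", seq_len(n_cells)),
                     genes = sprintf("gene%02d", seq_len(n_genes))) {
  matrix(values, n_cells, n_genes, dimnames = list(cells, genes))
}

# majority planted segment per partition, and whether the lineage tree
# links partitions in planted parent -> child order
branch_adjacency_recovered <- function(res, branch) {
  tab <- table(res$partition$labels, branch[names(res$partition$labels)])
  maj <- apply(tab, 1, which.max)
  ed <- res$lineage$edges
  cross <- ed[maj[ed$parent] != maj[ed$child], , drop = FALSE]
  nrow(cross) > 0 && all(maj[cross$parent] == 1 & maj[cross$child] == 2)
}
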