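#' Generate a synthetic branching lineage
#'
#' Builds an expression matrix over a rooted tree of `n_branches` segments
#' with known per-cell time, designed so every stage of the pipeline is
#' testable: a large pool of "potency" genes shuts down progressively along
#' true time (so the expressed-gene count, and hence the per-gene-group
#' entropy, decreases along the lineage); each segment carries its own
#' marker program ramping up along local time (separating partitions); and
#' for every parent-child segment pair, designated ligand genes are
#' expressed in the parent's cells and matching receptor genes in the
#' child's cells, so communication information is informative about lineage
#' adjacency. Noise is multiplicative lognormal. Bit-reproducible under a
#' fixed seed.
#'
#' @param n_cells Total cells (split evenly over segments; >= 10 per
#'   segment).
#' @param n_genes Total genes (>= 10 per segment).
#' @param n_branches Number of tree segments (segment s hangs off segment
#'   `floor(s/2)`; segment 1 is the root).
#' @param noise_sd Standard deviation of the lognormal noise (0 for
#'   noiseless).
#' @param seed Integer seed.
#' @return Object of class `synthetic_lineage`: list with `matrix`
#'   (cells x genes), `true_time` (in \[0, 1\]), `branch` (per-cell segment
#'   label), `lr_table`, and `params`.
#' @export
generate_lineage <- function(n_cells = 600, n_genes = 200, n_branches = 2,
                             noise_sd = 0.2, seed = 1) {
  if (n_branches < 1) stop("infeasible sizes: need at least one branch")
  if (n_genes < 10 * n_branches)
    stop("infeasible sizes: need at least 10 genes per branch")
  if (floor(n_cells / n_branches) < 10)
    stop("infeasible sizes: need at least 10 cells per branch")
  set.seed(seed)
  B <- n_branches
  parent <- c(0L, as.integer(floor(seq_len(B)[-1] / 2)))
  depth <- integer(B)
  for (s in seq_len(B)[-1]) depth[s] <- depth[parent[s]] + 1L
  D <- max(depth) + 1L
  seg <- rep(seq_len(B), length.out = n_cells)
  seg <- sort(seg)
  # sigmoidal ramps pinned to exactly zero at the segment boundary, so
  # expression profiles are continuous along every lineage path
  soft_on <- function(t, t0, offset, scale) {
    b <- stats::plogis(-offset / scale)
    pmax(0, (stats::plogis((t - t0 - offset) / scale) - b) / (1 - b))
  }
  soft_off <- function(t, t1, offset, scale) {
    b <- stats::plogis(-offset / scale)
    pmax(0, (stats::plogis((t1 - offset - t) / scale) - b) / (1 - b))
  }
  u <- stats::runif(n_cells)
  true_time <- (depth[seg] + u) / D
  seg_start <- depth / D

  n_lr_pairs <- 2L                      # ligand-receptor pairs per tree edge
  edges <- which(parent > 0L)           # child segments
  n_lr_genes <- 2L * n_lr_pairs * length(edges)
  m_per <- max(5L, floor(0.15 * n_genes / B))
  n_marker <- m_per * B
  n_pot <- n_genes - n_marker - n_lr_genes
  if (n_pot < B) stop("infeasible sizes: too few genes for the potency pool")

  mat <- matrix(0, n_cells, n_genes)
  gene_names <- character(n_genes)
  g <- 0L
  # potency pool: high early, shutting down at gene-specific times
  tau <- stats::runif(n_pot, 0.1, 1.05)
  amp <- stats::runif(n_pot, 5, 15)
  for (j in seq_len(n_pot)) {
    g <- g + 1L
    gene_names[g] <- sprintf("POT_%03d", j)
    mat[, g] <- amp[j] * stats::plogis((tau[j] - true_time) / 0.04)
  }
  # per-segment marker programs: ramp up at the segment start and stay on
  # in descendant segments, so expression is continuous along every
  # root-to-leaf path while branches still separate
  in_subtree <- function(s) {
    vapply(seg, function(t0) {
      v <- t0
      while (v > 0L) {
        if (v == s) return(TRUE)
        v <- parent[v]
      }
      FALSE
    }, logical(1))
  }
  for (s in seq_len(B)) {
    amps <- stats::runif(m_per, 5, 15)
    on <- in_subtree(s)
    for (j in seq_len(m_per)) {
      g <- g + 1L
      gene_names[g] <- sprintf("MRK_s%d_%02d", s, j)
      mat[on, g] <- amps[j] *
        soft_on(true_time[on], seg_start[s], 0.15, 0.05)
    }
  }
  # planted ligand-receptor structure along tree edges
  lig <- character(0); rec <- character(0); pid <- character(0)
  for (ch in edges) {
    pa <- parent[ch]
    bnd <- seg_start[ch]
    for (j in seq_len(n_lr_pairs)) {
      # ligand in parent-segment cells, tapering towards the boundary;
      # receptor in child-segment cells, ramping up after it: the pair is
      # validly co-expressed across the planted lineage edge while the
      # expression profile stays continuous in time
      g <- g + 1L
      lg <- sprintf("LIG_e%d_%d", ch, j)
      gene_names[g] <- lg
      on <- seg == pa
      lig_expr <- 8 * soft_off(true_time[on], bnd, 0.1, 0.04)
      if (parent[pa] > 0L)  # ramp in after the parent's own start boundary
        lig_expr <- lig_expr *
          soft_on(true_time[on], seg_start[pa], 0.1, 0.04)
      mat[on, g] <- lig_expr
      g <- g + 1L
      rg <- sprintf("REC_e%d_%d", ch, j)
      gene_names[g] <- rg
      on <- seg == ch
      rec_expr <- 8 * soft_on(true_time[on], bnd, 0.1, 0.04)
      if (any(parent == ch))  # taper out before the child's end boundary
        rec_expr <- rec_expr *
          soft_off(true_time[on], seg_start[ch] + 1 / D, 0.1, 0.04)
      mat[on, g] <- rec_expr
      lig <- c(lig, lg); rec <- c(rec, rg)
      pid <- c(pid, sprintf("edge%d_pair%d", ch, j))
    }
  }
  if (noise_sd > 0)
    mat <- mat * exp(matrix(stats::rnorm(n_cells * n_genes, 0, noise_sd),
                            n_cells, n_genes))
  dimnames(mat) <- list(sprintf("cell_%04d", seq_len(n_cells)), gene_names)
  structure(list(matrix = mat,
                 true_time = stats::setNames(true_time, rownames(mat)),
                 branch = stats::setNames(paste0("segment_", seg),
                                          rownames(mat)),
                 lr_table = data.frame(ligand = lig, receptor = rec,
                                       pair_id = pid,
                                       stringsAsFactors = FALSE),
                 params = list(n_cells = n_cells, n_genes = n_genes,
                               n_branches = n_branches,
                               noise_sd = noise_sd, seed = seed,
                               parent = parent, depth = depth)),
            class = "synthetic_lineage")
}

#' Generate a structureless null dataset
#'
#' I.i.d. lognormal noise with no lineage, uniform `true_time`, and an
#' empty ligand-receptor table; a negative control on which pseudotime
#' should carry no label information (PAS near 0).
#'
#' @param n_cells,n_genes Dimensions (>= 2).
#' @param seed Integer seed.
#' @return A `synthetic_lineage` object (branch label `"none"`).
#' @export
generate_null <- function(n_cells = 200, n_genes = 100, seed = 1) {
  stopifnot(n_cells >= 2, n_genes >= 2)
  set.seed(seed)
  mat <- matrix(exp(stats::rnorm(n_cells * n_genes, log(3), 1)),
                n_cells, n_genes,
                dimnames = list(sprintf("cell_%04d", seq_len(n_cells)),
                                sprintf("GENE_%03d", seq_len(n_genes))))
  structure(list(matrix = mat,
                 true_time = stats::setNames(stats::runif(n_cells),
                                             rownames(mat)),
                 branch = stats::setNames(rep("none", n_cells),
                                          rownames(mat)),
                 lr_table = data.frame(ligand = character(0),
                                       receptor = character(0),
                                       pair_id = character(0),
                                       stringsAsFactors = FALSE),
                 params = list(n_cells = n_cells, n_genes = n_genes,
                               seed = seed)),
            class = "synthetic_lineage")
}

#' Quartile labels of true time
#'
#' Ordinal external labels (0..3) from the quartiles of a true-time vector,
#' mimicking stage labels for PAS evaluation.
#'
#' @param true_time Numeric vector in \[0, 1\].
#' @return Named integer vector of quartile ranks.
#' @export
time_quartile_labels <- function(true_time) {
  q <- stats::quantile(true_time, c(0.25, 0.5, 0.75), names = FALSE)
  stats::setNames(as.integer(findInterval(true_time, q)), names(true_time))
}
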