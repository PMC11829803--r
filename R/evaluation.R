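#' Pseudotime accuracy score
#'
#' Signed concordance between a pseudotime ordering and external ordinal
#' labels. Over all unordered cell pairs with distinct labels: a pair is
#' concordant when the earlier cell in pseudotime carries the earlier
#' label, discordant when it carries the later label; pairs tied in
#' pseudotime (including pairs where both values are infinite) score 0.
#' The score is `(concordant - discordant) / comparable`, in \[-1, 1\].
#'
#' @param pseudotime Per-cell numeric vector (`Inf` allowed). If named and
#'   `external` is also named, the two are aligned by name.
#' @param external Per-cell ordinal labels (integer ranks or ordered
#'   factor).
#' @return Object of class `pas_report`: list with `pas`, `n_comparable`,
#'   `n_concordant`, `n_discordant`, `n_tied_pseudotime`.
#' @export
pas <- function(pseudotime, external) {
  if (length(pseudotime) != length(external))
    stop("pseudotime and external must have the same length")
  if (length(pseudotime) < 2) stop("need at least 2 cells")
  if (!is.null(names(pseudotime)) && !is.null(names(external)))
    external <- external[names(pseudotime)]
  lab <- if (is.factor(external)) as.integer(external) else
    as.numeric(external)
  n <- length(pseudotime)
  Ti <- matrix(lab, n, n)
  Tj <- t(Ti)
  Pi <- matrix(pseudotime, n, n)
  Pj <- t(Pi)
  ut <- upper.tri(Ti)
  comp <- ut & (Ti != Tj)
  M <- sum(comp)
  if (M == 0) stop("no comparable pairs")
  tied <- comp & (Pi == Pj)
  conc <- comp & ((Pi < Pj & Ti < Tj) | (Pi > Pj & Ti > Tj))
  disc <- comp & ((Pi < Pj & Ti > Tj) | (Pi > Pj & Ti < Tj))
  structure(list(pas = (sum(conc) - sum(disc)) / M,
                 n_comparable = M,
                 n_concordant = sum(conc),
                 n_discordant = sum(disc),
                 n_tied_pseudotime = sum(tied)),
            class = "pas_report")
}

#' @export
print.pas_report <- function(x, ...) {
  cat(sprintf(
    "PAS = %.4f  (%d concordant, %d discordant, %d tied of %d comparable pairs)\n",
    x$pas, x$n_concordant, x$n_discordant, x$n_tied_pseudotime,
    x$n_comparable))
  invisible(x)
}

#' Sweep the CCI weight parameter
#'
#' Reruns the downstream pipeline (edge weighting, partitioning,
#' connectivity, entropy ordering, lineage tree, pseudotime, PAS) for each
#' value of the CCI weight K on a fixed grid, caching everything upstream
#' (preprocessing, communication scoring, PCA, fuzzy kNN skeleton, per-cell
#' entropy). Returns the K maximizing the PAS (ties towards the smallest
#' K). Failures at single grid points are skipped with a warning.
#'
#' @param x Raw cells x genes expression matrix.
#' @param lr Ligand-receptor table.
#' @param external Named per-cell external ordinal labels.
#' @param grid Strictly increasing vector of K values (default 0 to 10 in
#'   0.1 steps).
#' @param config A [trajcci_config()] list.
#' @param labels Optional per-cell group labels for communication scoring.
#' @param gene_groups Optional gene-group mapping for entropy.
#' @return Object of class `sweep_result`: list with `grid`, `pas_per_k`,
#'   `best_k`, `best_pas`.
#' @export
sweep_cci_weight <- function(x, lr, external, grid = seq(0, 10, by = 0.1),
                             config = trajcci_config(), labels = NULL,
                             gene_groups = NULL) {
  if (length(grid) == 0) stop("grid must be nonempty")
  if (any(diff(grid) <= 0) || any(grid < 0))
    stop("grid must be strictly increasing and nonnegative")
  mat <- prepare_matrix(x, config)
  if (!is.null(names(external))) {
    external <- external[rownames(mat)]  # drop cells lost to filtering
  } else if (length(external) != nrow(mat)) {
    stop("external labels must be named when preprocessing drops cells")
  }
  if (!is.null(labels) && !is.null(names(labels)))
    labels <- labels[rownames(mat)]
  skel <- build_skeleton(mat, lr, labels, gene_groups, config,
                         need_cci = any(grid > 0))
  pas_per_k <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    res <- tryCatch(
      run_from_weight(skel, grid[i], config, external),
      error = function(e) {
        warning("K = ", grid[i], " failed: ", conditionMessage(e))
        NULL
      })
    if (!is.null(res) && !is.null(res$pas))
      pas_per_k[i] <- res$pas$pas
  }
  if (all(is.na(pas_per_k))) stop("all grid points failed")
  best <- which.max(pas_per_k) # first max = smallest K on ties
  structure(list(grid = grid, pas_per_k = pas_per_k,
                 best_k = grid[best], best_pas = pas_per_k[best]),
            class = "sweep_result")
}
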