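#' Count expressed genes per cell
#'
#' A gene counts as expressed in a cell when its value is strictly greater
#' than `threshold` (e.g. FPKM > 1).
#'
#' @param x Cells x genes expression matrix.
#' @param threshold Expression threshold (>= 0); strict inequality.
#' @return Named integer vector, one count per cell.
#' @export
count_expressed_genes <- function(x, threshold = 1) {
  validate_expression(x)
  stopifnot(threshold >= 0)
  counts <- rowSums(x > threshold)
  stats::setNames(as.integer(counts), rownames(x))
}

#' Filter out low-complexity cells
#'
#' Removes cells whose expressed-gene count falls below
#' `factor` x (the `quantile`-th percentile of all expressed-gene counts);
#' with the defaults, below three quarters of the 10th percentile. The
#' percentile uses linear interpolation between order statistics.
#'
#' @inheritParams count_expressed_genes
#' @param quantile Percentile (in (0, 1)) of the per-cell counts.
#' @param factor Multiplier (> 0, or 0 to disable) applied to the percentile.
#' @return The matrix with offending cells removed, order preserved.
#' @export
filter_low_complexity_cells <- function(x, threshold = 1, quantile = 0.1,
                                        factor = 0.75) {
  validate_expression(x)
  stopifnot(quantile > 0, quantile < 1, factor >= 0)
  counts <- count_expressed_genes(x, threshold)
  cutoff <- factor * stats::quantile(counts, probs = quantile, names = FALSE)
  keep <- counts >= cutoff
  if (!any(keep)) stop("all cells filtered")
  x[keep, , drop = FALSE]
}

#' Filter genes by expression prevalence
#'
#' Keeps genes expressed (strictly above `threshold`) in more than
#' `min_fraction` of cells (strict inequality).
#'
#' @inheritParams count_expressed_genes
#' @param min_fraction Minimum fraction of expressing cells, in \[0, 1\].
#' @return The matrix with low-prevalence genes removed, order preserved.
#' @export
filter_genes_by_prevalence <- function(x, min_fraction = 0.05,
                                       threshold = 1) {
  validate_expression(x)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  frac <- colMeans(x > threshold)
  keep <- frac > min_fraction
  if (!any(keep)) stop("no genes pass the prevalence filter")
  x[, keep, drop = FALSE]
}

#' Scale cells to the median library size
#'
#' Per-cell scaling so every cell's total expression equals the median
#' library size; applied before log transformation. Cells with zero totals
#' are left unchanged (with a warning).
#'
#' @inheritParams count_expressed_genes
#' @return The rescaled matrix.
#' @export
normalize_library_size <- function(x) {
  validate_expression(x)
  lib <- rowSums(x)
  target <- stats::median(lib)
  scale <- ifelse(lib > 0, target / lib, 1)
  if (any(lib == 0)) warning("cells with zero library size left unscaled")
  x * scale
}

#' Log-transform expression values
#'
#' Applies `log2(x + 1)` entrywise; the pseudo-count keeps zeros at zero.
#'
#' @inheritParams count_expressed_genes
#' @return The transformed matrix.
#' @export
log_transform <- function(x) {
  validate_expression(x)
  log2(x + 1)
}
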