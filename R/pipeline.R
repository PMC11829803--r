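#' Pipeline configuration
#'
#' Collects every tunable parameter of the trajectory pipeline with its
#' default. The configuration is a plain list, serializable with
#' [write_config()] / [read_config()]; every run records the fully resolved
#' configuration in its result.
#'
#' @param expr_threshold Valid-expression threshold for CCI scoring and
#'   entropy activation (default 1, log scale).
#' @param n_pcs Principal components for the embedding (default 50).
#' @param n_neighbors Neighbours of the fuzzy kNN graph (default 10).
#' @param cci_weight CCI weight K added to the edge weights (default 1;
#'   0 bypasses communication information).
#' @param resolution Louvain resolution (default 1).
#' @param core_fraction Stable-state core fraction (default 0.25).
#' @param n_dcs Diffusion components for pseudotime (default 10).
#' @param kh Saturation constant of the communication score (default 0.5).
#' @param k_max,n_ref Gap-statistic limits for unsupervised grouping.
#' @param scale_cci Min-max scale the symmetrized CCI matrix (default TRUE).
#' @param preprocess Apply cell/gene filters, normalization and log
#'   transform to the input (default TRUE; set FALSE for matrices that are
#'   already on log scale).
#' @param normalize Median library-size scaling during preprocessing.
#' @param gene_min_fraction Gene prevalence filter fraction (default 0.05).
#' @param cell_quantile,cell_factor Low-complexity cell filter parameters
#'   (default 0.1 and 0.75).
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `trajcci_config`.
#' @export
trajcci_config <- function(expr_threshold = 1, n_pcs = 50, n_neighbors = 10,
                           cci_weight = 1, resolution = 1,
                           core_fraction = 0.25, n_dcs = 10, kh = 0.5,
                           k_max = 8, n_ref = 20, scale_cci = TRUE,
                           preprocess = TRUE, normalize = TRUE,
                           gene_min_fraction = 0.05, cell_quantile = 0.1,
                           cell_factor = 0.75, seed = 1) {
  cfg <- list(expr_threshold = expr_threshold, n_pcs = n_pcs,
              n_neighbors = n_neighbors, cci_weight = cci_weight,
              resolution = resolution, core_fraction = core_fraction,
              n_dcs = n_dcs, kh = kh, k_max = k_max, n_ref = n_ref,
              scale_cci = scale_cci, preprocess = preprocess,
              normalize = normalize, gene_min_fraction = gene_min_fraction,
              cell_quantile = cell_quantile, cell_factor = cell_factor,
              seed = as.integer(seed))
  stopifnot(cfg$expr_threshold >= 0, cfg$cci_weight >= 0,
            cfg$resolution > 0, cfg$core_fraction > 0,
            cfg$core_fraction <= 1, cfg$n_dcs >= 2, cfg$kh > 0)
  class(cfg) <- "trajcci_config"
  cfg
}

#' Write / read a configuration file (JSON)
#' @param config A `trajcci_config` list.
#' @param path File path.
#' @return `read_config` returns a `trajcci_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(trajcci_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

# stage-derived seeds (kept well below 2^31)
stage_seed <- function(seed, offset) (as.integer(seed) %% 1000000L) + offset

# preprocessing: filters, normalization, log transform
prepare_matrix <- function(x, config) {
  validate_expression(x)
  if (!config$preprocess) return(x)
  x <- filter_low_complexity_cells(x, threshold = 1,
                                   quantile = config$cell_quantile,
                                   factor = config$cell_factor)
  x <- filter_genes_by_prevalence(x, min_fraction = config$gene_min_fraction,
                                  threshold = 1)
  if (config$normalize) x <- normalize_library_size(x)
  log_transform(x)
}

# everything upstream of the CCI weight: groups, symmetrized CCI matrix,
# PCA embedding, fuzzy kNN skeleton, per-cell entropy
build_skeleton <- function(mat, lr, labels, gene_groups, config,
                           need_cci = TRUE) {
  S <- NULL
  groups <- NULL
  if (need_cci && !is.null(lr)) {
    groups <- assign_groups(mat, labels = labels, k_max = config$k_max,
                            n_ref = config$n_ref,
                            seed = stage_seed(config$seed, 11L))
    comm <- cluster_communication(mat, groups, lr, kh = config$kh)
    P <- build_cci_matrix(mat, groups, comm,
                          expr_threshold = config$expr_threshold)
    S <- symmetrize_cci(P, scale = config$scale_cci)
  }
  emb <- pca_embed(mat, config$n_pcs, seed = stage_seed(config$seed, 7L))
  cond <- conditional_probabilities(emb, config$n_neighbors)
  p_joint <- joint_probabilities(cond$p_cond)
  entropy <- cell_entropy(mat, gene_groups = gene_groups,
                          threshold = config$expr_threshold)
  list(mat = mat, groups = groups, S = S, embedding = emb,
       p_cond = cond$p_cond, rho = cond$rho, sigma = cond$sigma,
       p_joint = p_joint, entropy = entropy)
}

# downstream of the CCI weight: partitioning, abstraction, entropy ordering,
# lineage tree, root, pseudotime, optional PAS
run_from_weight <- function(skel, K, config, external = NULL) {
  p_hat <- apply_cci_weights(skel$p_joint, skel$S, K)
  part <- louvain_partition(p_hat, resolution = config$resolution,
                            seed = stage_seed(config$seed, 31L))
  pg <- paga_connectivity(p_hat, part)
  sse <- stable_state_entropy(skel$entropy, part,
                              core_fraction = config$core_fraction)
  dg <- orient_partition_graph(pg, sse)
  tree <- max_arborescence(dg)
  root <- select_root_cell(skel$entropy, sse, part)
  dpt <- diffusion_pseudotime(p_hat, root, n_dcs = config$n_dcs)
  report <- NULL
  if (!is.null(external))
    report <- pas(dpt$pseudotime, external)
  list(p_hat = p_hat, partition = part, partition_graph = pg, sse = sse,
       lineage = tree, root_cell = root, pseudotime = dpt, pas = report)
}

#' Run the full trajectory pipeline
#'
#' Executes preprocessing, communication scoring, graph construction,
#' Louvain partitioning and abstraction, entropy-ordered lineage inference
#' and diffusion pseudotime; scores the ordering against external labels
#' when the metadata provides them. Fully deterministic under a fixed
#' `config$seed`.
#'
#' @param x Raw cells x genes expression matrix (see
#'   [read_expression()]).
#' @param lr Optional ligand-receptor table; required when
#'   `config$cci_weight > 0`.
#' @param metadata Optional data.frame with `cell_id` and optional
#'   `cluster_label` / `external_label` columns (see
#'   [read_cell_metadata()]).
#' @param config A [trajcci_config()] list.
#' @param gene_groups Optional gene-group mapping for [cell_entropy()].
#' @return Object of class `trajcci_result`: list with `pseudotime`
#'   (a `pseudotime_result`), `lineage`, `partition`, `partition_graph`,
#'   `entropy`, `sse`, `groups`, `root_cell`, `pas` (or `NULL`), `config`.
#' @export
run_trajcci <- function(x, lr = NULL, metadata = NULL,
                        config = trajcci_config(), gene_groups = NULL) {
  if (config$cci_weight > 0 && is.null(lr))
    stop("CCI requested without ligand-receptor table")
  labels <- NULL
  external <- NULL
  if (!is.null(metadata)) {
    idx <- match(rownames(x), metadata$cell_id)
    if ("cluster_label" %in% names(metadata) &&
        !anyNA(idx) && !anyNA(metadata$cluster_label[idx]))
      labels <- metadata$cluster_label[idx]
    if ("external_label" %in% names(metadata) && !anyNA(idx))
      external <- stats::setNames(metadata$external_label[idx], rownames(x))
  }
  mat <- prepare_matrix(x, config)
  if (!is.null(labels)) labels <- labels[match(rownames(mat), rownames(x))]
  if (!is.null(external)) external <- external[rownames(mat)]
  skel <- build_skeleton(mat, lr, labels, gene_groups, config,
                         need_cci = config$cci_weight > 0)
  res <- run_from_weight(skel, config$cci_weight, config, external)
  structure(list(pseudotime = res$pseudotime, lineage = res$lineage,
                 partition = res$partition,
                 partition_graph = res$partition_graph,
                 entropy = skel$entropy, sse = res$sse,
                 groups = skel$groups, root_cell = res$root_cell,
                 pas = res$pas, config = config,
                 n_cells = nrow(mat), n_genes = ncol(mat)),
            class = "trajcci_result")
}

#' @export
print.trajcci_result <- function(x, ...) {
  cat("Trajectory inference result\n")
  cat(sprintf("  %d cells x %d genes after preprocessing\n",
              x$n_cells, x$n_genes))
  cat(sprintf("  %d partitions; root partition(s): %s; root cell: %s\n",
              length(x$sse), paste(x$lineage$roots, collapse = ", "),
              x$root_cell))
  if (nrow(x$lineage$edges))
    cat("  lineage edges:",
        paste(sprintf("%s->%s", x$lineage$edges$parent,
                      x$lineage$edges$child), collapse = " "), "\n")
  if (!is.null(x$pas)) print(x$pas)
  invisible(x)
}
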